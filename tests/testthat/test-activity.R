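test_that("posterior exceedance matches dense quadrature without random effects", {
  set.seed(42)
  design1 <- generate_design(1, 8, seed = 1)   # one obs per cell, one lane
  h <- flat_hyper()
  worst <- 0
  for (i in 1:25) {
    phi <- exp(rnorm(1, log(0.1), 0.5))
    b_true <- rnorm(8, 1, sqrt(2))
    off <- rnorm(8, 0, 0.3)
    y <- rnbinom(8, size = 1 / phi, mu = exp(off + b_true))
    T_ <- rnorm(1, 1, 1)
    gp <- gene_posterior(y, design1, off, h, threshold = T_, phi = phi)
    for (cell in 1:8) {
      p_quad <- quadrature_tail(y[cell], off[cell], phi, 1, 2, T_)
      worst <- max(worst, abs(gp$p_exceed[cell] - p_quad))
    }
  }
  expect_lt(worst, 0.02)
})

test_that("exceedance probabilities move in the right directions", {
  design1 <- generate_design(1, 8, seed = 2)
  h <- flat_hyper(beta_mean = rep(-4, 8), beta_var = rep(1, 8))
  # all-zero counts, prior far below T: confidently inactive
  gp0 <- gene_posterior(rep(0L, 8), design1, rep(0, 8), h, threshold = 1,
                        phi = 0.1)
  expect_true(all(gp0$p_exceed < 0.05))
  # very large counts: confidently active
  h2 <- flat_hyper()
  gp1 <- gene_posterior(rep(5000L, 8), design1, rep(0, 8), h2, threshold = 1,
                        phi = 0.1)
  expect_true(all(gp1$p_exceed > 0.95))
})

test_that("p_exceed is monotone in the counts", {
  design1 <- generate_design(1, 8, seed = 3)
  h <- flat_hyper()
  prev <- 0
  for (y1 in c(0L, 1L, 2L, 5L, 10L, 25L, 60L)) {
    y <- rep(3L, 8); y[2] <- y1
    gp <- gene_posterior(y, design1, rep(0, 8), h, threshold = 1, phi = 0.1)
    # allow numerical-integration noise well below scientific relevance
    expect_gte(gp$p_exceed[2] + 1e-5, prev)
    prev <- gp$p_exceed[2]
  }
})

test_that("threshold calibration hits the reads-per-million target", {
  s <- default_sim()
  hyper <- cached_hyper()
  thr <- calibrate_threshold(hyper, s$norm, target_rpm = 2)
  b <- activity_boundary(thr, hyper)
  expect_equal(b$boundary_rpm, 2, tolerance = 1e-3)
  # monotonicity: doubling the target raises the threshold
  thr2 <- calibrate_threshold(hyper, s$norm, target_rpm = 4)
  expect_gt(thr2$threshold, thr$threshold)
})

test_that("calibration is a fixed point under re-calibration", {
  s <- default_sim()
  hyper <- cached_hyper()
  thr <- calibrate_threshold(hyper, s$norm, target_rpm = 2)
  b <- activity_boundary(thr, hyper)
  thr2 <- calibrate_threshold(hyper, s$norm, target_rpm = b$boundary_rpm)
  expect_equal(thr2$threshold, thr$threshold, tolerance = 1e-6)
})

test_that("longer genes need more reads when the length trend is positive", {
  s <- cached_sim("norm_slope",
                  sim_config(n_genes = 5000, seed = 32, length_slope = 1,
                             gc_lin = 0, gc_quad = 0, fraction_inactive = 0,
                             fraction_de = 0))
  hyper <- estimate_hyperparameters(s$sim$counts, s$sim$design, s$norm)
  thr <- calibrate_threshold(hyper, s$norm, target_rpm = 2)
  sm <- s$norm$smoother
  off_avg <- predict(sm)
  off_long <- predict(sm, length_bp = 2 * exp(sm$loglen_mean))
  b_avg <- activity_boundary(thr, hyper, offset = off_avg)
  b_long <- activity_boundary(thr, hyper, offset = off_long)
  expect_gt(b_long$boundary_count, b_avg$boundary_count)
})

test_that("the strict one-half rule decides activity calls", {
  probs <- matrix(c(0.5, 0.5001, 1, 0, 0.4999, 1, 1, 1), 1, 8)
  calls <- call_activity(probs)
  expect_equal(as.vector(calls$calls),
               c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  all1 <- call_activity(matrix(1, 3, 8))
  expect_true(all(all1$calls))
  expect_true(all(all1$active_overall))
})

test_that("hyperparameter estimates are invariant to gene order", {
  s <- default_sim()
  h1 <- cached_hyper()
  set.seed(99)
  perm <- sample(nrow(s$sim$counts))
  h2 <- estimate_hyperparameters(s$sim$counts[perm, ], s$sim$design,
                                 s$norm$offsets[perm, ])
  expect_equal(h2$beta_mean, h1$beta_mean, tolerance = 1e-6)
  expect_equal(h2$log_disp_mean, h1$log_disp_mean, tolerance = 1e-6)
})

test_that("a degenerate fixed-effect population shrinks toward zero variance", {
  s <- cached_sim("betavar0",
                  sim_config(n_genes = 600, seed = 41, beta_var = rep(0, 8),
                             fraction_inactive = 0, fraction_de = 0))
  h <- estimate_hyperparameters(s$sim$counts, s$sim$design,
                                s$sim$offsets_true)
  expect_true(all(h$beta_var < 0.05))
})

test_that("too few genes is an error", {
  s <- default_sim()
  expect_error(estimate_hyperparameters(s$sim$counts[1:100, ], s$sim$design,
                                        s$norm$offsets[1:100, ]),
               "500")
})
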