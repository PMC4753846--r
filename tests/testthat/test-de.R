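make_design <- function() generate_design(4, 4, seed = 11)

test_that("the count filter keeps genes with one fully covered group", {
  d <- make_design()
  cells <- rootzone:::cell_index(d)
  m <- matrix(0L, 3, 32)
  m[1, cells == 1] <- 5L                      # (5,5,5,5) in one group
  m[2, ] <- 4L; m[2, cells == 2] <- c(5L, 5L, 5L, 4L)  # never all >= 5
  m[3, ] <- 50L
  keep <- filter_low_counts(m, d, min_count = 5)
  expect_identical(keep, c(TRUE, FALSE, TRUE))
})

test_that("the filter matches a per-group brute-force minimum check", {
  d <- make_design()
  cells <- rootzone:::cell_index(d)
  set.seed(6)
  m <- matrix(rpois(6 * 32, 5), 6, 32)
  keep <- filter_low_counts(m, d, min_count = 5)
  brute <- logical(6)
  for (g in 1:6) {
    ok <- FALSE
    for (k in 1:8) if (min(m[g, cells == k]) >= 5) ok <- TRUE
    brute[g] <- ok
  }
  expect_identical(keep, brute)
})

test_that("precision weights are positive, finite, and flat when data are", {
  d <- make_design()
  set.seed(7)
  # dominant dispersion at high counts: log-scale variance is constant
  m <- matrix(rnbinom(2000 * 32, size = 50,
                      mu = exp(rnorm(2000, log(2e4), 0.15))), 2000, 32)
  ew <- transform_and_weight(m, d)
  expect_true(all(is.finite(ew$weights) & ew$weights > 0))
  # away from the span edges the trend is flat: weights within 10%
  x <- rowMeans(ew$logged)
  interior <- x > quantile(x, 0.05) & x < quantile(x, 0.95)
  w_int <- rowMeans(ew$weights)[interior]
  expect_lt(diff(range(w_int)) / mean(w_int), 0.1)
})

test_that("weights decrease toward low counts for NB data", {
  s <- cached_sim("de_clean",
                  sim_config(n_genes = 1500, seed = 52, fraction_inactive = 0,
                             fraction_de = 0))
  keep <- filter_low_counts(s$sim$counts, s$sim$design)
  ew <- transform_and_weight(s$sim$counts[keep, ], s$sim$design,
                             lib_eff = s$norm$lib_eff)
  expect_true(all(is.finite(ew$weights) & ew$weights > 0))
  # NB mean-variance: lower expression means larger log-scale variance,
  # hence smaller weight
  avg_expr <- rowMeans(ew$logged)
  avg_w <- rowMeans(ew$weights)
  expect_gt(cor(avg_expr, avg_w, method = "spearman"), 0.5)
})

test_that("block correlation recovers null and planted lane variance", {
  d <- make_design()
  cells <- rootzone:::cell_index(d)
  lane_idx <- match(d$lane, unique(d$lane))
  set.seed(8)
  base <- matrix(rnorm(2000 * 32), 2000, 32) +
    matrix(rnorm(2000 * 8), 2000, 8)[, cells]
  # no lane effect: rho near 0
  expect_lt(abs(estimate_block_correlation(base, d)), 0.05)
  # lane variance equal to residual variance: rho near 0.5
  lane_fx <- matrix(rnorm(2000 * 8), 2000, 8)
  withlane <- base + lane_fx[, lane_idx]
  rho <- estimate_block_correlation(withlane, d)
  expect_lt(abs(rho - 0.5), 0.1)
  # invariance to lane relabelling
  d2 <- d
  d2$lane <- factor(d2$lane, labels = sample(LETTERS[1:8]))
  expect_equal(estimate_block_correlation(withlane, d2), rho,
               tolerance = 1e-12)
})

test_that("single-lane designs warn and return zero correlation", {
  d <- generate_design(1, 8, seed = 2)
  m <- matrix(rnorm(100 * 8), 100, 8)
  expect_warning(rho <- estimate_block_correlation(m, d), "single lane")
  expect_equal(rho, 0)
})

test_that("contrasts are exact on noise-free means and reduce to OLS", {
  d <- make_design()
  cells <- rootzone:::cell_index(d)
  means <- matrix(c(1, 2, 3, 4, 2.5, 2, 5, 4), 1, 8)  # lfc 1.5, 0, 2, 0
  Y <- means[, cells, drop = FALSE]
  rownames(Y) <- "g1"
  expr <- structure(list(logged = Y, weights = matrix(1, 1, 32), design = d,
                         lib_eff = rep(1e6, 32)), class = "expression_matrix")
  fit <- fit_contrasts(expr, rho = 0)
  expect_equal(unname(fit$coefficients[1, ]), c(1.5, 0, 2, 0),
               tolerance = 1e-10)

  # equal weights + rho 0: estimates equal OLS cell-mean differences and the
  # unmoderated statistic equals the lm t statistic
  set.seed(9)
  Y2 <- matrix(rnorm(150 * 32, sd = 0.7), 150, 32,
               dimnames = list(sprintf("g%03d", 1:150), d$sample_id))
  expr2 <- structure(list(logged = Y2, weights = matrix(1, 150, 32),
                          design = d, lib_eff = rep(1e6, 32)),
                     class = "expression_matrix")
  fit2 <- fit_contrasts(expr2, rho = 0)
  res2 <- moderate_and_test(fit2, d0 = 0)
  i <- 42
  lmfit <- lm(Y2[i, ] ~ 0 + factor(cells))
  ct <- coef(lmfit)[5] - coef(lmfit)[1]
  se <- sqrt(sum(vcov(lmfit)[c(1, 5), c(1, 5)] * c(1, -1, -1, 1)))
  expect_equal(res2$moderated_stat[res2$gene_id == rownames(Y2)[i] &
                                     res2$tissue == "Mz"],
               unname(ct / se), tolerance = 1e-10)
  expect_equal(unname(fit2$coefficients[i, 1]), unname(ct),
               tolerance = 1e-10)
})

test_that("planted effects are estimated without bias", {
  # bias is an expectation: averaged over independent experiments so that
  # shared per-experiment normalization noise (a handful of samples) is not
  # mistaken for estimator bias; restricted to the high-count regime where
  # the log2(count + 0.5) transform is accurate
  ests <- c()
  for (sd_ in c(51, 52, 53)) {
    cfg <- sim_config(n_genes = 2000, seed = sd_, fraction_inactive = 0,
                      fraction_de = 0.15, de_log2fc = 2)
    sim <- simulate_experiment(cfg)
    norm <- normalize_counts(sim$counts, sim$gene_covariates,
                             lib_sizes = sim$lib_sizes)
    de <- de_analysis(sim$counts, sim$design, lib_eff = norm$lib_eff)
    planted <- sim$params$planted_log2fc[de$kept, , drop = FALSE]
    beta <- sim$params$beta[de$kept, , drop = FALSE]
    kept_ids <- rownames(sim$counts)[de$kept]
    res <- de$results
    for (t in 1:4) {
      tt <- c("Mz", "Ez", "Co", "St")[t]
      hit <- which(abs(planted[, t]) == 2 &
                     pmin(beta[, t], beta[, t + 4]) > log(64))
      est <- res$log2fc[match(paste(kept_ids[hit], tt),
                              paste(res$gene_id, res$tissue))]
      ests <- c(ests, est * sign(planted[hit, t]))
    }
  }
  expect_gt(length(ests), 50)
  expect_lt(abs(mean(ests) - 2), 0.05)
})

test_that("variance moderation has the documented limits and matches limma", {
  d <- make_design()
  set.seed(10)
  Y <- matrix(rnorm(500 * 32, sd = rep(sqrt(rchisq(500, 8) / 8), 32)), 500, 32)
  rownames(Y) <- sprintf("g%03d", 1:500)
  expr <- structure(list(logged = Y, weights = matrix(1, 500, 32), design = d,
                         lib_eff = rep(1e6, 32)), class = "expression_matrix")
  fit <- fit_contrasts(expr, rho = 0)

  res0 <- moderate_and_test(fit, d0 = 0)
  tt_plain <- fit$coefficients / (fit$stdev_unscaled *
                                    sqrt(matrix(fit$sigma2, 500, 4)))
  expect_equal(res0$moderated_stat, as.vector(tt_plain), tolerance = 1e-12)

  resInf <- moderate_and_test(fit, d0 = Inf, s02 = 1.3)
  ttInf <- fit$coefficients / (fit$stdev_unscaled * sqrt(1.3))
  expect_equal(resInf$moderated_stat, as.vector(ttInf), tolerance = 1e-12)

  skip_if_not_installed("limma")
  own <- rootzone:::fit_variance_prior(fit$sigma2, fit$df[1])
  sq <- limma::squeezeVar(fit$sigma2, df = fit$df[1])
  expect_equal(own$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(own$s02, sq$var.prior, tolerance = 0.05)
})

test_that("BH adjustment matches a step-up loop oracle", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    prev <- 1
    for (i in n:1) {
      prev <- min(prev, p[o[i]] * n / i)
      q[o[i]] <- prev
    }
    q
  }
  expect_equal(adjust_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(12)
  for (n in c(10, 1000, 10000)) {
    p <- runif(n)^2
    q <- adjust_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(q >= p))
  }
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("responsive-gene selection summarises overlap and direction", {
  # construct results with known multi-tissue direction consistency
  gid <- sprintf("g%03d", 1:500)
  res <- expand.grid(gene_id = gid, tissue = c("Mz", "Ez", "Co", "St"),
                     stringsAsFactors = FALSE)
  res$log2fc <- 0; res$q_value <- 1
  # 414 genes responsive in Mz and Ez; 407 share sign, 7 conflict
  two <- gid[1:414]
  idx_mz <- match(paste(two, "Mz"), paste(res$gene_id, res$tissue))
  idx_ez <- match(paste(two, "Ez"), paste(res$gene_id, res$tissue))
  res$q_value[c(idx_mz, idx_ez)] <- 0.001
  res$log2fc[idx_mz] <- 2
  res$log2fc[idx_ez] <- c(rep(2, 407), rep(-2, 7))
  res$p_value <- res$q_value
  sel <- select_responsive(res, fdr_cut = 0.01, lfc_cut = 1)
  expect_equal(sel$n_multi_tissue, 414L)
  expect_equal(sel$n_consistent, 407L)
  expect_equal(round(100 * sel$consistency), 98)
  # lfc_cut 0: selection by q alone
  sel0 <- select_responsive(res, fdr_cut = 0.01, lfc_cut = 0)
  expect_equal(sel0$per_tissue$n[1], 414L)
})
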