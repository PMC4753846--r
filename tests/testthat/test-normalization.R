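# Brute-force TMM reimplementation with explicit loops, used as the exact
# oracle for tmm_factors.
tmm_bruteforce <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  q75 <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    q75[j] <- quantile(counts[, j], 0.75) / lib[j]
  ref <- which.min(abs(q75 - mean(q75)))
  f <- rep(1, ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) next
    m <- a <- w <- c()
    for (g in seq_len(nrow(counts))) {
      yo <- counts[g, j]; yr <- counts[g, ref]
      if (yo > 0 && yr > 0) {
        po <- yo / lib[j]; pr <- yr / lib[ref]
        m <- c(m, log2(po / pr))
        a <- c(a, 0.5 * log2(po * pr))
        w <- c(w, (lib[j] - yo) / (lib[j] * yo) +
                 (lib[ref] - yr) / (lib[ref] * yr))
      }
    }
    if (!length(m) || max(abs(m)) < 1e-6) next
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    rm_ <- rank(m, ties.method = "first")
    ra_ <- rank(a, ties.method = "first")
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    if (!any(keep)) next
    f[j] <- 2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f
}

test_that("TMM factors are 1 for identical samples and scale invariant", {
  m <- matrix(rpois(400, 40), 100, 4)
  m[, 2] <- m[, 1]
  f <- tmm_factors(m)
  expect_equal(unname(f[2] / f[1]), 1, tolerance = 1e-12)
  m2 <- m
  m2[, 3] <- m2[, 3] * 10L
  f2 <- tmm_factors(m2, ref = 1)
  f1 <- tmm_factors(m, ref = 1)
  # proportions are invariant; only the precision weights feel the depth
  expect_equal(unname(f2[3]), unname(f1[3]), tolerance = 0.01)
})

test_that("TMM matches the explicit-loop oracle exactly on random matrices", {
  set.seed(21)
  for (i in 1:5) {
    g <- sample(5:50, 1); n <- sample(2:6, 1)
    m <- matrix(rnbinom(g * n, size = 3, mu = exp(rnorm(g, 3, 1.2))), g, n)
    m[sample(length(m), round(length(m) * 0.1))] <- 0L
    if (any(colSums(m) == 0)) next
    expect_equal(unname(tmm_factors(m)), tmm_bruteforce(m), tolerance = 1e-12)
  }
})

test_that("TMM agrees with the established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(22)
  m <- matrix(rnbinom(300 * 6, size = 5, mu = exp(rnorm(300, 4, 1.5))), 300, 6)
  mine <- tmm_factors(m)
  mine <- mine / exp(mean(log(mine)))   # edgeR centres at geometric mean 1
  ref <- edgeR::calcNormFactors(edgeR::DGEList(counts = m))$samples$norm.factors
  # conventions agree; tie handling at trim boundaries may differ slightly
  expect_equal(unname(mine), ref, tolerance = 0.005)
})

test_that("an all-zero sample is reported by name", {
  m <- matrix(rpois(60, 10), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  m[, 2] <- 0L
  expect_error(tmm_factors(m), "b")
})

test_that("the covariate smoother is flat under a null covariate effect", {
  s <- cached_sim("norm_null",
                  sim_config(n_genes = 2000, seed = 31, length_slope = 0,
                             gc_lin = 0, gc_quad = 0, fraction_inactive = 0,
                             fraction_de = 0))
  sm <- s$norm$smoother
  # fitted covariate slopes are indistinguishable from zero against the
  # population spread of log counts (slope 1 is planted in the paired test)
  ll <- log(s$sim$gene_covariates$length_bp)
  gc <- s$sim$gene_covariates$gc_fraction
  y <- log(rowMeans(s$sim$counts) + 0.5)
  noise_ll <- 3 * summary(lm(y ~ ll))$coefficients[2, 2]
  noise_gc <- 3 * summary(lm(y ~ gc))$coefficients[2, 2]
  expect_lt(abs(coef(lm(sm$fitted ~ ll))[2]), noise_ll)
  expect_lt(abs(coef(lm(sm$fitted ~ gc))[2]), noise_gc)
})

test_that("a known log-linear length effect is recovered", {
  s <- cached_sim("norm_slope",
                  sim_config(n_genes = 5000, seed = 32, length_slope = 1,
                             gc_lin = 0, gc_quad = 0, fraction_inactive = 0,
                             fraction_de = 0))
  sm <- s$norm$smoother
  ll <- log(s$sim$gene_covariates$length_bp)
  slope <- coef(lm(sm$fitted ~ ll))[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("smoother fitted values are invariant to gene order", {
  s <- default_sim()
  perm <- sample(nrow(s$sim$counts))
  sm1 <- fit_covariate_smoother(s$sim$counts, s$sim$gene_covariates)
  sm2 <- fit_covariate_smoother(s$sim$counts[perm, ],
                                s$sim$gene_covariates[perm, ])
  expect_equal(sm2$fitted, sm1$fitted[perm], tolerance = 1e-8)
})

test_that("degenerate covariates are rejected", {
  m <- matrix(rpois(300, 20), 100, 3)
  cov <- data.frame(gene_id = sprintf("g%d", 1:100), length_bp = 1000L,
                    gc_fraction = 0.5)
  expect_error(fit_covariate_smoother(m, cov), "degenerate")
})

test_that("offsets compose additively and respond to library size", {
  s <- default_sim()
  n1 <- s$norm
  # doubling one library shifts that sample's offset column by log 2
  lib2 <- s$sim$lib_sizes
  lib2[3] <- lib2[3] * 2
  n2 <- compose_offsets(n1$tmm_factors, n1$smoother, lib2)
  shift <- n2$offsets[, 3] - n1$offsets[, 3]
  # relative to geometric-mean recentring: log 2 minus log(2)/n_samples
  expected <- log(2) - log(2) / length(lib2)
  expect_equal(unname(shift), rep(expected, nrow(n1$offsets)),
               tolerance = 1e-10)
  # flat smoother + unit factors + equal libraries => constant offsets
  smf <- n1$smoother
  smf$fitted <- rep(2, nrow(n1$offsets))
  nflat <- compose_offsets(rep(1, 32), smf, rep(1e6, 32))
  expect_true(all(abs(nflat$offsets - 2) < 1e-12))
})

test_that("estimated offsets track the generating offsets", {
  s <- cached_sim("norm_recov",
                  sim_config(n_genes = 5000, seed = 33, fraction_inactive = 0,
                             fraction_de = 0))
  expect_gt(cor(as.vector(s$norm$offsets), as.vector(s$sim$offsets_true)),
            0.99)
})

test_that("offset translation leaves the NB likelihood unchanged", {
  # adding c to offsets and subtracting c from the fixed effect is a no-op
  y <- c(3, 7, 5, 6)
  off <- rep(0.4, 4)
  k <- 10
  ll1 <- rootzone:::nb_loglik(y, exp(off + 1.2), k)
  ll2 <- rootzone:::nb_loglik(y, exp((off + 0.7) + (1.2 - 0.7)), k)
  expect_equal(ll1, ll2, tolerance = 1e-12)
})
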