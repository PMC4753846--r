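test_that("zero-variance populations collapse to their means", {
  cfg <- sim_config(n_genes = 50, beta_var = rep(0, 8), log_disp_var = 0,
                    fraction_inactive = 0, fraction_de = 0, seed = 1)
  p <- draw_gene_params(cfg)
  expect_true(all(abs(sweep(p$beta, 2L, cfg$beta_mean)) < 1e-12))
  expect_true(all(p$log_dispersion == cfg$log_disp_mean))
})

test_that("forcing every cell inactive yields all-false truth", {
  cfg <- sim_config(n_genes = 40, fraction_inactive = 1,
                    inactive_cell_prob = 1, fraction_de = 0, seed = 2)
  p <- draw_gene_params(cfg)
  expect_false(any(p$truly_active))
})

test_that("drawn parameters match configured moments (Monte Carlo)", {
  cfg <- sim_config(n_genes = 10000, fraction_inactive = 0, fraction_de = 0,
                    beta_mean = c(1, 2, 3, 0.5, 1.2, 2.2, 3.2, 0.7),
                    beta_var = rep(1.5, 8), seed = 3)
  p <- draw_gene_params(cfg)
  se_mean <- sqrt(1.5 / 10000)
  for (k in 1:8)
    expect_lt(abs(mean(p$beta[, k]) - cfg$beta_mean[k]), 3 * se_mean)
  # control cells are free draws; deficit cells are tied to them
  se_var <- 1.5 * sqrt(2 / 9999)
  for (k in 1:4)
    expect_lt(abs(var(p$beta[, k]) - 1.5), 3 * se_var)
  expect_equal(p$planted_log2fc,
               (p$beta[, 5:8] - p$beta[, 1:4] -
                  rep(cfg$beta_mean[5:8] - cfg$beta_mean[1:4],
                      each = nrow(p$beta))) / log(2),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("count simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 60, seed = 4)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$lib_sizes, s2$lib_sizes)
})

test_that("an effectively silenced gene produces all-zero counts", {
  cfg <- sim_config(n_genes = 10, seed = 5, fraction_inactive = 0)
  p <- draw_gene_params(cfg)
  p$beta[1, ] <- -30
  d <- generate_design(cfg$n_replicates, cfg$libraries_per_lane, seed = 5)
  s <- simulate_counts(p, d)
  expect_true(all(s$counts[1, ] == 0))
})

test_that("per-cell moments approach the negative-binomial limits", {
  # near-zero dispersion and silenced random effects: Poisson var/mean -> 1
  cfg <- sim_config(n_genes = 1, n_replicates = 1250, libraries_per_lane = 8,
                    beta_mean = rep(3, 8), beta_var = rep(0, 8),
                    log_disp_mean = -20, log_disp_var = 0,
                    replicate_precision_shape = 1e8,
                    replicate_precision_rate = 1,
                    lane_precision_shape = 1e8, lane_precision_rate = 1,
                    library_size_sdlog = 0, fraction_inactive = 0,
                    fraction_de = 0, seed = 6)
  s <- simulate_experiment(cfg)
  cells <- rootzone:::cell_index(s$design)
  for (k in 1:8) {
    y <- s$counts[1, cells == k]
    expect_lt(abs(var(y) / mean(y) - 1), 0.15)
    # empirical mean converges to exp(offset + beta), within 5%
    mu <- exp(s$offsets_true[1, cells == k][1] + 3)
    expect_lt(abs(mean(y) / mu - 1), 0.05)
  }
})

test_that("the gamma-precision lane hierarchy is recoverable by moments", {
  cfg <- sim_config(n_genes = 1, seed = 9)
  vars <- vapply(1:200, function(i) {
    c2 <- cfg; c2$seed <- 1000L + i
    var(simulate_experiment(c2)$lane_effects)
  }, numeric(1))
  # E[var(lane effects)] = E[1/tau] = rate / (shape - 1)
  target <- cfg$lane_precision_rate / (cfg$lane_precision_shape - 1)
  se <- sd(vars) / sqrt(length(vars))
  expect_lt(abs(mean(vars) - target), 3 * se + 1e-6)
})

test_that("fixtures round-trip losslessly through the readers", {
  cfg <- sim_config(n_genes = 40, seed = 8)
  s <- simulate_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(s, dir)
  counts2 <- read_counts(paths[["counts"]])
  expect_identical(unname(counts2), unname(s$counts))
  expect_identical(rownames(counts2), rownames(s$counts))
  d2 <- read_design(paths[["design"]])
  expect_equal(as.character(d2$lane), as.character(s$design$lane))
  cov2 <- read_covariates(paths[["covariates"]])
  expect_equal(cov2$length_bp, s$gene_covariates$length_bp)
  truth <- utils::read.delim(paths[["truth"]], comment.char = "#")
  expect_equal(nrow(truth), cfg$n_genes)
  expect_true(all(c("gene_id", "active_Mz_control", "log2fc_St") %in%
                    names(truth)))
})
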