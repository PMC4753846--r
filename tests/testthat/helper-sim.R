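# Shared small simulations, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, config) {
  if (is.null(.sim_cache[[key]])) {
    sim <- simulate_experiment(config)
    norm <- normalize_counts(sim$counts, sim$gene_covariates,
                             lib_sizes = sim$lib_sizes)
    .sim_cache[[key]] <- list(sim = sim, norm = norm, config = config)
  }
  .sim_cache[[key]]
}

# Default mid-size experiment reused across modules.
default_sim <- function() {
  cached_sim("default", sim_config(n_genes = 800, seed = 101))
}

cached_hyper <- function() {
  if (is.null(.sim_cache$hyper_default)) {
    s <- default_sim()
    .sim_cache$hyper_default <-
      estimate_hyperparameters(s$sim$counts, s$sim$design, s$norm)
  }
  .sim_cache$hyper_default
}

# A hyperparameter object with no random-effect mass, for oracle tests on
# instances without lanes or replicates.
flat_hyper <- function(beta_mean = rep(1, 8), beta_var = rep(2, 8),
                       log_disp_mean = log(0.1), log_disp_var = 0.25) {
  structure(list(beta_mean = beta_mean, beta_var = beta_var,
                 log_disp_mean = log_disp_mean, log_disp_var = log_disp_var,
                 replicate_precision_shape = 1e6,
                 replicate_precision_rate = 1,
                 lane_precision_shape = 0.01, lane_precision_rate = 0.01,
                 lane_precision_est = 1e8),
            class = "nb_hyper")
}

# Independent dense-grid oracle for a single-cell NB-likelihood x normal
# prior posterior: exact upper-tail mass above T.
quadrature_tail <- function(y, off, phi, m0, v0, T) {
  bg <- seq(m0 - 8 * sqrt(v0) - 6, m0 + 8 * sqrt(v0) + 6, length.out = 6001)
  ll <- vapply(bg, function(b)
    sum(dnbinom(y, size = 1 / phi, mu = exp(off + b), log = TRUE)),
    numeric(1)) + dnorm(bg, m0, sqrt(v0), log = TRUE)
  w <- exp(ll - max(ll)); w <- w / sum(w)
  sum(w[bg > T])
}
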