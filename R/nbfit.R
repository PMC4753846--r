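# Vectorized per-gene negative-binomial cell-means fits.
#
# The activity model's empirical-Bayes step needs, for every gene, maximum
# likelihood estimates of the 8 tissue x treatment fixed effects and of the
# log dispersion, all conditional on known offsets. The cell-means layout
# makes the fixed-effect updates separable by cell, so the whole gene set is
# fit simultaneously with matrix Newton steps alternating between the cell
# means (given dispersion) and the log dispersion (given cell means).

# counts, offsets: genes x samples; cells: integer 1..n_cells per sample.
# Returns beta (genes x n_cells), se_beta, log_phi, se_log_phi (phi is the NB
# dispersion in Var = mu + phi mu^2).
fit_nb_cellmeans <- function(counts, cells, offsets, n_cells = 8L,
                             max_iter = 40L, phi_init = 0.1,
                             logk_bounds = c(-7, 12)) {
  counts <- as.matrix(counts)
  g <- nrow(counts); n <- ncol(counts)
  if (length(cells) != n) stop("cells length must match sample count")
  Z <- matrix(0, n, n_cells)
  Z[cbind(seq_len(n), cells)] <- 1

  eoff <- exp(offsets)
  beta <- log((counts %*% Z + 0.5) / (eoff %*% Z))
  beta <- pmin(pmax(beta, -15), 15)
  logk <- rep(log(1 / phi_init), g)

  info <- NULL
  for (iter in seq_len(max_iter)) {
    k <- exp(logk)
    # two cell-mean Newton sweeps per outer iteration
    for (sweep in 1:2) {
      mu <- eoff * exp(beta[, cells, drop = FALSE])
      r <- counts - (counts + k) * mu / (k + mu)
      W <- (counts + k) * k * mu / (k + mu)^2
      score <- r %*% Z
      info <- W %*% Z
      step <- score / pmax(info, 1e-10)
      step <- pmin(pmax(step, -3), 3)
      beta <- pmin(pmax(beta + step, -15), 15)
    }
    mu <- eoff * exp(beta[, cells, drop = FALSE])
    gr <- nb_grad_logk_adj(counts, mu, logk, Z)
    h <- 1e-4
    gr2 <- nb_grad_logk_adj(counts, mu, logk + h, Z)
    curv <- (gr2 - gr) / h
    dstep <- gr / pmax(-curv, 1e-8)
    dstep <- pmin(pmax(dstep, -1), 1)
    logk <- pmin(pmax(logk + dstep, logk_bounds[1]), logk_bounds[2])
    if (max(abs(dstep)) < 1e-9 && max(abs(step)) < 1e-9) break
  }
  mu <- eoff * exp(beta[, cells, drop = FALSE])
  gr <- nb_grad_logk_adj(counts, mu, logk, Z)
  curv <- (nb_grad_logk_adj(counts, mu, logk + 1e-4, Z) - gr) / 1e-4

  list(beta = beta,
       se_beta = 1 / sqrt(pmax(info, 1e-10)),
       log_phi = -logk,
       se_log_phi = 1 / sqrt(pmax(-curv, 1e-8)),
       mu = mu)
}

# Gradient of the NB log likelihood with respect to log k (k = 1/dispersion),
# summed over samples, one value per gene.
nb_grad_logk <- function(counts, mu, logk) {
  k <- exp(logk)
  s <- rowSums(digamma(counts + k) - digamma(k) + log(k) + 1 -
                 log(k + mu) - (counts + k) / (k + mu))
  k * s
}

# Cox-Reid adjusted gradient: profile gradient plus the derivative of
# -0.5 * sum_cells log I_cell(beta_hat), removing the downward bias of the
# dispersion MLE caused by estimating the 8 cell means. The adjustment term
# is differentiated numerically on the log k scale.
nb_grad_logk_adj <- function(counts, mu, logk, Z) {
  h <- 1e-3
  cr <- function(lk) {
    k <- exp(lk)
    W <- (counts + k) * k * mu / (k + mu)^2
    -0.5 * rowSums(log(pmax(W %*% Z, 1e-12)))
  }
  nb_grad_logk(counts, mu, logk) + (cr(logk + h) - cr(logk - h)) / (2 * h)
}

# NB log likelihood (up to data-only constants) for a vector of observations.
nb_loglik <- function(y, mu, k) {
  sum(lgamma(y + k) - lgamma(k) + k * log(k) + y * log(mu) -
        (y + k) * log(k + mu))
}

# Cox-Reid adjusted profile log likelihood of the log dispersion on a grid,
# for every gene at once: at each grid value the cell means are re-maximised
# by vectorized Newton and the adjusted profile value recorded. Rows = genes,
# columns = grid points.
nb_profile_logphi <- function(counts, cells, offsets, grid, n_cells = 8L,
                              inner_iter = 8L) {
  counts <- as.matrix(counts)
  g <- nrow(counts); n <- ncol(counts)
  Z <- matrix(0, n, n_cells)
  Z[cbind(seq_len(n), cells)] <- 1
  eoff <- exp(offsets)
  beta <- log((counts %*% Z + 0.5) / (eoff %*% Z))
  beta <- pmin(pmax(beta, -15), 15)
  pll <- matrix(NA_real_, g, length(grid))
  for (j in seq_along(grid)) {
    k <- exp(-grid[j])
    for (it in seq_len(inner_iter)) {
      mu <- eoff * exp(beta[, cells, drop = FALSE])
      r <- counts - (counts + k) * mu / (k + mu)
      W <- (counts + k) * k * mu / (k + mu)^2
      info <- W %*% Z
      step <- (r %*% Z) / pmax(info, 1e-10)
      step <- pmin(pmax(step, -3), 3)
      beta <- pmin(pmax(beta + step, -15), 15)
      if (max(abs(step)) < 1e-8) break
    }
    mu <- eoff * exp(beta[, cells, drop = FALSE])
    W <- (counts + k) * k * mu / (k + mu)^2
    ll <- rowSums(lgamma(counts + k) - lgamma(k) + k * log(k) +
                    counts * log(mu) - (counts + k) * log(k + mu))
    pll[, j] <- ll - 0.5 * rowSums(log(pmax(W %*% Z, 1e-12)))
  }
  pll
}

# Empirical-Bayes fit of the normal population of log dispersions: maximises
# the sum over genes of log integral N(x; m, V) * exp(profile_g(x)) dx on the
# grid. Returns the population mean and variance.
fit_logphi_population <- function(pll, grid) {
  pll <- pll - apply(pll, 1L, max)
  dg <- c(diff(grid)[1], diff(grid))
  nll <- function(par) {
    m <- par[1]; V <- exp(par[2])
    w <- stats::dnorm(grid, m, sqrt(V)) * dg
    lw <- log(pmax(w, 1e-300))
    mix <- exp(sweep(pll, 2L, lw, `+`))
    -sum(log(pmax(rowSums(mix), 1e-300)))
  }
  start <- c(grid[which.max(colSums(pll))], log(0.5))
  opt <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  list(mean = opt$par[1], var = exp(opt$par[2]))
}
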