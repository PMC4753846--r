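#' Estimate the hyperparameters of the hierarchical activity model
#'
#' Empirical-Bayes estimation of the population distributions the activity
#' model conditions on: per-gene maximum-likelihood fits of the 8
#' tissue-by-treatment fixed effects and the log negative-binomial dispersion
#' (given normalization offsets) are pooled across genes by method of moments
#' with a sampling-variance correction, yielding the mean and variance of the
#' fixed-effect population per cell and of the log-dispersion population. The
#' gamma hyperprior of the per-gene biological-replicate precision is fit by
#' moments on per-gene variance components; the lane-effect precision prior
#' stays at its configured vague values, while a cross-gene empirical
#' estimate of the realized lane precision is also returned for plug-in use.
#'
#' @param counts Count matrix, genes x samples (at least 500 genes).
#' @param design Design table (see [generate_design()]).
#' @param offsets A \code{norm_offsets} object or a genes x samples offset
#'   matrix on the natural-log scale.
#' @param lane_prior Length-2 gamma (shape, rate) of the vague lane prior.
#' @return A list of class \code{nb_hyper} with elements \code{beta_mean},
#'   \code{beta_var} (length 8), \code{log_disp_mean}, \code{log_disp_var},
#'   \code{replicate_precision_shape}, \code{replicate_precision_rate},
#'   \code{lane_precision_shape}, \code{lane_precision_rate},
#'   \code{lane_precision_est}, \code{n_genes_used}, \code{n_dropped}.
#' @export
estimate_hyperparameters <- function(counts, design, offsets,
                                     lane_prior = c(0.01, 0.01)) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 500L)
    stop("need at least 500 genes for stable hyperparameter estimation")
  validate_design(design)
  off <- offset_matrix(offsets, counts)
  cells <- cell_index(design)

  # Realized lane effects are shared by all genes, hence estimable almost
  # exactly by cross-gene averaging of cell-centred log residuals; absorb
  # them into the offsets so they do not contaminate the per-gene fits.
  lane_fx <- estimate_lane_effects(counts, off, cells, design)
  off_adj <- off + matrix(lane_fx$per_sample, nrow(counts), ncol(counts),
                          byrow = TRUE)

  fit <- fit_nb_cellmeans(counts, cells, off_adj)
  ok <- apply(is.finite(fit$beta), 1L, all) & is.finite(fit$log_phi)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("dropping ", n_dropped, " gene(s) with non-finite fits")
  beta <- fit$beta[ok, , drop = FALSE]
  se2 <- fit$se_beta[ok, , drop = FALSE]^2

  beta_mean <- beta_var <- numeric(8L)
  for (k in 1:8) {
    mm <- normal_noise_moments(beta[, k], se2[, k])
    beta_mean[k] <- mm$mean
    beta_var[k] <- max(mm$var, 1e-6)
  }
  vc <- replicate_variance_components(counts[ok, , drop = FALSE],
                                      fit$mu[ok, , drop = FALSE], design)
  rep_gamma <- fit_invgamma_moments(vc$sigma2_rep, vc$noise_var)
  rep_var_mean <- rep_gamma$rate / (rep_gamma$shape - 1)

  grid <- seq(-7, 3, by = 0.25)
  pll <- nb_profile_logphi(counts[ok, , drop = FALSE], cells,
                           off_adj[ok, , drop = FALSE], grid)
  mmd <- fit_logphi_population(pll, grid)
  # the per-gene replicate effect inflates the apparent dispersion by about
  # its variance; map the fitted population back to the clean scale
  mmd <- decontaminate_logdisp(mmd$mean, mmd$var, rep_var_mean)
  log_disp_mean <- mmd$mean
  log_disp_var <- max(mmd$var, 1e-6)

  hyper <- list(beta_mean = beta_mean,
                beta_var = beta_var,
                log_disp_mean = log_disp_mean,
                log_disp_var = log_disp_var,
                replicate_precision_shape = rep_gamma$shape,
                replicate_precision_rate = rep_gamma$rate,
                lane_precision_shape = lane_prior[1],
                lane_precision_rate = lane_prior[2],
                lane_precision_est = lane_fx$precision,
                lane_effects_est = lane_fx$per_lane,
                n_genes_used = sum(ok),
                n_dropped = n_dropped)
  class(hyper) <- "nb_hyper"
  hyper
}

# Cross-gene estimate of the realized (shared) lane effects: cell-centred
# log residuals averaged over genes isolate per-sample effects common to all
# genes; their lane means, centred, estimate the lane effects, and the
# variance of those means supplies a plug-in lane precision.
estimate_lane_effects <- function(counts, off, cells, design) {
  z <- log(counts + 0.5) - off
  Zc <- matrix(0, ncol(counts), 8L)
  Zc[cbind(seq_len(ncol(counts)), cells)] <- 1
  cm <- (z %*% Zc) %*% diag(1 / colSums(Zc))
  zc <- z - cm[, cells, drop = FALSE]
  delta <- colMeans(zc)
  lanes <- unique(design$lane)
  if (length(lanes) < 2L) {
    per_lane <- stats::setNames(rep(0, length(lanes)), lanes)
    return(list(per_lane = per_lane,
                per_sample = rep(0, ncol(counts)), precision = 1e6))
  }
  u <- tapply(delta, factor(design$lane, levels = lanes), mean)
  u <- u - mean(u)
  list(per_lane = u,
       per_sample = as.numeric(u[match(design$lane, lanes)]),
       precision = 1 / max(stats::var(as.numeric(u)), 1e-6))
}

# Invert the additive dispersion contamination by the replicate-effect
# variance: the apparent dispersion is approximately phi + s, so find the
# normal population of log(phi) whose forward image under
# x -> log(exp(x) + s) matches the fitted (mean, var), by Gauss-Hermite
# moment matching.
decontaminate_logdisp <- function(m_prime, v_prime, s) {
  if (s <= 0) return(list(mean = m_prime, var = v_prime))
  gh_n <- 21L
  gh <- list(nodes = NULL, weights = NULL)
  # Hermite nodes via eigenvalues of the Jacobi matrix
  i <- seq_len(gh_n - 1L)
  J <- diag(0, gh_n)
  J[cbind(i, i + 1L)] <- J[cbind(i + 1L, i)] <- sqrt(i / 2)
  ev <- eigen(J, symmetric = TRUE)
  gh$nodes <- ev$values
  gh$weights <- ev$vectors[1L, ]^2
  fwd <- function(m, v) {
    x <- m + sqrt(2 * max(v, 1e-10)) * gh$nodes
    y <- log(exp(x) + s)
    mu <- sum(gh$weights * y)
    c(mu, sum(gh$weights * (y - mu)^2))
  }
  obj <- function(par) {
    f <- fwd(par[1], exp(par[2]))
    (f[1] - m_prime)^2 + (sqrt(f[2]) - sqrt(v_prime))^2
  }
  opt <- stats::optim(c(log(max(exp(m_prime) - s, 1e-4)),
                        log(max(v_prime, 1e-4))), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  list(mean = opt$par[1], var = exp(opt$par[2]))
}

# Variance components of the replicate and lane random effects from
# log-scale residuals against the fitted cell means. Estimation is
# restricted to well-measured genes (every cell's mean count >= 5), where
# the log-linear approximation of the NB model is accurate; the replicate
# precision's population is gene-independent, so the subset is unbiased.
replicate_variance_components <- function(counts, mu_hat, design,
                                          min_cell_mean = 5, min_genes = 100L) {
  cells <- cell_index(design)
  Zc <- matrix(0, ncol(counts), 8L)
  Zc[cbind(seq_len(ncol(counts)), cells)] <- 1
  cell_means <- (counts %*% Zc) %*% diag(1 / colSums(Zc))
  minc <- apply(cell_means, 1L, min)
  sel <- minc >= min_cell_mean
  if (sum(sel) < min_genes)
    sel <- rank(-minc, ties.method = "first") <= min(min_genes, nrow(counts))

  z <- log(counts[sel, , drop = FALSE] + 0.5) -
    log(mu_hat[sel, , drop = FALSE] + 0.5)

  reps <- sort(unique(design$replicate))
  if (length(reps) > 1L) {
    er <- ems_components(z, design, design$replicate)
    sigma2_rep <- er$sigma_f
    lam <- er$t1 / max(er$r1, 1)
    s_e <- pmax(er$sigma_e, 1e-8)
    noise <- (2 * (s_e + lam * pmax(sigma2_rep, 0))^2 / max(er$r1, 1) +
                2 * s_e^2 / max(er$r2, 1)) / lam^2
  } else {
    sigma2_rep <- rep(0, nrow(z)); noise <- rep(1e-4, nrow(z))
  }

  list(sigma2_rep = sigma2_rep, noise_var = noise, n_genes_re = nrow(z))
}

# Fit an inverse-gamma law to noisy per-gene variance estimates by moments,
# subtracting the average sampling noise from the observed spread. Returns
# the gamma (shape, rate) of the corresponding precision distribution.
fit_invgamma_moments <- function(sigma2_hat, noise_var) {
  m <- mean(sigma2_hat)
  if (m <= 0) m <- 1e-4
  v <- stats::var(sigma2_hat) - mean(noise_var)
  if (!is.finite(v) || v <= m^2 / 98) {
    shape <- 100
  } else {
    shape <- 2 + m^2 / v
  }
  list(shape = shape, rate = m * (shape - 1))
}

offset_matrix <- function(offsets, counts) {
  off <- if (inherits(offsets, "norm_offsets")) offsets$offsets else as.matrix(offsets)
  if (!all(dim(off) == dim(counts)))
    stop("offset dimensions do not match the count matrix")
  off
}

#' Posterior summaries of the fixed effects for one gene
#'
#' Approximates, for each of the 8 tissue-by-treatment cells, the marginal
#' posterior of the gene's fixed effect under the negative-binomial
#' likelihood, the normal population prior, and normal lane and replicate
#' random effects, by a nested Laplace approximation: an inner Newton search
#' finds the joint mode of (fixed effects, lane effects, replicate effects)
#' with the replicate precision updated at its conditional posterior mode,
#' and the curvature at the mode supplies the approximating normal. The
#' dispersion is plugged in at its empirical-Bayes shrunken estimate.
#'
#' @param y Integer count vector for one gene (length = samples).
#' @param design Design table.
#' @param offsets_g Offset vector for this gene (natural-log scale).
#' @param hyper A \code{nb_hyper} object.
#' @param threshold Optional activity threshold T; when given, the exceedance
#'   probability \code{p_exceed = P(beta > T | data)} is included.
#' @param phi Optional plug-in dispersion; default is the shrunken per-gene
#'   estimate.
#' @param max_restarts Bounded jittered restarts on non-convergence.
#' @return A data.frame with one row per cell: \code{cell},
#'   \code{posterior_mean}, \code{posterior_sd}, optional \code{p_exceed},
#'   and a \code{converged} flag.
#' @export
gene_posterior <- function(y, design, offsets_g, hyper, threshold = NULL,
                           phi = NULL, max_restarts = 3L) {
  validate_design(design)
  ctx <- posterior_context(design, hyper)
  if (is.null(phi)) {
    f1 <- fit_nb_cellmeans(matrix(y, 1), ctx$cells, matrix(offsets_g, 1))
    phi <- shrink_dispersion(f1$log_phi, f1$se_log_phi, hyper)
  }
  res <- laplace_gene(y, offsets_g, phi, ctx, hyper, max_restarts)
  if (res$converged) {
    ref <- refine_marginals(res, y, offsets_g, phi, ctx, threshold)
    out <- data.frame(cell = cell_names(),
                      posterior_mean = ref$mean,
                      posterior_sd = ref$sd,
                      converged = TRUE,
                      stringsAsFactors = FALSE)
    if (!is.null(threshold)) out$p_exceed <- ref$p_exceed
  } else {
    out <- data.frame(cell = cell_names(),
                      posterior_mean = hyper$beta_mean,
                      posterior_sd = sqrt(hyper$beta_var),
                      converged = FALSE,
                      stringsAsFactors = FALSE)
    if (!is.null(threshold))
      out$p_exceed <- stats::pnorm(threshold, hyper$beta_mean,
                                   sqrt(hyper$beta_var), lower.tail = FALSE)
  }
  out
}

# Marginal refinement of the joint-mode Gaussian summaries: cells whose
# plain-Laplace exceedance is not already decisive (|z| < 5) get the
# profile-marginal treatment; the rest keep the Gaussian tail.
refine_marginals <- function(res, y, off, phi, ctx, threshold = NULL) {
  kdisp <- 1 / phi
  mean_ <- res$mean; sd_ <- res$sd
  p_exceed <- if (!is.null(threshold))
    stats::pnorm(threshold, mean_, sd_, lower.tail = FALSE)
  else rep(NA_real_, 8L)
  for (cell in 1:8) {
    if (!is.null(threshold) &&
        abs(threshold - mean_[cell]) / sd_[cell] >= 5) next
    gp <- profile_marginal_cell(cell, y, off, kdisp, ctx$X, res$theta0,
                                res$prec, res$theta, sd_[cell])
    mean_[cell] <- gp$mean; sd_[cell] <- gp$sd
    if (!is.null(threshold)) p_exceed[cell] <- gp$tail(threshold)
  }
  list(mean = mean_, sd = sd_, p_exceed = p_exceed)
}

shrink_dispersion <- function(log_phi, se_log_phi, hyper) {
  w <- 1 / pmax(se_log_phi^2, 1e-6)
  w0 <- 1 / max(hyper$log_disp_var, 1e-6)
  exp((log_phi * w + hyper$log_disp_mean * w0) / (w + w0))
}

# Precomputed design structure shared across genes.
posterior_context <- function(design, hyper) {
  cells <- cell_index(design)
  lanes <- unique(design$lane)
  reps <- sort(unique(design$replicate))
  n <- nrow(design)
  X <- matrix(0, n, 8L + length(lanes) + length(reps))
  X[cbind(seq_len(n), cells)] <- 1
  X[cbind(seq_len(n), 8L + match(design$lane, lanes))] <- 1
  X[cbind(seq_len(n), 8L + length(lanes) + match(design$replicate, reps))] <- 1
  rep_idx <- 8L + length(lanes) + seq_along(reps)
  lane_idx <- 8L + seq_along(lanes)
  tau_u <- hyper$lane_precision_est %||%
    (hyper$lane_precision_shape / hyper$lane_precision_rate)
  list(cells = cells, X = X, lane_idx = lane_idx, rep_idx = rep_idx,
       n_lanes = length(lanes), n_reps = length(reps), tau_u = tau_u)
}

# Nested Laplace approximation for one gene given a posterior_context.
laplace_gene <- function(y, off, phi, ctx, hyper, max_restarts = 3L) {
  k <- 1 / phi
  X <- ctx$X
  p <- ncol(X)
  theta0 <- c(hyper$beta_mean, rep(0, p - 8L))
  a_rep <- hyper$replicate_precision_shape
  b_rep <- hyper$replicate_precision_rate
  tau_e <- a_rep / b_rep

  Zc <- matrix(0, length(y), 8L)
  Zc[cbind(seq_along(y), ctx$cells)] <- 1
  beta_init <- log((crossprod(Zc, y) + 0.5) / crossprod(Zc, exp(off)))
  init <- c(pmin(pmax(beta_init, -12), 12), rep(0, p - 8L))

  for (attempt in 0:max_restarts) {
    start <- init
    if (attempt > 0)
      start <- init + stats::rnorm(p, 0, 0.3 * attempt)
    res <- laplace_mode(y, off, k, X, theta0, hyper, ctx, tau_e, start,
                        a_rep, b_rep)
    if (res$converged) return(res)
  }
  res
}

laplace_mode <- function(y, off, k, X, theta0, hyper, ctx, tau_e, start,
                         a_rep, b_rep) {
  p <- ncol(X)
  theta <- start
  prec <- numeric(p)
  prec[1:8] <- 1 / hyper$beta_var
  prec[ctx$lane_idx] <- ctx$tau_u
  converged <- FALSE
  H <- NULL
  for (outer in 1:3) {
    prec[ctx$rep_idx] <- tau_e
    negpost <- function(th) {
      eta <- off + as.vector(X %*% th)
      mu <- exp(eta)
      -nb_loglik(y, mu, k) + 0.5 * sum(prec * (th - theta0)^2)
    }
    f <- negpost(theta)
    converged <- FALSE
    for (it in 1:60) {
      eta <- off + as.vector(X %*% theta)
      mu <- exp(eta)
      r <- y - (y + k) * mu / (k + mu)
      w <- (y + k) * k * mu / (k + mu)^2
      grad <- as.vector(crossprod(X, r)) - prec * (theta - theta0)
      H <- crossprod(X * w, X) + diag(prec, p)
      step <- tryCatch(solve(H, grad), error = function(e) grad / diag(H))
      sc <- 1
      for (half in 1:25) {
        thn <- theta + sc * step
        fn <- negpost(thn)
        if (is.finite(fn) && fn <= f + 1e-12) break
        sc <- sc / 2
      }
      if (!is.finite(fn) || fn > f + 1e-12) break
      moved <- max(abs(sc * step))
      theta <- thn; f <- fn
      if (moved < 1e-9) { converged <- TRUE; break }
    }
    e_hat <- theta[ctx$rep_idx]
    Sig <- tryCatch(chol2inv(chol(H)), error = function(e) solve(H))
    tr_ee <- sum(diag(Sig)[ctx$rep_idx])
    tau_new <- (a_rep + ctx$n_reps / 2) /
      (b_rep + (sum(e_hat^2) + tr_ee) / 2)
    if (abs(log(tau_new / tau_e)) < 1e-6) { tau_e <- tau_new; break }
    tau_e <- tau_new
  }
  Sig <- tryCatch(chol2inv(chol(H)), error = function(e) solve(H))
  list(mean = theta[1:8], sd = sqrt(pmax(diag(Sig)[1:8], 1e-12)),
       converged = converged, tau_e = tau_e, theta = theta, Sigma = Sig,
       prec = prec, theta0 = theta0)
}

# Profile (Tierney-Kadane) marginal of one fixed effect: on a grid of values
# anchored at the joint mode, the remaining parameters are re-maximised by
# reduced Newton steps and the Laplace log-determinant correction of the
# nuisance block is applied; the resulting one-dimensional density is
# integrated numerically. This is the nested-Laplace marginal: inner Laplace
# for the nuisance integral, numerical integration for the effect itself.
profile_marginal_cell <- function(kcell, y, off, kdisp, X, theta0, prec,
                                  theta_hat, sd_k) {
  p <- ncol(X)
  idx <- setdiff(seq_len(p), kcell)
  prof_one <- function(b, start) {
    th <- start; th[kcell] <- b
    for (it in 1:30) {
      eta <- off + as.vector(X %*% th)
      mu <- exp(eta)
      r <- y - (y + kdisp) * mu / (kdisp + mu)
      w <- (y + kdisp) * kdisp * mu / (kdisp + mu)^2
      grad <- as.vector(crossprod(X, r)) - prec * (th - theta0)
      H <- crossprod(X * w, X) + diag(prec, p)
      step <- solve(H[idx, idx], grad[idx])
      step <- pmin(pmax(step, -2), 2)
      th[idx] <- th[idx] + step
      if (max(abs(step)) < 1e-7) break
    }
    eta <- off + as.vector(X %*% th)
    mu <- exp(eta)
    w <- (y + kdisp) * kdisp * mu / (kdisp + mu)^2
    H <- crossprod(X * w, X) + diag(prec, p)
    ch <- tryCatch(chol(H[idx, idx]), error = function(e) NULL)
    ldet <- if (is.null(ch)) determinant(H[idx, idx])$modulus else
      2 * sum(log(diag(ch)))
    list(lp = nb_loglik(y, mu, kdisp) -
           0.5 * sum(prec * (th - theta0)^2) - 0.5 * as.numeric(ldet),
         th = th)
  }
  tgrid <- seq(0, 6, by = 0.5)
  m <- theta_hat[kcell]
  bs_r <- m + sd_k * tgrid
  bs_l <- m - sd_k * tgrid[-1]
  lp_r <- numeric(length(bs_r)); lp_l <- numeric(length(bs_l))
  st <- theta_hat
  for (j in seq_along(bs_r)) {
    res <- prof_one(bs_r[j], st); lp_r[j] <- res$lp; st <- res$th
  }
  st <- theta_hat
  for (j in seq_along(bs_l)) {
    res <- prof_one(bs_l[j], st); lp_l[j] <- res$lp; st <- res$th
  }
  grid <- c(rev(bs_l), bs_r)
  grid_posterior(grid, c(rev(lp_l), lp_r))
}

#' Posterior exceedance probabilities for all genes
#'
#' Runs [gene_posterior()] over every gene of a count matrix, returning the
#' matrices of posterior means, standard deviations and exceedance
#' probabilities P(beta > T | data) for the 8 tissue-by-treatment cells.
#'
#' @param counts Count matrix, genes x samples.
#' @param design Design table.
#' @param offsets A \code{norm_offsets} object or offset matrix.
#' @param hyper A \code{nb_hyper} object.
#' @param threshold Activity threshold T (natural-log scale), e.g. from
#'   [calibrate_threshold()].
#' @return A list of class \code{activity_posteriors}: \code{probabilities},
#'   \code{posterior_mean}, \code{posterior_sd} (all genes x 8),
#'   \code{converged}, \code{threshold}.
#' @export
activity_posteriors <- function(counts, design, offsets, hyper, threshold) {
  counts <- as.matrix(counts)
  off <- offset_matrix(offsets, counts)
  ctx <- posterior_context(design, hyper)
  fit <- fit_nb_cellmeans(counts, ctx$cells, off)
  phis <- shrink_dispersion(fit$log_phi, fit$se_log_phi, hyper)

  g <- nrow(counts)
  pm <- ps <- pp <- matrix(NA_real_, g, 8L,
                           dimnames = list(rownames(counts), cell_names()))
  conv <- logical(g)
  for (i in seq_len(g)) {
    res <- laplace_gene(counts[i, ], off[i, ], phis[i], ctx, hyper)
    conv[i] <- res$converged
    if (res$converged) {
      ref <- refine_marginals(res, counts[i, ], off[i, ], phis[i], ctx,
                              threshold)
      pm[i, ] <- ref$mean; ps[i, ] <- ref$sd; pp[i, ] <- ref$p_exceed
    } else {
      pm[i, ] <- hyper$beta_mean; ps[i, ] <- sqrt(hyper$beta_var)
      pp[i, ] <- stats::pnorm(threshold, hyper$beta_mean,
                              sqrt(hyper$beta_var), lower.tail = FALSE)
    }
  }
  if (any(!conv))
    warning(sum(!conv), " gene(s) did not converge; prior tail used")
  out <- list(probabilities = pp, posterior_mean = pm, posterior_sd = ps,
              converged = conv, threshold = threshold)
  class(out) <- "activity_posteriors"
  out
}

# One-cell posterior used by the threshold calibration: n replicate
# observations, no random effects. The mode and curvature anchor a dense
# grid on which the exact one-dimensional posterior is integrated, so the
# exceedance probability is accurate even where the posterior is skewed.
laplace_posterior_1cell <- function(y, off, phi, m0, v0) {
  k <- 1 / phi
  negpost <- function(b) {
    mu <- exp(off + b)
    -nb_loglik(y, mu, k) + 0.5 * (b - m0)^2 / v0
  }
  b <- log((sum(y) + 0.5) / sum(exp(off)))
  f <- negpost(b)
  for (it in 1:100) {
    mu <- exp(off + b)
    grad <- sum(y - (y + k) * mu / (k + mu)) - (b - m0) / v0
    h <- sum((y + k) * k * mu / (k + mu)^2) + 1 / v0
    step <- grad / h
    sc <- 1
    for (half in 1:25) {
      bn <- b + sc * step
      fn <- negpost(bn)
      if (is.finite(fn) && fn <= f + 1e-12) break
      sc <- sc / 2
    }
    b <- bn; f <- fn
    if (abs(sc * step) < 1e-10) break
  }
  mu <- exp(off + b)
  h <- sum((y + k) * k * mu / (k + mu)^2) + 1 / v0
  sd0 <- 1 / sqrt(h)
  grid <- b + sd0 * seq(-10, 10, by = 0.1)
  ld <- -vapply(grid, negpost, numeric(1))
  grid_posterior(grid, ld)
}

# Normalised summaries of a log density sampled on a grid: mean, sd, and an
# upper-tail function with linear interpolation of the CDF.
grid_posterior <- function(grid, logdens) {
  ld <- logdens - max(logdens)
  w <- exp(ld)
  dx <- diff(grid)
  # trapezoid cell masses
  cellm <- (w[-1] + w[-length(w)]) / 2 * dx
  total <- sum(cellm)
  pm <- sum((grid[-1] + grid[-length(grid)]) / 2 * cellm) / total
  m2 <- sum(((grid[-1] + grid[-length(grid)]) / 2 - pm)^2 * cellm) / total
  cdf <- c(0, cumsum(cellm)) / total
  tail_fun <- function(T) {
    if (T <= grid[1]) return(1)
    if (T >= grid[length(grid)]) return(0)
    1 - stats::approx(grid, cdf, xout = T)$y
  }
  list(mean = pm, sd = sqrt(m2), tail = tail_fun,
       grid = grid, logdens = logdens)
}

#' Calibrate the activity threshold against a reads-per-million target
#'
#' Finds the threshold T such that a pseudo-gene of average length and GC
#' content, sequenced under average library conditions, sits exactly on the
#' active/inactive boundary (exceedance probability one half) when its
#' expected coverage equals \code{target_rpm} reads per million mapped reads.
#' T is located by root finding on \code{p_exceed(T) - 0.5} for the Laplace
#' posterior given pseudo-observations at the boundary expected count.
#'
#' @param hyper A \code{nb_hyper} object.
#' @param offsets A \code{norm_offsets} object (supplies the average-gene
#'   smoother value and library sizes), or a single number giving the
#'   average-gene offset directly.
#' @param target_rpm Boundary expressed in reads per million (default 2).
#' @param n_replicates Replicates backing a single cell (default 4).
#' @param mean_library Average mapped-library size; default the geometric
#'   mean of the normalization's library sizes, or 1e6.
#' @return A list of class \code{activity_threshold}: \code{threshold},
#'   \code{target_rpm}, \code{boundary_count}, \code{ref_offset},
#'   \code{mean_library}, \code{n_replicates}, \code{phi}, \code{prior}.
#' @export
calibrate_threshold <- function(hyper, offsets, target_rpm = 2,
                                n_replicates = 4, mean_library = NULL) {
  if (target_rpm <= 0) stop("target_rpm must be positive")
  if (inherits(offsets, "norm_offsets")) {
    ref_offset <- predict(offsets$smoother)
    mean_library <- mean_library %||% geometric_mean(offsets$lib_sizes)
  } else {
    ref_offset <- as.numeric(offsets)
    mean_library <- mean_library %||% 1e6
  }
  boundary_count <- target_rpm * mean_library / 1e6
  phi <- exp(hyper$log_disp_mean)
  m0 <- mean(hyper$beta_mean)
  v0 <- mean(hyper$beta_var)
  y <- rep(boundary_count, n_replicates)
  off <- rep(ref_offset, n_replicates)
  post <- laplace_posterior_1cell(y, off, phi, m0, v0)
  fr <- function(T) post$tail(T) - 0.5
  lo <- post$mean - 10 * post$sd
  hi <- post$mean + 10 * post$sd
  if (fr(lo) < 0 || fr(hi) > 0)
    stop(sprintf("no root in threshold bracket [%.3f, %.3f]", lo, hi))
  T <- stats::uniroot(fr, c(lo, hi), tol = 1e-10)$root
  out <- list(threshold = T, target_rpm = target_rpm,
              boundary_count = boundary_count, ref_offset = ref_offset,
              mean_library = mean_library, n_replicates = n_replicates,
              phi = phi, prior = c(mean = m0, var = v0))
  class(out) <- "activity_threshold"
  out
}

#' Invert a calibrated threshold back to a boundary expected count
#'
#' Given a threshold T, root-finds the expected count c at which a
#' pseudo-gene with offset \code{offset} crosses the activity boundary
#' (exceedance probability one half), and converts it to reads per million.
#' Applied at the average-gene offset this recovers the calibration target;
#' applied at another gene's smoother value it yields that gene's effective
#' count threshold, adjusted up or down for its length and GC content.
#'
#' @param threshold An \code{activity_threshold} object or a bare numeric T.
#' @param hyper A \code{nb_hyper} object.
#' @param offset Pseudo-gene offset; defaults to the calibration's reference.
#' @param mean_library,n_replicates Defaults taken from the threshold object.
#' @return A list with \code{boundary_count} and \code{boundary_rpm}.
#' @export
activity_boundary <- function(threshold, hyper, offset = NULL,
                              mean_library = NULL, n_replicates = NULL) {
  if (inherits(threshold, "activity_threshold")) {
    offset <- offset %||% threshold$ref_offset
    mean_library <- mean_library %||% threshold$mean_library
    n_replicates <- n_replicates %||% threshold$n_replicates
    T <- threshold$threshold
  } else {
    T <- as.numeric(threshold)
    if (is.null(offset) || is.null(mean_library))
      stop("offset and mean_library are required with a bare threshold")
    n_replicates <- n_replicates %||% 4
  }
  phi <- exp(hyper$log_disp_mean)
  m0 <- mean(hyper$beta_mean)
  v0 <- mean(hyper$beta_var)
  fb <- function(logc) {
    c_ <- exp(logc)
    post <- laplace_posterior_1cell(rep(c_, n_replicates),
                                    rep(offset, n_replicates), phi, m0, v0)
    post$tail(T) - 0.5
  }
  root <- stats::uniroot(fb, c(log(1e-6), log(1e8)), tol = 1e-10)$root
  bc <- exp(root)
  list(boundary_count = bc, boundary_rpm = bc / (mean_library / 1e6))
}

#' Binary activity calls from exceedance probabilities
#'
#' Applies the strict rule: gene g is active in cell k iff
#' \code{P(beta > T | data) > 0.5}; a probability of exactly one half is
#' inactive. A gene is active overall if active in at least one cell.
#'
#' @param posteriors An \code{activity_posteriors} object or a genes x 8
#'   probability matrix.
#' @param threshold Threshold recorded alongside the calls (metadata only;
#'   probabilities are already computed at T).
#' @return A list of class \code{activity_calls}: \code{calls} (logical genes
#'   x 8), \code{probabilities}, \code{threshold}, \code{active_overall}.
#' @export
call_activity <- function(posteriors, threshold = NULL) {
  if (inherits(posteriors, "activity_posteriors")) {
    probs <- posteriors$probabilities
    threshold <- threshold %||% posteriors$threshold
  } else {
    probs <- as.matrix(posteriors)
  }
  if (any(probs < 0 | probs > 1, na.rm = TRUE))
    stop("probabilities must lie in [0, 1]")
  calls <- probs > 0.5
  out <- list(calls = calls, probabilities = probs, threshold = threshold,
              active_overall = rowSums(calls) > 0)
  class(out) <- "activity_calls"
  out
}
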