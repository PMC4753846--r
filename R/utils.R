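# Internal helpers shared across modules.

TISSUES <- c("Mz", "Ez", "Co", "St")
TREATMENTS <- c("control", "deficit")

# Names of the 8 tissue x treatment cells, control block first.
cell_names <- function() {
  as.vector(outer(TISSUES, TREATMENTS, paste, sep = "_"))
}

# Map a design table to the 1..8 cell index (tissue within treatment).
cell_index <- function(design) {
  ti <- match(as.character(design$tissue), TISSUES)
  tr <- match(as.character(design$treatment), TREATMENTS)
  if (anyNA(ti)) stop("unknown tissue label(s): ",
                      paste(unique(design$tissue[is.na(ti)]), collapse = ", "))
  if (anyNA(tr)) stop("unknown treatment label(s): ",
                      paste(unique(design$treatment[is.na(tr)]), collapse = ", "))
  ti + 4L * (tr - 1L)
}

# Run code with a temporary RNG state seeded by `seed`; restores the caller's
# stream so library code does not perturb user simulations.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

geometric_mean <- function(x) exp(mean(log(x)))

# Inverse of trigamma by Newton iteration on 1/x scale (monotone, stable).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) < 1e-10 * x) break
    }
    x
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Method-of-moments variance components for one random grouping factor on top
# of the tissue x treatment cell-means model, via expected-mean-square
# algebra on two quadratic forms: the grouping-adjusted sum of squares after
# sweeping out the cell means, and the remainder. Vectorized over the rows of
# Y. Returns per-row residual (sigma_e) and grouping (sigma_f) variance
# components (sigma_f may be negative: pure moment estimates).
ems_components <- function(Y, design, groups) {
  Y <- as.matrix(Y)
  n <- ncol(Y)
  cells <- cell_index(design)
  X <- matrix(0, n, 8L); X[cbind(seq_len(n), cells)] <- 1
  M1 <- diag(n) - X %*% solve(crossprod(X), t(X))
  g <- factor(groups)
  Zl <- matrix(0, n, nlevels(g))
  Zl[cbind(seq_len(n), as.integer(g))] <- 1
  A <- M1 %*% Zl
  qrA <- qr(A, tol = 1e-8)
  if (qrA$rank == 0L)
    return(list(sigma_e = rowSums((Y %*% M1) * Y) / max(sum(diag(M1)), 1),
                sigma_f = rep(0, nrow(Y)), r1 = 0, r2 = sum(diag(M1)),
                t1 = 0, t2 = 0))
  Qm <- tcrossprod(qr.Q(qrA)[, seq_len(qrA$rank), drop = FALSE])
  Rm <- M1 - Qm
  r1 <- sum(diag(Qm)); t1 <- sum(diag(crossprod(Zl, Qm %*% Zl)))
  r2 <- sum(diag(Rm)); t2 <- sum(diag(crossprod(Zl, Rm %*% Zl)))
  C <- rbind(c(r1, t1), c(r2, t2))
  ss1 <- rowSums((Y %*% Qm) * Y)
  ss2 <- rowSums((Y %*% Rm) * Y)
  comp <- t(solve(C, rbind(ss1, ss2)))
  list(sigma_e = comp[, 1], sigma_f = comp[, 2],
       r1 = r1, r2 = r2, t1 = t1, t2 = t2)
}

# Maximum likelihood moments of a normal population observed with known
# per-observation sampling variance: est_i ~ N(mean, var + se2_i). The
# population variance is profiled by 1-D optimization; observations with
# large sampling variance are automatically downweighted.
normal_noise_moments <- function(est, se2) {
  ok <- is.finite(est) & is.finite(se2)
  est <- est[ok]; se2 <- pmax(se2[ok], 0)
  prof <- function(V) {
    w <- 1 / (V + se2)
    mu <- sum(w * est) / sum(w)
    -0.5 * sum(log(V + se2)) - 0.5 * sum(w * (est - mu)^2)
  }
  upper <- max(stats::var(est), 1e-4) * 2
  opt <- stats::optimize(function(V) -prof(V), c(0, upper))
  V <- opt$minimum
  w <- 1 / (V + se2)
  list(mean = sum(w * est) / sum(w), var = V)
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name))
  invisible(x)
}
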