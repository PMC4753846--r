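#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Computes between-sample scaling factors by the trimmed mean of M-values:
#' for each sample against a reference, per-gene log2 expression ratios (M)
#' are trimmed on both tails together with the tails of average log2
#' abundance (A), and the surviving M values are averaged with inverse
#' asymptotic-variance weights. Genes with a zero count in either member of a
#' pair are excluded from that pair. The reference sample is the one whose
#' 75th-percentile count fraction is closest to the across-sample mean, and
#' its factor is exactly 1.
#'
#' @param counts Non-negative count matrix, genes x samples.
#' @param trim_m Two-sided trim fraction on M values (default 0.3).
#' @param trim_a Two-sided trim fraction on A values (default 0.05).
#' @param ref Optional reference sample (index or name); default automatic.
#' @return Named numeric vector of per-sample factors (reference = 1).
#' @examples
#' m <- matrix(rpois(600, 50), 100, 6)
#' tmm_factors(m)
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05, ref = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM requires at least 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  if (is.null(ref)) {
    q75 <- apply(counts, 2L, function(x) quantile(x, 0.75)) / lib
    ref <- which.min(abs(q75 - mean(q75)))
  } else if (is.character(ref)) {
    ref <- match(ref, colnames(counts))
    if (is.na(ref)) stop("reference sample not found")
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  names(f) <- colnames(counts)
  f
}

# One TMM comparison of sample `obs` against reference `ref`.
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  p_obs <- obs[keep] / n_obs
  p_ref <- ref[keep] / n_ref
  m <- log2(p_obs / p_ref)
  a <- 0.5 * log2(p_obs * p_ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2)) return(1)
  # delta-method variance of M for a pair of binomial proportions
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
       (n_ref - ref[keep]) / (n_ref * ref[keep])
  f <- sum(m[keep2] / w[keep2]) / sum(1 / w[keep2])
  2^f
}

#' Fit a smoother of log mean count on GC content and gene length
#'
#' Fits a two-dimensional local linear regression (tri-cube weights) of the
#' log of each gene's mean raw count on its GC fraction and log length; the
#' fitted surface captures the systematic dependence of expected counts on
#' gene composition and is later absorbed into the normalization offsets.
#'
#' @param counts Count matrix, genes x samples.
#' @param covariates Data frame with columns \code{gene_id}, \code{length_bp},
#'   \code{gc_fraction}, rows matching the count matrix.
#' @param span Local-regression span (default 0.5).
#' @return An object of class \code{covariate_smoother}: the fitted loess
#'   surface, per-gene fitted values, and covariate averages.
#' @export
fit_covariate_smoother <- function(counts, covariates, span = 0.5) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 50L) stop("need at least 50 genes to fit the smoother")
  if (nrow(covariates) != nrow(counts))
    stop("covariate rows do not match count rows")
  gc <- covariates$gc_fraction
  loglen <- log(covariates$length_bp)
  if (length(unique(gc)) < 3L || length(unique(loglen)) < 3L)
    stop("degenerate covariates: GC or length is (nearly) constant")
  y <- log(rowMeans(counts) + 0.5)
  dat <- data.frame(y = y, gc = gc, loglen = loglen)
  fit <- stats::loess(y ~ gc + loglen, data = dat, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  out <- list(fit = fit,
              fitted = as.numeric(predict(fit, dat)),
              span = span,
              gc_mean = mean(gc), loglen_mean = mean(loglen))
  class(out) <- "covariate_smoother"
  out
}

#' Predict the smoother at new covariate values
#'
#' @param object A \code{covariate_smoother}.
#' @param gc_fraction,length_bp Covariates at which to evaluate; defaults are
#'   the averages of the training genes (the "average gene").
#' @param ... Unused.
#' @return Predicted log mean raw count.
#' @export
predict.covariate_smoother <- function(object, gc_fraction = NULL,
                                       length_bp = NULL, ...) {
  gc <- gc_fraction %||% object$gc_mean
  ll <- if (is.null(length_bp)) object$loglen_mean else log(length_bp)
  as.numeric(predict(object$fit, data.frame(gc = gc, loglen = ll)))
}

#' Compose per-gene, per-sample normalization offsets
#'
#' Combines the per-sample term (log effective library scaling, i.e. library
#' size times TMM factor, centred at its geometric mean) with the per-gene
#' term (the covariate smoother's fitted log mean count) into the additive
#' natural-log offsets that the activity model conditions on:
#' \code{offset[g, s] = log(lib_s * tmm_s / geomean) + smoother_fitted[g]}.
#'
#' @param tmm Per-sample TMM factors from [tmm_factors()].
#' @param smoother A [fit_covariate_smoother()] result.
#' @param lib_sizes Per-sample library sizes (total mapped reads).
#' @return An object of class \code{norm_offsets}: \code{offsets} (genes x
#'   samples), \code{tmm_factors}, \code{lib_sizes}, \code{lib_eff},
#'   \code{smoother}.
#' @export
compose_offsets <- function(tmm, smoother, lib_sizes) {
  if (!inherits(smoother, "covariate_smoother"))
    stop("smoother must come from fit_covariate_smoother()")
  if (length(tmm) != length(lib_sizes))
    stop("tmm factors and library sizes differ in length")
  lib_eff <- lib_sizes * tmm
  sample_term <- log(lib_eff / geometric_mean(lib_eff))
  offsets <- outer(smoother$fitted, sample_term, `+`)
  colnames(offsets) <- names(lib_sizes) %||% names(tmm)
  out <- list(offsets = offsets,
              tmm_factors = tmm,
              lib_sizes = lib_sizes,
              lib_eff = lib_eff,
              smoother = smoother)
  class(out) <- "norm_offsets"
  out
}

#' Normalize a count matrix end to end
#'
#' Convenience wrapper chaining [tmm_factors()], [fit_covariate_smoother()]
#' and [compose_offsets()].
#'
#' @param counts Count matrix, genes x samples.
#' @param covariates Per-gene covariate table (gene_id, length_bp,
#'   gc_fraction).
#' @param lib_sizes Optional true library sizes; default column sums.
#' @param trim_m,trim_a,span Stage parameters, see the underlying functions.
#' @return A \code{norm_offsets} object.
#' @export
normalize_counts <- function(counts, covariates, lib_sizes = NULL,
                             trim_m = 0.3, trim_a = 0.05, span = 0.5) {
  counts <- as.matrix(counts)
  lib_sizes <- lib_sizes %||% colSums(counts)
  tmm <- tmm_factors(counts, trim_m = trim_m, trim_a = trim_a)
  sm <- fit_covariate_smoother(counts, covariates, span = span)
  compose_offsets(tmm, sm, lib_sizes)
}
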