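#' Filter genes on a minimum per-replicate count
#'
#' Retains gene g iff there exists at least one tissue-by-treatment group in
#' which every replicate has at least \code{min_count} mapped reads (default
#' 5 in all four replicates of at least one group).
#'
#' @param counts Count matrix, genes x samples.
#' @param design Design table.
#' @param min_count Minimum reads per replicate (default 5).
#' @return Logical vector, TRUE for retained genes.
#' @export
filter_low_counts <- function(counts, design, min_count = 5) {
  counts <- as.matrix(counts)
  if (min_count < 0) stop("min_count must be >= 0")
  cells <- cell_index(design)
  keep <- rep(FALSE, nrow(counts))
  for (k in sort(unique(cells))) {
    grp_min <- do.call(pmin, as.data.frame(counts[, cells == k, drop = FALSE]))
    keep <- keep | (grp_min >= min_count)
  }
  keep
}

#' Log-transform counts and assign precision weights
#'
#' Computes \code{log2((count + 0.5) / effective library size * 1e6)} and
#' attaches to every observation an inverse-variance weight from a fitted
#' mean-variance trend: per-gene group (cell) means and residual standard
#' deviations are computed, a lowess trend of sqrt(sd) on average
#' log-expression is fit across genes, and each observation's weight is the
#' inverse of the predicted variance at its fitted log-expression. This
#' counteracts the strong heteroscedasticity of logged count data, where low
#' counts are noisiest.
#'
#' @param counts Filtered count matrix, genes x samples.
#' @param design Design table.
#' @param lib_eff Effective library sizes (library size x TMM factor);
#'   default column sums of \code{counts}.
#' @param span Lowess span for the mean-variance trend (default 0.5).
#' @return A list of class \code{expression_matrix}: \code{logged},
#'   \code{weights} (same shape), \code{design}, \code{lib_eff},
#'   \code{trend} (the lowess curve).
#' @export
transform_and_weight <- function(counts, design, lib_eff = NULL, span = 0.5) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 10L) stop("mean-variance trend needs at least 10 genes")
  validate_design(design)
  lib_eff <- lib_eff %||% colSums(counts)
  logged <- log2(sweep(counts + 0.5, 2L, lib_eff, `/`) * 1e6)

  cells <- cell_index(design)
  Z <- matrix(0, ncol(counts), 8L)
  Z[cbind(seq_len(ncol(counts)), cells)] <- 1
  fitted_means <- (logged %*% Z) %*% diag(1 / colSums(Z))
  fitted_obs <- fitted_means[, cells, drop = FALSE]
  resid <- logged - fitted_obs
  df <- ncol(counts) - 8L
  sd_g <- sqrt(rowSums(resid^2) / df)
  x_g <- rowMeans(logged)

  lo <- stats::lowess(x_g, sqrt(sd_g), f = span)
  trend_fun <- stats::approxfun(lo$x, pmax(lo$y, 1e-3), rule = 2)
  pred_sqrt_sd <- trend_fun(fitted_obs)
  weights <- matrix(1 / pred_sqrt_sd^4, nrow(counts), ncol(counts))
  dimnames(weights) <- dimnames(logged)

  out <- list(logged = logged, weights = weights, design = design,
              lib_eff = lib_eff, trend = lo)
  class(out) <- "expression_matrix"
  out
}

#' Estimate the shared within-lane correlation
#'
#' Estimates a single correlation, shared across genes, induced by the random
#' sequencing-lane (incomplete block) effect: per gene, lane and residual
#' variance components are obtained from quadratic forms of the cell-means
#' residuals (expected-mean-square equations of the lane-adjusted sums of
#' squares), converted to an intraclass correlation, combined across genes on
#' the Fisher-z scale, and transformed back.
#'
#' @param expr An \code{expression_matrix} from [transform_and_weight()], or
#'   a bare logged matrix.
#' @param design Design table (taken from \code{expr} when available).
#' @return A single correlation in (-1, 1).
#' @export
estimate_block_correlation <- function(expr, design = NULL) {
  if (inherits(expr, "expression_matrix")) {
    design <- design %||% expr$design
    Y <- expr$logged
  } else Y <- as.matrix(expr)
  validate_design(design)
  lanes <- unique(design$lane)
  if (length(lanes) < 2L) {
    warning("single lane: returning rho = 0")
    return(0)
  }
  # Quadratic-form moment equations targeting the same-lane covariance
  # directly: with Cov(y) = sigma_tot I + gamma B (B = same-lane indicator,
  # zero diagonal), E[y' Q y] = sigma_tot tr(Q) + gamma tr(Q B) for any Q
  # orthogonal to the cell means. This stays valid when lanes are nested in
  # replicates, where a lane-variance decomposition would double-count the
  # replicate contribution to within-lane correlation.
  n <- nrow(design)
  cells <- cell_index(design)
  X <- matrix(0, n, 8L); X[cbind(seq_len(n), cells)] <- 1
  M1 <- diag(n) - X %*% solve(crossprod(X), t(X))
  Zl <- matrix(0, n, length(lanes))
  Zl[cbind(seq_len(n), match(design$lane, lanes))] <- 1
  A <- M1 %*% Zl
  qrA <- qr(A, tol = 1e-8)
  Q1 <- tcrossprod(qr.Q(qrA)[, seq_len(qrA$rank), drop = FALSE])
  Rm <- M1 - Q1
  B <- outer(design$lane, design$lane, `==`) * 1
  diag(B) <- 0
  C <- rbind(c(sum(diag(Q1)), sum(Q1 * B)),
             c(sum(diag(Rm)), sum(Rm * B)))
  ss1 <- rowSums((Y %*% Q1) * Y)
  ss2 <- rowSums((Y %*% Rm) * Y)
  comp <- t(solve(C, rbind(ss1, ss2)))
  sig_tot <- pmax(comp[, 1], 1e-10)
  gam <- comp[, 2]
  rho_g <- gam / sig_tot
  rho_g <- pmin(pmax(rho_g, -0.97), 0.97)
  tanh(mean(atanh(rho_g)))
}

#' Per-gene weighted generalized least squares with a block correlation
#'
#' Fits, for every gene, the tissue-by-treatment cell-means model by
#' generalized least squares using the observation weights and a common
#' correlation \code{rho} between observations sharing a sequencing lane, and
#' evaluates the four water-deficit-minus-control contrasts (one per tissue).
#'
#' @param expr An \code{expression_matrix} (log2 scale, with weights).
#' @param rho Within-lane correlation from [estimate_block_correlation()].
#' @return A list of class \code{de_fits}: \code{coefficients} (genes x 4
#'   log2 fold changes), \code{stdev_unscaled}, \code{sigma2}, \code{df},
#'   \code{rho}, \code{gene_id}.
#' @export
fit_contrasts <- function(expr, rho = 0) {
  if (!inherits(expr, "expression_matrix"))
    stop("expr must come from transform_and_weight()")
  design <- expr$design
  Y <- expr$logged; W <- expr$weights
  n <- ncol(Y)
  cells <- cell_index(design)
  X <- matrix(0, n, 8L); X[cbind(seq_len(n), cells)] <- 1
  if (qr(X)$rank < 8L) {
    bad <- which(colSums(X) == 0)
    stop("rank-deficient design; empty cell(s): ",
         paste(cell_names()[bad], collapse = ", "))
  }
  same_lane <- outer(design$lane, design$lane, `==`) * 1
  Rcor <- (1 - rho) * diag(n) + rho * same_lane
  Rinv <- solve(Rcor)

  Ct <- matrix(0, 4L, 8L, dimnames = list(TISSUES, cell_names()))
  for (t in 1:4) { Ct[t, t] <- -1; Ct[t, t + 4L] <- 1 }

  g <- nrow(Y)
  coefs <- se_un <- matrix(NA_real_, g, 4L,
                           dimnames = list(rownames(Y), TISSUES))
  sigma2 <- numeric(g)
  df <- n - 8L
  for (i in seq_len(g)) {
    sw <- sqrt(W[i, ])
    Xw <- X * sw
    yw <- Y[i, ] * sw
    XtRi <- crossprod(Xw, Rinv)
    XtSiX <- XtRi %*% Xw
    b <- solve(XtSiX, XtRi %*% yw)
    r <- yw - Xw %*% b
    sigma2[i] <- as.numeric(crossprod(r, Rinv %*% r)) / df
    covb <- solve(XtSiX)
    coefs[i, ] <- Ct %*% b
    se_un[i, ] <- sqrt(diag(Ct %*% covb %*% t(Ct)))
  }
  out <- list(coefficients = coefs, stdev_unscaled = se_un,
              sigma2 = sigma2, df = rep(df, g), rho = rho,
              gene_id = rownames(Y) %||% sprintf("gene%05d", seq_len(g)))
  class(out) <- "de_fits"
  out
}

#' Moderate residual variances and test the contrasts
#'
#' Borrows strength across genes by fitting a scaled inverse chi-square prior
#' (prior variance \code{s0^2}, prior degrees of freedom \code{d0}) to the
#' per-gene residual variances via moments of log variances, shrinking each
#' gene's variance to \code{(d0 s0^2 + dg sg^2) / (d0 + dg)}, and forming
#' moderated t statistics with \code{d0 + dg} degrees of freedom. P-values
#' are two-sided; q-values are Benjamini-Hochberg within each tissue.
#'
#' @param fits A \code{de_fits} object (at least 100 genes unless \code{d0}
#'   is supplied).
#' @param d0,s02 Optional forced prior degrees of freedom / variance;
#'   \code{d0 = 0} reproduces ordinary t statistics, \code{d0 = Inf} shrinks
#'   completely to \code{s02}.
#' @param fdr_cut,lfc_cut Thresholds recorded in the \code{passes} flag
#'   (defaults 0.01 and 1).
#' @return A data.frame (one row per gene x tissue): \code{gene_id},
#'   \code{tissue}, \code{log2fc}, \code{moderated_stat}, \code{p_value},
#'   \code{q_value}, \code{passes}; with attributes \code{d0} and \code{s02}.
#' @export
moderate_and_test <- function(fits, d0 = NULL, s02 = NULL,
                              fdr_cut = 0.01, lfc_cut = 1) {
  if (!inherits(fits, "de_fits")) stop("fits must come from fit_contrasts()")
  s2 <- fits$sigma2
  ok <- is.finite(s2) & s2 > 0
  if (sum(!ok)) message("dropping ", sum(!ok), " non-finite variance(s)")
  dg <- fits$df[1]
  if (is.null(d0) && sum(ok) < 100L)
    stop("need at least 100 genes to estimate the variance hyperprior")
  if (is.null(d0)) {
    fd <- fit_variance_prior(s2[ok], dg)
    d0 <- fd$d0; s02 <- s02 %||% fd$s02
  } else if (is.null(s02)) {
    s02 <- exp(mean(log(s2[ok])))
  }
  post_var <-
    if (d0 == 0) s2
    else if (is.infinite(d0)) rep(s02, length(s2))
    else (d0 * s02 + dg * s2) / (d0 + dg)

  tt <- fits$coefficients / (fits$stdev_unscaled * sqrt(post_var))
  df_total <- dg + d0
  pp <- 2 * stats::pt(-abs(tt), df = df_total)
  qq <- apply(pp, 2L, adjust_fdr)
  res <- data.frame(
    gene_id = rep(fits$gene_id, 4L),
    tissue = rep(TISSUES, each = length(fits$gene_id)),
    log2fc = as.vector(fits$coefficients),
    moderated_stat = as.vector(tt),
    p_value = as.vector(pp),
    q_value = as.vector(qq),
    stringsAsFactors = FALSE)
  res$passes <- res$q_value < fdr_cut & abs(res$log2fc) >= lfc_cut
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  res
}

# Moments-of-log-variances fit of the scaled inverse chi-square hyperprior.
fit_variance_prior <- function(s2, dg) {
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(e))
  }
  list(d0 = d0, s02 = s02)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; the shared multiplicity
#' correction of the differential-expression and enrichment modules.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method \code{"BH"} (default) or \code{"BY"} for the
#'   dependency-robust variant.
#' @return q-values, same length and order as \code{p}.
#' @export
adjust_fdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Select water-deficit-responsive genes and summarise their overlap
#'
#' Flags genes with \code{q < fdr_cut} and \code{|log2fc| >= lfc_cut} per
#' tissue, and summarises: per-tissue up/down counts, the distribution of
#' genes over numbers of responsive tissues, the count responsive in all
#' four tissues, and the direction-consistency fraction among genes
#' responsive in more than one tissue.
#'
#' @param results Data frame from [moderate_and_test()].
#' @param fdr_cut,lfc_cut Selection thresholds (defaults 0.01 and 1).
#' @return A list: \code{per_tissue} (data.frame tissue/n/up/down),
#'   \code{sets} (gene ids per tissue), \code{n_responsive},
#'   \code{n_multi_tissue}, \code{n_consistent}, \code{consistency},
#'   \code{n_all_tissues}, \code{tissue_count_table}.
#' @export
select_responsive <- function(results, fdr_cut = 0.01, lfc_cut = 1) {
  sel <- results$q_value < fdr_cut & abs(results$log2fc) >= lfc_cut
  res <- results[sel, , drop = FALSE]
  sets <- split(res$gene_id, factor(res$tissue, levels = TISSUES))
  per_tissue <- data.frame(
    tissue = TISSUES,
    n = vapply(sets, length, integer(1)),
    up = vapply(split(res$log2fc > 0, factor(res$tissue, levels = TISSUES)),
                sum, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  per_tissue$down <- per_tissue$n - per_tissue$up

  by_gene <- split(res$log2fc, res$gene_id)
  n_tissues <- vapply(by_gene, length, integer(1))
  multi <- by_gene[n_tissues > 1L]
  consistent <- vapply(multi, function(x) all(x > 0) || all(x < 0), logical(1))
  list(per_tissue = per_tissue,
       sets = sets,
       n_responsive = length(by_gene),
       n_multi_tissue = length(multi),
       n_consistent = sum(consistent),
       consistency = if (length(multi)) mean(consistent) else NA_real_,
       n_all_tissues = sum(n_tissues == 4L),
       tissue_count_table = table(factor(n_tissues, levels = 1:4)))
}

#' Full differential-expression analysis
#'
#' Chains filtering, transformation and weighting, block-correlation
#' estimation, weighted GLS contrast fitting, variance moderation and FDR
#' adjustment.
#'
#' @param counts Count matrix, genes x samples.
#' @param design Design table.
#' @param lib_eff Effective library sizes (default column sums).
#' @param min_count,span,fdr_cut,lfc_cut Stage parameters.
#' @param adjust_lanes Remove the cross-gene estimate of the realized lane
#'   effects from the logged expression before the per-gene model (default
#'   TRUE). Lane effects are shared by every gene in a lane, so with
#'   thousands of genes they are estimable almost exactly; removing them
#'   eliminates the common shift they would otherwise impose on a whole
#'   contrast family. The residual within-lane correlation is still
#'   estimated and modelled.
#' @return A list: \code{results} (the [moderate_and_test()] table),
#'   \code{selection} (the [select_responsive()] summary), \code{rho},
#'   \code{kept} (logical filter vector), \code{expr}.
#' @export
de_analysis <- function(counts, design, lib_eff = NULL, min_count = 5,
                        span = 0.5, fdr_cut = 0.01, lfc_cut = 1,
                        adjust_lanes = TRUE) {
  counts <- as.matrix(counts)
  keep <- filter_low_counts(counts, design, min_count)
  if (!any(keep)) stop("no genes pass the count filter")
  expr <- transform_and_weight(counts[keep, , drop = FALSE], design,
                               lib_eff = lib_eff, span = span)
  if (adjust_lanes && length(unique(design$lane)) > 1L) {
    cells <- cell_index(design)
    Zc <- matrix(0, ncol(expr$logged), 8L)
    Zc[cbind(seq_len(ncol(expr$logged)), cells)] <- 1
    cm <- (expr$logged %*% Zc) %*% diag(1 / colSums(Zc))
    delta <- colMeans(expr$logged - cm[, cells, drop = FALSE])
    lanes <- unique(design$lane)
    u <- tapply(delta, factor(design$lane, levels = lanes), mean)
    u <- u - mean(u)
    expr$logged <- sweep(expr$logged, 2L,
                         as.numeric(u[match(design$lane, lanes)]))
  }
  rho <- estimate_block_correlation(expr)
  fits <- fit_contrasts(expr, rho)
  results <- moderate_and_test(fits, fdr_cut = fdr_cut, lfc_cut = lfc_cut)
  list(results = results,
       selection = select_responsive(results, fdr_cut, lfc_cut),
       rho = rho, kept = keep, expr = expr)
}
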