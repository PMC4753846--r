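#' Fisher's exact singular enrichment analysis
#'
#' Tests each annotation category for over-representation among a set of
#' differentially expressed genes relative to the background of all expressed
#' genes, using the one-sided Fisher's exact (hypergeometric upper-tail)
#' p-value of the 2x2 table, with FDR adjustment across categories.
#'
#' @param de_genes Character vector of selected gene ids (subset of
#'   \code{background}).
#' @param background Character vector of all expressed gene ids.
#' @param annotation Data frame with columns \code{gene_id}, \code{category};
#'   a gene may carry several categories. Unannotated background genes still
#'   count in the totals.
#' @param fdr_cut Enrichment cut-off on the q-value (default 0.05).
#' @param method FDR variant passed to [adjust_fdr()].
#' @return Data frame, one row per category: \code{category},
#'   \code{n_de_in}, \code{n_de}, \code{n_bg_in}, \code{n_bg},
#'   \code{p_value}, \code{q_value}, \code{enriched}; ordered by p-value.
#' @export
fisher_enrichment <- function(de_genes, background, annotation,
                              fdr_cut = 0.05, method = "BH") {
  de_genes <- unique(as.character(de_genes))
  background <- unique(as.character(background))
  if (!length(de_genes)) stop("the DE gene set is empty")
  extra <- setdiff(de_genes, background)
  if (length(extra))
    stop("DE gene(s) missing from the background: ",
         paste(utils::head(extra, 3), collapse = ", "))
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "category")])
  n_bg <- length(background)
  n_de <- length(de_genes)
  cats <- sort(unique(as.character(ann$category)))
  in_de <- ann$gene_id %in% de_genes
  n_bg_in <- table(factor(ann$category, levels = cats))
  n_de_in <- table(factor(ann$category[in_de], levels = cats))

  p <- stats::phyper(as.integer(n_de_in) - 1L, as.integer(n_bg_in),
                     n_bg - as.integer(n_bg_in), n_de, lower.tail = FALSE)
  out <- data.frame(category = cats,
                    n_de_in = as.integer(n_de_in),
                    n_de = n_de,
                    n_bg_in = as.integer(n_bg_in),
                    n_bg = n_bg,
                    p_value = p,
                    stringsAsFactors = FALSE)
  out$q_value <- adjust_fdr(out$p_value, method = method)
  out$enriched <- out$q_value < fdr_cut
  out[order(out$p_value, out$category), , drop = FALSE]
}

#' Chi-square test of the DE distribution over a fixed category partition
#'
#' Compares the distribution of differentially expressed genes over a fixed
#' partition of categories (e.g. 32 metabolic-pathway bins or transcription
#' factor families) with the distribution expected from all expressed genes:
#' expected DE counts are the background category proportions scaled to the
#' DE total. Returns the global chi-square statistic and p-value plus
#' per-category standardized residuals, flagging categories with more
#' observed than expected genes at the one-sided normal 0.05 level.
#' Categories with expected count zero are merged into \code{"other"}.
#'
#' @param de_genes Character vector of selected gene ids.
#' @param background Character vector of all expressed gene ids.
#' @param partition Data frame with columns \code{gene_id}, \code{category};
#'   each annotated gene must appear in exactly one category.
#' @return A list: \code{statistic}, \code{df}, \code{p_value},
#'   \code{table} (category/observed/expected/std_residual/over_represented).
#' @export
chisq_distribution_test <- function(de_genes, background, partition) {
  de_genes <- unique(as.character(de_genes))
  background <- unique(as.character(background))
  if (!length(de_genes)) stop("the DE gene set is empty")
  part <- partition[partition$gene_id %in% background, , drop = FALSE]
  if (anyDuplicated(part$gene_id))
    stop("partition assigns gene(s) to more than one category: ",
         part$gene_id[duplicated(part$gene_id)][1])
  bg_tab <- table(as.character(part$category))
  de_ann <- part[part$gene_id %in% de_genes, , drop = FALSE]
  n_de <- nrow(de_ann)
  if (!n_de) stop("no annotated DE genes")
  obs <- table(factor(as.character(de_ann$category), levels = names(bg_tab)))
  props <- as.numeric(bg_tab) / sum(bg_tab)
  expected <- n_de * props
  if (any(expected == 0)) {
    warning("merging categories with expected count 0 into 'other'")
    zero <- expected == 0
    obs <- c(obs[!zero], other = sum(obs[zero]))
    props <- c(props[!zero], other = sum(props[zero]))
    expected <- n_de * props
  }
  ct <- stats::chisq.test(as.integer(obs), p = props)
  stdres <- (as.numeric(obs) - expected) / sqrt(expected * (1 - props))
  tab <- data.frame(category = names(obs),
                    observed = as.integer(obs),
                    expected = expected,
                    std_residual = stdres,
                    over_represented = as.numeric(obs) > expected &
                      stats::pnorm(stdres, lower.tail = FALSE) < 0.05,
                    stringsAsFactors = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), table = tab)
}
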