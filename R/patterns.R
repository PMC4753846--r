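#' Count activity-status changes between conditions
#'
#' The number of spatial activity-status changes of a gene is the size of the
#' symmetric difference between its set of active tissues under control and
#' under water deficit, ranging from 0 (same tissues) to 4 (e.g. inactive
#' everywhere under control, active in all four tissues after treatment).
#'
#' @param control_set,deficit_set Character vectors of tissue labels (subsets
#'   of Mz, Ez, Co, St) in which the gene is active under each condition.
#' @return Integer in 0..4.
#' @examples
#' count_changes("Mz", c("Mz", "Ez"))  # 1
#' @export
count_changes <- function(control_set, deficit_set) {
  cs <- check_tissue_set(control_set)
  ds <- check_tissue_set(deficit_set)
  length(union(setdiff(cs, ds), setdiff(ds, cs)))
}

check_tissue_set <- function(x) {
  x <- unique(as.character(x))
  x <- x[!is.na(x) & nzchar(x)]
  bad <- setdiff(x, TISSUES)
  if (length(bad))
    stop("invalid tissue label(s): ", paste(bad, collapse = ", "))
  x
}

#' Classify a gene's activity pattern
#'
#' Assigns one of the activity-dynamics categories from the per-condition
#' active-tissue sets: \code{constitutive_all} (active in all four tissues
#' under both conditions), \code{never_active} (active nowhere),
#' \code{stable_single}/\code{stable_multi} (identical non-universal sets of
#' one / several tissues), \code{dynamic_increase} (deficit set strictly
#' contains the control set), \code{dynamic_decrease} (strictly contained),
#' or \code{dynamic_change} (sets differ, neither nested).
#'
#' @inheritParams count_changes
#' @return A list with \code{category}, \code{control_set},
#'   \code{deficit_set}, \code{n_changes}.
#' @examples
#' classify_pattern("Mz", c("Mz", "Ez"))$category   # dynamic_increase
#' classify_pattern(character(0), TISSUES)$n_changes  # 4
#' @export
classify_pattern <- function(control_set, deficit_set) {
  cs <- check_tissue_set(control_set)
  ds <- check_tissue_set(deficit_set)
  n_changes <- count_changes(cs, ds)
  category <-
    if (length(cs) == 4L && length(ds) == 4L) "constitutive_all"
    else if (!length(cs) && !length(ds)) "never_active"
    else if (n_changes == 0L) {
      if (length(cs) == 1L) "stable_single" else "stable_multi"
    } else if (all(cs %in% ds)) "dynamic_increase"
    else if (all(ds %in% cs)) "dynamic_decrease"
    else "dynamic_change"
  list(category = category,
       control_set = sort(cs), deficit_set = sort(ds),
       n_changes = n_changes)
}

PATTERN_CATEGORIES <- c("constitutive_all", "stable_single", "stable_multi",
                        "dynamic_increase", "dynamic_decrease",
                        "dynamic_change", "never_active")

#' Per-gene activity patterns from binary calls
#'
#' Converts an [call_activity()] result (or a bare genes x 8 logical matrix,
#' cells ordered Mz, Ez, Co, St under control then deficit) into one
#' activity-pattern record per gene.
#'
#' @param calls An \code{activity_calls} object or logical matrix.
#' @return A data.frame with columns \code{gene_id}, \code{category},
#'   \code{control_set}, \code{deficit_set} (comma-separated tissue labels),
#'   \code{n_changes}, plus the 8 per-cell logical columns.
#' @export
activity_patterns <- function(calls) {
  m <- if (inherits(calls, "activity_calls")) calls$calls else as.matrix(calls)
  if (ncol(m) != 8L) stop("calls must have 8 columns (4 tissues x 2 conditions)")
  gene_id <- rownames(m) %||% sprintf("gene%05d", seq_len(nrow(m)))
  out <- data.frame(gene_id = gene_id,
                    category = character(nrow(m)),
                    control_set = character(nrow(m)),
                    deficit_set = character(nrow(m)),
                    n_changes = integer(nrow(m)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    cs <- TISSUES[m[i, 1:4]]
    ds <- TISSUES[m[i, 5:8]]
    cl <- classify_pattern(cs, ds)
    out$category[i] <- cl$category
    out$control_set[i] <- paste(cl$control_set, collapse = ",")
    out$deficit_set[i] <- paste(cl$deficit_set, collapse = ",")
    out$n_changes[i] <- cl$n_changes
  }
  cellcalls <- as.data.frame(m)
  names(cellcalls) <- paste0("active_", cell_names())
  cbind(out, cellcalls)
}

#' Summarise activity patterns
#'
#' Tabulates a set of per-gene activity patterns: counts per category (with
#' stable and dynamic totals and the multi-tissue "MT" pooling of stable
#' genes), counts of dynamic genes per number of activity-status changes,
#' per-tissue active-gene counts under each condition, and the per-condition
#' tissue-set (Venn) occupancy. Genes never active in any cell are reported
#' separately and excluded from active-gene denominators.
#'
#' @param patterns A data.frame from [activity_patterns()], or a list/vector
#'   of categories with an \code{n_changes} column alongside.
#' @return A list with \code{category_counts}, \code{n_active},
#'   \code{n_genes}, \code{stable_total}, \code{stable_single_share},
#'   \code{dynamic_total}, \code{change_counts}, \code{per_tissue_active}
#'   (when cell calls are present) and \code{venn} per condition.
#' @export
tabulate_patterns <- function(patterns) {
  cat_counts <- table(factor(patterns$category, levels = PATTERN_CATEGORIES))
  n_genes <- nrow(patterns)
  n_never <- as.integer(cat_counts["never_active"])
  n_active <- n_genes - n_never
  stable_total <- as.integer(cat_counts["stable_single"] +
                               cat_counts["stable_multi"])
  dynamic_total <- as.integer(cat_counts["dynamic_increase"] +
                                cat_counts["dynamic_decrease"] +
                                cat_counts["dynamic_change"])
  dyn <- patterns$n_changes[grepl("^dynamic", patterns$category)]
  change_counts <- table(factor(dyn, levels = 1:4))

  out <- list(
    category_counts = cat_counts,
    n_genes = n_genes,
    n_active = n_active,
    constitutive_share = if (n_active > 0)
      as.integer(cat_counts["constitutive_all"]) / n_active else NA_real_,
    stable_total = stable_total,
    stable_single_share = if (stable_total > 0)
      as.integer(cat_counts["stable_single"]) / stable_total else NA_real_,
    dynamic_total = dynamic_total,
    change_counts = change_counts)

  cell_cols <- paste0("active_", cell_names())
  if (all(cell_cols %in% names(patterns))) {
    m <- as.matrix(patterns[, cell_cols])
    out$per_tissue_active <- matrix(colSums(m), 4L, 2L,
                                    dimnames = list(TISSUES, TREATMENTS))
    out$venn <- list(
      control = table(patterns$control_set[rowSums(m) > 0]),
      deficit = table(patterns$deficit_set[rowSums(m) > 0]))
  }
  out
}
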