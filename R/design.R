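#' Generate an incomplete-block lane design
#'
#' Builds the sample layout of a 4-tissue (Mz, Ez, Co, St) by 2-treatment
#' (control, water deficit) experiment with \code{n_replicates} biological
#' replicates, and assigns the resulting libraries to sequencing lanes of
#' \code{libraries_per_lane} libraries each, treating each lane as an
#' incomplete block. Assignment uses a deterministic cyclic construction:
#' within each replicate the 8 tissue-by-treatment libraries are rotated by a
#' seed-derived shift and chunked into lanes, so no lane ever carries two
#' replicates of the same tissue-by-treatment combination when lanes fit
#' within a replicate (\code{libraries_per_lane} dividing 8).
#'
#' @param n_replicates Number of biological replicates per tissue-by-treatment
#'   combination (default 4).
#' @param libraries_per_lane Number of libraries pooled per flow-cell lane
#'   (default 4).
#' @param seed Optional integer seed controlling the cyclic rotation offsets.
#' @return A data.frame with columns \code{sample_id}, \code{tissue},
#'   \code{treatment}, \code{replicate}, \code{lane}; one row per library.
#' @examples
#' d <- generate_design(n_replicates = 4, libraries_per_lane = 4, seed = 1)
#' table(d$lane)
#' @export
generate_design <- function(n_replicates = 4, libraries_per_lane = 4,
                            seed = NULL) {
  n_replicates <- as.integer(n_replicates)
  libraries_per_lane <- as.integer(libraries_per_lane)
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1")
  if (libraries_per_lane < 1L) stop("'libraries_per_lane' must be >= 1")
  n_samples <- 8L * n_replicates
  if (n_samples %% libraries_per_lane != 0L)
    stop(sprintf(
      "total libraries (%d) not divisible by libraries_per_lane (%d)",
      n_samples, libraries_per_lane))

  cells <- expand.grid(tissue = TISSUES, treatment = TREATMENTS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  shifts <- with_seed(seed, sample.int(8L, n_replicates, replace = TRUE) - 1L)

  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    ord <- ((seq_len(8L) - 1L + shifts[r]) %% 8L) + 1L
    rows[[r]] <- data.frame(
      tissue = cells$tissue[order(ord)],
      treatment = cells$treatment[order(ord)],
      replicate = r,
      stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, rows)
  n_lanes <- n_samples %/% libraries_per_lane
  design$lane <- sprintf("lane%02d",
                         rep(seq_len(n_lanes), each = libraries_per_lane))
  design$sample_id <- sprintf("%s_%s_r%d", design$tissue,
                              substr(design$treatment, 1, 3), design$replicate)
  design$tissue <- factor(design$tissue, levels = TISSUES)
  design$treatment <- factor(design$treatment, levels = TREATMENTS)
  design <- design[, c("sample_id", "tissue", "treatment", "replicate", "lane")]
  rownames(design) <- NULL
  validate_design(design)
  design
}

#' Validate a sample design table
#'
#' Checks the structural invariants of the lane design: every
#' tissue-by-treatment-by-replicate combination present exactly once, equal
#' lane sizes, and no duplicated sample identifiers.
#'
#' @param design A design data.frame as returned by [generate_design()] or
#'   read by [read_design()].
#' @return The design, invisibly; errors describe the first violated cell.
#' @export
validate_design <- function(design) {
  req <- c("sample_id", "tissue", "treatment", "replicate", "lane")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols))
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicated sample_id: ",
         design$sample_id[duplicated(design$sample_id)][1])
  reps <- sort(unique(design$replicate))
  expected <- expand.grid(tissue = TISSUES, treatment = TREATMENTS,
                          replicate = reps, stringsAsFactors = FALSE)
  key <- function(t, tr, r) paste(t, tr, r, sep = "|")
  have <- key(design$tissue, design$treatment, design$replicate)
  want <- key(expected$tissue, expected$treatment, expected$replicate)
  absent <- setdiff(want, have)
  if (length(absent))
    stop("design is missing tissue x treatment x replicate cell(s): ",
         paste(absent, collapse = "; "))
  if (anyDuplicated(have))
    stop("duplicated tissue x treatment x replicate cell: ",
         have[duplicated(have)][1])
  lane_sizes <- table(design$lane)
  if (length(unique(as.integer(lane_sizes))) != 1L)
    stop("lanes are not equally sized: ",
         paste(names(lane_sizes), lane_sizes, sep = "=", collapse = ", "))
  invisible(design)
}
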