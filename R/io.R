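# Readers and writers for the pipeline's tab-separated artifact tables.
# All files are UTF-8, tab-delimited, '.' decimal, with a one-line
# '#rootzone-schema' header comment recording the table kind and version.

SCHEMA_VERSION <- "1"

write_tsv <- function(df, path, schema = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(schema))
    writeLines(sprintf("#rootzone-schema %s v%s", schema, SCHEMA_VERSION), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a count matrix to TSV
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, schema = "counts")
}

#' Read and validate a count matrix
#'
#' Expects a TSV with a \code{gene_id} column followed by one integer column
#' per sample. Errors name the offending gene and sample for duplicated ids,
#' negative or non-integer entries.
#'
#' @param path Counts TSV file.
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "gene_id")
    stop("counts file must start with a 'gene_id' column: ", path)
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in ", path, ": ",
         df$gene_id[duplicated(df$gene_id)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at gene '%s', sample '%s' in %s",
                 df$gene_id[bad[1, 1]], colnames(m)[bad[1, 2]], path))
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Read and validate a design table
#'
#' @param path Design TSV with columns sample_id, tissue, treatment,
#'   replicate, lane.
#' @return A validated design data.frame.
#' @export
read_design <- function(path) {
  df <- read_tsv(path)
  validate_design(df)
  df$tissue <- factor(df$tissue, levels = TISSUES)
  df$treatment <- factor(df$treatment, levels = TREATMENTS)
  df
}

#' Read and validate per-gene covariates
#'
#' @param path TSV with columns gene_id, length_bp, gc_fraction.
#' @return A data.frame.
#' @export
read_covariates <- function(path) {
  df <- read_tsv(path)
  req <- c("gene_id", "length_bp", "gc_fraction")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("covariate file missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in ", path)
  if (any(df$length_bp <= 0))
    stop("non-positive gene length at gene '",
         df$gene_id[which(df$length_bp <= 0)[1]], "'")
  if (any(df$gc_fraction < 0 | df$gc_fraction > 1))
    stop("gc_fraction outside [0, 1] at gene '",
         df$gene_id[which(df$gc_fraction < 0 | df$gc_fraction > 1)[1]], "'")
  df
}

#' Read a gene-to-category annotation table
#'
#' @param path TSV with columns gene_id, category and optionally system.
#' @return A data.frame.
#' @export
read_annotation <- function(path) {
  df <- read_tsv(path)
  if (!all(c("gene_id", "category") %in% names(df)))
    stop("annotation file needs columns gene_id and category: ", path)
  df
}
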