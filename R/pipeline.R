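#' Pipeline configuration
#'
#' Collects paths and stage parameters for [run_pipeline()]. Either input
#' paths (counts/design/covariates TSVs) or a simulation configuration must
#' be supplied; stages can be toggled individually.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param counts,design,covariates,annotation Optional input TSV paths.
#' @param simulate Optional [sim_config()] used when no counts are given.
#' @param stages Character vector of enabled stages, any of
#'   \code{c("normalize", "activity", "patterns", "de", "enrich", "qc")}.
#' @param trim_m,trim_a,span TMM trim fractions and smoother span.
#' @param target_rpm Activity calibration target (reads per million).
#' @param min_count,fdr_cut,lfc_cut DE stage parameters.
#' @param enrich_fdr Enrichment q-value cut-off.
#' @param top_k Genes per pair for the leading-fold-change distances.
#' @param seed Seed recorded in the manifest and used for any simulation.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir,
                            counts = NULL, design = NULL, covariates = NULL,
                            annotation = NULL, simulate = NULL,
                            stages = c("normalize", "activity", "patterns",
                                       "de", "qc"),
                            trim_m = 0.3, trim_a = 0.05, span = 0.5,
                            target_rpm = 2, min_count = 5,
                            fdr_cut = 0.01, lfc_cut = 1, enrich_fdr = 0.05,
                            top_k = 500, seed = 1L) {
  known <- c("normalize", "activity", "patterns", "de", "enrich", "qc")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(counts) && is.null(simulate))
    stop("either input paths or a simulation config must be given")
  for (p in c(counts, design, covariates, annotation))
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  if (target_rpm <= 0) stop("target_rpm must be positive")
  stopifnot_scalar_prob(fdr_cut, "fdr_cut")
  stopifnot_scalar_prob(enrich_fdr, "enrich_fdr")
  cfg <- list(out_dir = out_dir, counts = counts, design = design,
              covariates = covariates, annotation = annotation,
              simulate = simulate, stages = stages,
              trim_m = trim_m, trim_a = trim_a, span = span,
              target_rpm = target_rpm, min_count = min_count,
              fdr_cut = fdr_cut, lfc_cut = lfc_cut, enrich_fdr = enrich_fdr,
              top_k = top_k, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()] arguments.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate/read inputs, normalize,
#' activity calling, pattern classification, differential expression,
#' enrichment, sample diagnostics — writing each stage's TSV artifacts, a
#' plain-text log of per-stage parameters, and a manifest with input
#' checksums and the seed. Re-running with an identical configuration
#' reproduces identical outputs.
#'
#' @param config A \code{pipeline_config} (or a YAML path).
#' @return Invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  paths <- character(0)
  emit <- function(df, name, schema) {
    p <- file.path(config$out_dir, name)
    write_tsv(df, p, schema = schema)
    paths <<- c(paths, p)
    p
  }
  results <- list()
  stage <- "inputs"
  run <- function(name, expr) {
    stage <- name
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  run("inputs", {
    if (!is.null(config$counts)) {
      counts <- read_counts(config$counts)
      design <- read_design(config$design)
      covariates <- read_covariates(config$covariates)
      note("inputs: read %d genes x %d samples from %s",
           nrow(counts), ncol(counts), config$counts)
      lib_sizes <- colSums(counts)
      sim <- NULL
    } else {
      sim <- simulate_experiment(config$simulate)
      counts <- sim$counts
      design <- sim$design
      covariates <- sim$gene_covariates
      lib_sizes <- sim$lib_sizes
      note("inputs: simulated %d genes x %d samples (seed %d)",
           nrow(counts), ncol(counts), config$simulate$seed)
      emit(data.frame(gene_id = rownames(counts), counts,
                      check.names = FALSE), "counts.tsv", "counts")
      emit(design, "design.tsv", "design")
      emit(covariates, "gene_covariates.tsv", "covariates")
    }
    results$counts <- counts; results$design <- design
    results$covariates <- covariates; results$lib_sizes <- lib_sizes
  })
  counts <- results$counts; design <- results$design

  norm <- NULL
  if ("normalize" %in% config$stages ||
      any(c("activity", "de") %in% config$stages)) {
    run("normalize", {
      norm <- normalize_counts(counts, results$covariates,
                               lib_sizes = results$lib_sizes,
                               trim_m = config$trim_m, trim_a = config$trim_a,
                               span = config$span)
      note("normalize: trim_m=%.2f trim_a=%.2f span=%.2f",
           config$trim_m, config$trim_a, config$span)
      emit(data.frame(sample_id = design$sample_id,
                      tmm_factor = unname(norm$tmm_factors),
                      lib_size = unname(norm$lib_sizes)),
           "normalization_factors.tsv", "factors")
      emit(data.frame(gene_id = rownames(counts), norm$offsets,
                      check.names = FALSE), "offsets.tsv", "offsets")
      results$norm <- norm
    })
  }

  if ("activity" %in% config$stages) {
    run("activity", {
      hyper <- estimate_hyperparameters(counts, design, norm)
      thr <- calibrate_threshold(hyper, norm, target_rpm = config$target_rpm,
                                 n_replicates = max(design$replicate))
      post <- activity_posteriors(counts, design, norm, hyper, thr$threshold)
      calls <- call_activity(post)
      note("activity: target_rpm=%.2f threshold=%.4f", config$target_rpm,
           thr$threshold)
      long <- data.frame(
        gene_id = rep(rownames(counts), 8L),
        cell = rep(cell_names(), each = nrow(counts)),
        posterior_mean = as.vector(post$posterior_mean),
        posterior_sd = as.vector(post$posterior_sd),
        p_exceed = as.vector(post$probabilities))
      emit(long, "activity_posteriors.tsv", "posteriors")
      emit(data.frame(gene_id = rownames(counts), calls$calls * 1L,
                      check.names = FALSE), "activity_calls.tsv", "calls")
      results$hyper <- hyper; results$threshold <- thr
      results$posteriors <- post; results$calls <- calls
    })
  }

  if ("patterns" %in% config$stages) {
    run("patterns", {
      if (is.null(results$calls))
        stop("patterns stage needs the activity stage")
      pats <- activity_patterns(results$calls)
      summ <- tabulate_patterns(pats)
      emit(pats, "activity_patterns.tsv", "patterns")
      emit(data.frame(category = names(summ$category_counts),
                      n = as.integer(summ$category_counts)),
           "pattern_summary.tsv", "pattern_summary")
      venn <- do.call(rbind, lapply(names(summ$venn), function(cond)
        data.frame(condition = cond,
                   tissue_set = names(summ$venn[[cond]]),
                   n = as.integer(summ$venn[[cond]]))))
      emit(venn, "pattern_venn.tsv", "pattern_venn")
      note("patterns: %d active, %d stable, %d dynamic",
           summ$n_active, summ$stable_total, summ$dynamic_total)
      results$patterns <- pats; results$pattern_summary <- summ
    })
  }

  if ("de" %in% config$stages) {
    run("de", {
      de <- de_analysis(counts, design,
                        lib_eff = norm$lib_eff,
                        min_count = config$min_count, span = config$span,
                        fdr_cut = config$fdr_cut, lfc_cut = config$lfc_cut)
      note("de: min_count=%d rho=%.3f fdr=%.3g lfc=%.2f", config$min_count,
           de$rho, config$fdr_cut, config$lfc_cut)
      emit(de$results, "de_results.tsv", "de_results")
      emit(de$selection$per_tissue, "de_summary.tsv", "de_summary")
      results$de <- de
    })
  }

  if ("enrich" %in% config$stages) {
    run("enrich", {
      if (is.null(config$annotation))
        stop("enrichment stage needs an annotation path")
      if (is.null(results$de)) stop("enrichment stage needs the de stage")
      ann <- read_annotation(config$annotation)
      background <- rownames(counts)[results$de$kept]
      systems <- if ("system" %in% names(ann)) unique(ann$system) else "all"
      enr <- list()
      for (sys in systems) {
        a <- if ("system" %in% names(ann)) ann[ann$system == sys, ] else ann
        de_set <- unique(unlist(results$de$selection$sets))
        tab <- fisher_enrichment(de_set, background, a,
                                 fdr_cut = config$enrich_fdr)
        emit(tab, sprintf("enrichment_%s.tsv", sys), "enrichment")
        enr[[sys]] <- tab
      }
      note("enrich: fdr=%.3g systems=%s", config$enrich_fdr,
           paste(systems, collapse = ","))
      results$enrichment <- enr
    })
  }

  if ("qc" %in% config$stages) {
    run("qc", {
      logged <- log2(sweep(counts + 0.5, 2L, colSums(counts), `/`) * 1e6)
      sd_ <- sample_distances(logged, top_k = min(config$top_k, nrow(counts)))
      emit(data.frame(sample_id = rownames(sd_$dist), sd_$dist,
                      check.names = FALSE), "sample_distances.tsv",
           "distances")
      emit(data.frame(sample_id = rownames(sd_$mds), sd_$mds),
           "sample_mds.tsv", "mds")
      writeLines(sd_$newick, file.path(config$out_dir, "sample_tree.nwk"))
      paths <- c(paths, file.path(config$out_dir, "sample_tree.nwk"))
      note("qc: top_k=%d", sd_$top_k)
      results$distances <- sd_
    })
  }

  manifest <- c(
    sprintf("seed\t%d", config$seed),
    sprintf("stages\t%s", paste(config$stages, collapse = ",")),
    vapply(c(config$counts, config$design, config$covariates,
             config$annotation),
           function(p) sprintf("input\t%s\t%s", p, unname(tools::md5sum(p))),
           character(1)),
    vapply(sort(unique(paths)),
           function(p) sprintf("output\t%s\t%s", basename(p),
                               unname(tools::md5sum(p))), character(1)))
  writeLines(manifest, file.path(config$out_dir, "manifest.tsv"))
  writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  invisible(c(results, list(paths = paths, config = config)))
}
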