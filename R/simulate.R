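#' Simulation configuration for synthetic tissue-resolved RNA-Seq experiments
#'
#' Collects every tunable of the synthetic-data generator: the population law
#' of the per-gene fixed effects (one per tissue-by-treatment cell, on the
#' natural-log reads-per-million scale), the log-normal dispersion population,
#' the gamma hyperpriors of the random-effect precisions, library sizes, the
#' length/GC trend, and the planted-truth fractions.
#'
#' The 8 cells are ordered Mz, Ez, Co, St under control then the same four
#' tissues under water deficit. Fixed effects are parameterised so that a gene
#' with average length and GC in a library of \code{mean_library_size} reads
#' has expected count \code{exp(beta) * mean_library_size / 1e6}; i.e. beta is
#' the log of the expected reads per million mapped reads. Deficit-cell
#' effects are tied to their control counterparts:
#' \code{beta_deficit = beta_control + (beta_mean[k+4] - beta_mean[k]) +
#' planted_log2fc * log(2)}, so genes without a planted effect are exact nulls
#' for the treatment contrast.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Biological replicates per cell (default 4).
#' @param libraries_per_lane Libraries pooled per lane (default 4).
#' @param beta_mean,beta_var Length-8 mean and (diagonal) variance of the
#'   fixed-effect population, natural-log RPM scale.
#' @param log_disp_mean,log_disp_var Moments of the log negative-binomial
#'   dispersion population (dispersion phi in Var = mu + phi mu^2).
#' @param replicate_precision_shape,replicate_precision_rate Gamma law of the
#'   per-gene replicate-effect precision.
#' @param lane_precision_shape,lane_precision_rate Gamma law from which the
#'   single (gene-independent) lane-effect precision is drawn. Defaults give a
#'   realistic lane artifact (precision mean 100, lane-effect sd about 0.1).
#' @param mean_library_size Geometric-mean target for log-normally drawn
#'   library sizes (default 1e6; all downstream statistics are scale free).
#' @param library_size_sdlog Log-sd of library sizes.
#' @param fraction_inactive Fraction of genes forced inactive in a random
#'   subset of cells (effects pushed far below the activity threshold).
#' @param inactive_cell_prob Probability that each of the 8 cells of a
#'   forced-inactive gene is deactivated (default 0.7; 1 deactivates every
#'   cell, yielding never-active genes).
#' @param fraction_de Fraction of genes given a planted per-tissue treatment
#'   effect of size \code{de_log2fc} (random sign, random tissue subset).
#' @param de_log2fc Absolute planted log2 fold change for DE genes.
#' @param activity_threshold Natural-log RPM boundary defining the generated
#'   truth \code{truly_active}; default \code{log(2)} (2 reads per million).
#' @param min_separation If positive, betas falling within this many
#'   natural-log units of \code{activity_threshold} are reflected out of the
#'   dead zone so that truth labels are well separated (used by recovery
#'   studies; default 0 = pure normal draws).
#' @param inactive_offset How far below the threshold forced-inactive cells
#'   are placed (natural-log units).
#' @param length_slope Slope of expected log count in centred log gene length.
#' @param gc_lin,gc_quad Linear and quadratic coefficients of expected log
#'   count in centred GC fraction.
#' @param seed Integer seed for all generator randomness.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 2000,
                       n_replicates = 4,
                       libraries_per_lane = 4,
                       beta_mean = rep(2.5, 8),
                       beta_var = rep(1.5, 8),
                       log_disp_mean = log(0.1),
                       log_disp_var = 0.25,
                       replicate_precision_shape = 10,
                       replicate_precision_rate = 0.1,
                       lane_precision_shape = 50,
                       lane_precision_rate = 0.5,
                       mean_library_size = 1e6,
                       library_size_sdlog = 0.15,
                       fraction_inactive = 0.3,
                       inactive_cell_prob = 0.7,
                       fraction_de = 0.1,
                       de_log2fc = 2,
                       activity_threshold = log(2),
                       min_separation = 0,
                       inactive_offset = 2.5,
                       length_slope = 1,
                       gc_lin = 0.5,
                       gc_quad = -2,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              libraries_per_lane = as.integer(libraries_per_lane),
              beta_mean = as.numeric(beta_mean),
              beta_var = as.numeric(beta_var),
              log_disp_mean = log_disp_mean, log_disp_var = log_disp_var,
              replicate_precision_shape = replicate_precision_shape,
              replicate_precision_rate = replicate_precision_rate,
              lane_precision_shape = lane_precision_shape,
              lane_precision_rate = lane_precision_rate,
              mean_library_size = mean_library_size,
              library_size_sdlog = library_size_sdlog,
              fraction_inactive = fraction_inactive,
              inactive_cell_prob = inactive_cell_prob,
              fraction_de = fraction_de,
              de_log2fc = de_log2fc,
              activity_threshold = activity_threshold,
              min_separation = min_separation,
              inactive_offset = inactive_offset,
              length_slope = length_slope,
              gc_lin = gc_lin, gc_quad = gc_quad,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (length(cfg$beta_mean) != 8L || length(cfg$beta_var) != 8L)
    stop("beta_mean and beta_var must have length 8")
  if (any(cfg$beta_var < 0)) stop("beta_var must be non-negative")
  if (cfg$log_disp_var < 0) stop("log_disp_var must be non-negative")
  pos <- c("replicate_precision_shape", "replicate_precision_rate",
           "lane_precision_shape", "lane_precision_rate",
           "mean_library_size")
  for (p in pos) if (cfg[[p]] <= 0) stop(sprintf("'%s' must be positive", p))
  stopifnot_scalar_prob(cfg$fraction_inactive, "fraction_inactive")
  stopifnot_scalar_prob(cfg$fraction_de, "fraction_de")
  if ((8L * cfg$n_replicates) %% cfg$libraries_per_lane != 0L)
    stop("8 * n_replicates must be divisible by libraries_per_lane")
  invisible(cfg)
}

#' Draw per-gene population parameters
#'
#' Samples, for each gene, the 8 tissue-by-treatment fixed effects, the log
#' negative-binomial dispersion, gene length and GC content, and the planted
#' ground truth (activity labels and per-tissue treatment log2 fold changes).
#' Control-cell effects are iid normal draws; deficit-cell effects equal the
#' control effect plus the configured population mean shift plus any planted
#' effect, so the treatment contrast of a non-DE gene is exactly zero.
#'
#' @param config A [sim_config()] object.
#' @return A list of class \code{gene_params} with elements \code{gene_id},
#'   \code{beta} (genes x 8), \code{log_dispersion}, \code{length_bp},
#'   \code{gc_fraction}, \code{truly_active} (genes x 8 logical),
#'   \code{planted_log2fc} (genes x 4), and the generating config.
#' @export
draw_gene_params <- function(config) {
  validate_sim_config(config)
  g <- config$n_genes
  with_seed(config$seed, {
    beta <- matrix(NA_real_, g, 8L,
                   dimnames = list(NULL, cell_names()))
    for (k in 1:4)
      beta[, k] <- rnorm(g, config$beta_mean[k], sqrt(config$beta_var[k]))
    planted <- matrix(0, g, 4L, dimnames = list(NULL, TISSUES))
    if (config$fraction_de > 0) {
      n_de <- round(config$fraction_de * g)
      de_idx <- sample.int(g, n_de)
      for (i in de_idx) {
        tset <- which(runif(4) < 0.5)
        if (!length(tset)) tset <- sample.int(4L, 1L)
        planted[i, tset] <- config$de_log2fc *
          sample(c(-1, 1), length(tset), replace = TRUE)
      }
    }
    for (k in 1:4)
      beta[, k + 4L] <- beta[, k] +
        (config$beta_mean[k + 4L] - config$beta_mean[k]) +
        planted[, k] * log(2)

    thr <- config$activity_threshold
    if (config$fraction_inactive > 0) {
      n_off <- round(config$fraction_inactive * g)
      off_idx <- sample.int(g, n_off)
      for (i in off_idx) {
        # deactivate a random subset of cells, producing a mix of stable and
        # dynamic truth patterns
        cells <- which(runif(8) < config$inactive_cell_prob)
        if (!length(cells)) cells <- sample.int(8L, 1L)
        beta[i, cells] <- thr - config$inactive_offset +
          rnorm(length(cells), 0, 0.25)
      }
    }
    if (config$min_separation > 0) {
      lo <- thr - config$min_separation
      hi <- thr + config$min_separation
      inside <- beta > lo & beta < hi
      beta[inside] <- ifelse(beta[inside] >= thr,
                             hi + (beta[inside] - thr), lo - (thr - beta[inside]))
      # keep deficit = control + planted consistent after reflection
      for (k in 1:4) {
        drift <- beta[, k + 4L] - (beta[, k] + planted[, k] * log(2) +
                                   (config$beta_mean[k + 4L] - config$beta_mean[k]))
        # genes whose control cell moved: recompute deficit only where the
        # pair was originally tied and neither cell was forced inactive
        adj <- abs(drift) > 1e-12 & !inside[, k + 4L] & inside[, k]
        beta[adj, k + 4L] <- beta[adj, k] + planted[adj, k] * log(2) +
          (config$beta_mean[k + 4L] - config$beta_mean[k])
      }
    }

    log_disp <- rnorm(g, config$log_disp_mean, sqrt(config$log_disp_var))
    length_bp <- pmax(200L, as.integer(round(rlnorm(g, log(1500), 0.6))))
    gc_fraction <- rbeta(g, 12.5, 12.5)

    params <- list(
      gene_id = sprintf("gene%05d", seq_len(g)),
      beta = beta,
      log_dispersion = log_disp,
      length_bp = length_bp,
      gc_fraction = gc_fraction,
      truly_active = beta > thr,
      planted_log2fc = planted,
      config = config)
    class(params) <- "gene_params"
    params
  })
}

#' Simulate a read-count matrix under the generative model
#'
#' Draws negative-binomial counts whose log mean is the sum of a library-size
#' offset, a length/GC covariate trend, the gene's tissue-by-treatment fixed
#' effect, a lane effect shared by all genes in a lane, and a per-gene
#' biological-replicate effect. Lane effects are drawn once per lane from a
#' normal with gamma-drawn precision; replicate effects are drawn per gene and
#' replicate id with per-gene gamma-drawn precisions.
#'
#' @param params A [draw_gene_params()] result.
#' @param design A design table from [generate_design()].
#' @param seed Optional seed; defaults to \code{config$seed + 1} so parameter
#'   draws and count draws are independent streams.
#' @return A list of class \code{sim_counts}: \code{counts} (integer genes x
#'   samples), \code{design}, \code{gene_covariates}, \code{lib_sizes},
#'   \code{offsets_true}, \code{lane_effects}, \code{params}.
#' @export
simulate_counts <- function(params, design, seed = NULL) {
  if (!inherits(params, "gene_params")) stop("params must come from draw_gene_params()")
  validate_design(design)
  cfg <- params$config
  g <- cfg$n_genes
  n <- nrow(design)
  cells <- cell_index(design)
  seed <- seed %||% (cfg$seed + 1L)

  with_seed(seed, {
    lib_sizes <- rlnorm(n, log(cfg$mean_library_size) -
                          cfg$library_size_sdlog^2 / 2, cfg$library_size_sdlog)
    names(lib_sizes) <- design$sample_id

    lanes <- unique(design$lane)
    tau_lane <- rgamma(1, cfg$lane_precision_shape, cfg$lane_precision_rate)
    lane_effects <- rnorm(length(lanes), 0, 1 / sqrt(tau_lane))
    names(lane_effects) <- lanes

    reps <- sort(unique(design$replicate))
    tau_rep <- rgamma(g, cfg$replicate_precision_shape,
                      cfg$replicate_precision_rate)
    rep_effects <- matrix(rnorm(g * length(reps), 0, rep(1 / sqrt(tau_rep),
                                                         length(reps))),
                          g, length(reps))

    covar <- covariate_trend(params$length_bp, params$gc_fraction, cfg)
    # read competition: sequencing depth is fixed, so samples whose
    # transcript mass grows (e.g. by induced genes) yield proportionally
    # fewer reads per transcript. The mass is taken over the fixed effects
    # only and centred at its geometric mean, preserving the overall
    # reads-per-million scale; lane and replicate effects stay outside the
    # renormalisation, acting as depth artifacts relative to the recorded
    # library size (which is what makes them estimable downstream).
    expr_fixed <- exp(covar + params$beta[, cells, drop = FALSE])
    mass <- colSums(expr_fixed)
    r_s <- mass / geometric_mean(mass)
    # offset as generated: library/composition scaling plus the length/GC
    # trend (random effects sit on top of it)
    off <- outer(covar, log(lib_sizes / 1e6 / r_s), `+`)
    eta <- off + params$beta[, cells, drop = FALSE] +
      matrix(lane_effects[design$lane], g, n, byrow = TRUE) +
      rep_effects[, match(design$replicate, reps), drop = FALSE]
    mu <- exp(eta)
    phi <- exp(params$log_dispersion)
    counts <- matrix(rnbinom(g * n, size = rep(1 / phi, n), mu = as.vector(mu)),
                     g, n)
    storage.mode(counts) <- "integer"
    dimnames(counts) <- list(params$gene_id, design$sample_id)

    out <- list(counts = counts,
                design = design,
                gene_covariates = data.frame(
                  gene_id = params$gene_id,
                  length_bp = params$length_bp,
                  gc_fraction = params$gc_fraction,
                  stringsAsFactors = FALSE),
                lib_sizes = lib_sizes,
                offsets_true = off,
                lane_effects = lane_effects,
                params = params)
    class(out) <- "sim_counts"
    out
  })
}

# Expected log-count contribution of gene length and GC, centred so that a
# gene of average (log) length and GC has zero trend.
covariate_trend <- function(length_bp, gc_fraction, cfg) {
  ll <- log(length_bp) - mean(log(length_bp))
  gg <- gc_fraction - mean(gc_fraction)
  cfg$length_slope * ll + cfg$gc_lin * gg + cfg$gc_quad * gg^2
}

#' Simulate a complete experiment in one call
#'
#' Convenience wrapper: [generate_design()], [draw_gene_params()] and
#' [simulate_counts()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return A \code{sim_counts} list (see [simulate_counts()]).
#' @export
simulate_experiment <- function(config = sim_config()) {
  design <- generate_design(config$n_replicates, config$libraries_per_lane,
                            seed = config$seed)
  params <- draw_gene_params(config)
  simulate_counts(params, design)
}

#' Write a simulated experiment to TSV fixtures
#'
#' Emits \code{counts.tsv}, \code{design.tsv}, \code{gene_covariates.tsv} and
#' \code{truth.tsv} (per-gene activity booleans for the 8 cells plus the 4
#' planted per-tissue log2 fold changes) under \code{dir}. The files
#' round-trip losslessly through [read_counts()], [read_design()] and
#' [read_covariates()].
#'
#' @param sim A \code{sim_counts} object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(sim, dir) {
  if (!inherits(sim, "sim_counts")) stop("sim must come from simulate_counts()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             covariates = file.path(dir, "gene_covariates.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_counts(sim$counts, paths["counts"])
  write_tsv(sim$design, paths["design"])
  write_tsv(sim$gene_covariates, paths["covariates"])
  truth <- data.frame(gene_id = sim$params$gene_id,
                      sim$params$truly_active,
                      sim$params$planted_log2fc,
                      check.names = FALSE, stringsAsFactors = FALSE)
  names(truth) <- c("gene_id", paste0("active_", cell_names()),
                    paste0("log2fc_", TISSUES))
  write_tsv(truth, paths["truth"])
  invisible(paths)
}
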