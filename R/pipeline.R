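#' Run configuration for the end-to-end pipeline
#'
#' @param sim a [sim_config()] (synthetic input), or `NULL` with `counts`
#'   and `intensities` supplied.
#' @param methods RNA-seq normalization methods to run.
#' @param alpha FDR threshold.
#' @param lfc absolute log2 fold threshold.
#' @param k gene clusters.
#' @param loess_span array LOESS span.
#' @param outdir output directory.
#' @param seed global seed; overrides `sim$seed` when `sim` is given.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       methods = c("rpm", "rpkm", "uqs", "tmm", "kdmm"),
                       alpha = 0.05, lfc = 1, k = 10, loess_span = 0.3,
                       outdir = tempfile("normconcord_run_"), seed = 1L) {
  if (!length(methods)) stop("at least one normalization method is required")
  methods <- match.arg(methods, c("rpm", "rpkm", "uqs", "tmm", "kdmm"),
                       several.ok = TRUE)
  stopifnot(alpha > 0, alpha < 1, lfc >= 0, k >= 2)
  if (!is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, methods = methods, alpha = alpha, lfc = lfc,
                 k = k, loess_span = loess_span, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML path; top-level keys mirror [run_config()] arguments,
#'   with `sim:` holding [sim_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (is.null(y$sim)) sim_config() else do.call(sim_config, y$sim)
  args <- y[setdiff(names(y), "sim")]
  do.call(run_config, c(list(sim = sim), args))
}

#' Run the whole analysis graph on one configuration
#'
#' simulate (or load) paired count/intensity matrices; normalize the counts
#' by every requested method and the intensities by LOESS; fit the per-gene
#' ANOVA and call differential genes for each; assemble the concordance
#' report; recompute the packaged fermentation/coverage summaries; and
#' write everything plus a manifest (seed, config hash, per-file MD5
#' checksums, and the tuning decisions actually used) under `outdir`.
#' Identical configuration and seed reproduce identical checksums.
#'
#' @param config a [run_config()].
#' @param counts,intensities optional pre-built `expr_matrix` inputs used
#'   when `config$sim` is `NULL`.
#' @return the manifest list, invisibly; all outputs are files in
#'   `config$outdir`.
#' @export
run_pipeline <- function(config = run_config(), counts = NULL,
                         intensities = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- step("simulate", simulate_experiment(config$sim))
    counts <- sim$counts
    intensities <- sim$intensities
    truth <- sim$truth
  }
  if (is.null(counts) || is.null(intensities))
    stop("either a sim config or both input matrices are required")

  paths <- character(0)
  emit <- function(name, writer) {
    p <- file.path(config$outdir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }
  emit("counts.tsv", function(p)
    write_matrix(counts, p, file.path(config$outdir, "samples_rnaseq.tsv")))
  paths[["samples_rnaseq.tsv"]] <- file.path(config$outdir,
                                             "samples_rnaseq.tsv")
  emit("intensities.tsv", function(p)
    write_matrix(intensities, p,
                 file.path(config$outdir, "samples_array.tsv")))
  paths[["samples_array.tsv"]] <- file.path(config$outdir,
                                            "samples_array.tsv")

  lengths <- NULL
  if (!is.null(truth)) {
    lengths <- data.frame(gene_id = names(truth$gene_lengths),
                          length_bp = unname(truth$gene_lengths),
                          stringsAsFactors = FALSE)
    emit("gene_lengths.tsv", function(p)
      utils::write.table(lengths, p, sep = "\t", quote = FALSE,
                         row.names = FALSE))
  }

  norms <- list()
  for (m in config$methods) {
    norms[[m]] <- step(paste0("normalize_", m),
                       normalize_counts(counts, m, lengths = lengths))
    emit(paste0("norm_", m, ".tsv"), function(p)
      write_matrix(norms[[m]]$normalized, p))
    emit(paste0("factors_", m, ".tsv"), function(p)
      utils::write.table(
        data.frame(sample_id = names(norms[[m]]$factors),
                   factor = unname(norms[[m]]$factors),
                   size_factor = unname(size_factors(norms[[m]]))),
        p, sep = "\t", quote = FALSE, row.names = FALSE))
  }
  arr_norm <- step("normalize_loess",
                   normalize_loess(intensities, span = config$loess_span))
  emit("norm_array.tsv", function(p) write_matrix(arr_norm$normalized, p))

  de_tables <- list()
  for (m in config$methods) {
    de_tables[[m]] <- step(paste0("detest_", m),
                           fit_anova(norms[[m]], alpha = config$alpha,
                                     lfc = config$lfc))
    emit(paste0("de_", m, ".tsv"), function(p)
      write_report(as.data.frame(de_tables[[m]]), p))
  }
  de_tables[["array"]] <- step("detest_array",
                               fit_anova(arr_norm, alpha = config$alpha,
                                         lfc = config$lfc))
  emit("de_array.tsv", function(p)
    write_report(as.data.frame(de_tables[["array"]]), p))

  concord <- step("concordance", concordance_report(
    de_tables,
    norm_results = c(norms, list(array = arr_norm)),
    counts_log2 = norms[[config$methods[1]]]$normalized,
    intens_log2 = arr_norm$normalized,
    k = config$k))
  emit("concordance.json", function(p) write_report(concord, p))

  ferm <- read_fermentation_table()
  summaries <- step("summaries", list(
    glucose_conversion_pct = list(
      populus = glucose_conversion(ferm, "populus"),
      switchgrass = glucose_conversion(ferm, "switchgrass")),
    combined_product_ratio_37h = as.numeric(
      product_ratio(ferm, 37, "populus", "combined"))))
  emit("summaries.json", function(p) write_report(summaries, p))

  cfg_path <- file.path(config$outdir, "config.json")
  cfg_ser <- unclass(config)
  cfg_ser$outdir <- NULL  # paths excluded so the config hash is portable
  jsonlite::write_json(unclass_deep(cfg_ser), cfg_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths[["config.json"]] <- cfg_path

  manifest <- list(
    package = "normconcord",
    version = as.character(utils::packageVersion("normconcord")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    params = list(
      pseudocount = 1, zero_policy = "pseudocount",
      percentile_rule = "type7_linear_interpolation",
      tie_break = "stable_input_order",
      kdmm_statistic = "mode", kdmm_bandwidth = "silverman",
      tmm_trim = c(m = 0.30, a = 0.05), loess_span = config$loess_span),
    checksums = as.list(tools::md5sum(unlist(paths))))
  names(manifest$checksums) <- names(paths)
  write_report(manifest, file.path(config$outdir, "manifest.json"))
  invisible(manifest)
}
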