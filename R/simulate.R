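#' Configuration for the paired-platform simulator
#'
#' Defaults emulate the structure of the study design the package targets:
#' two substrates (populus, switchgrass) x two time points (12 h, 37 h) x
#' two biological replicate fermentations, profiled by RNA-seq (one library
#' per biological sample) and by microarray (three technical replicates per
#' biological sample); ~3,424 genes; uniquely-mapped library sizes spanning
#' about 2-fold between the largest and smallest totals.
#'
#' @param n_genes number of genes.
#' @param n_bio biological replicates per condition.
#' @param n_tech_array technical array replicates per biological sample.
#' @param times time points in hours.
#' @param libsize_base expected mean library size (reads).
#' @param libsize_spread max/min ratio of expected library sizes (>= 1).
#' @param de_fraction fraction of genes carrying condition effects.
#' @param effect_log2_range `c(low, high)` of absolute log2 effect sizes.
#' @param effect_sign_balance fraction of up-effects (1 = all up).
#' @param nb_dispersion negative-binomial dispersion alpha in
#'   `Var = mu + alpha * mu^2`.
#' @param gene_mean_log2_sd SD of log2 gene baseline means across genes.
#' @param array_noise_sd SD (log2 scale) of per-measurement array noise.
#' @param array_affinity_sd SD of the gene-specific probe-affinity offset
#'   (log2 scale); the offset is constant across samples so it cancels in
#'   contrasts but degrades absolute cross-platform correlation.
#' @param gene_length_range_bp range of simulated gene lengths in bp.
#' @param seed integer seed; expanded into independent per-stream sub-seeds.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 3424L,
                       n_bio = 2L,
                       n_tech_array = 3L,
                       times = c(12, 37),
                       libsize_base = 2e6,
                       libsize_spread = 2.0,
                       de_fraction = 0.10,
                       effect_log2_range = c(1, 4),
                       effect_sign_balance = 0.5,
                       nb_dispersion = 0.05,
                       gene_mean_log2_sd = 2.0,
                       array_noise_sd = 0.35,
                       array_affinity_sd = 1.0,
                       gene_length_range_bp = c(200L, 6000L),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_bio = as.integer(n_bio),
              n_tech_array = as.integer(n_tech_array), times = times,
              libsize_base = libsize_base, libsize_spread = libsize_spread,
              de_fraction = de_fraction,
              effect_log2_range = effect_log2_range,
              effect_sign_balance = effect_sign_balance,
              nb_dispersion = nb_dispersion,
              gene_mean_log2_sd = gene_mean_log2_sd,
              array_noise_sd = array_noise_sd,
              array_affinity_sd = array_affinity_sd,
              gene_length_range_bp = gene_length_range_bp,
              seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 2, cfg$n_bio >= 1, cfg$n_tech_array >= 1,
            length(cfg$times) == 2, all(cfg$times > 0),
            cfg$libsize_spread >= 1, cfg$de_fraction >= 0,
            cfg$de_fraction <= 1, cfg$nb_dispersion > 0,
            cfg$gene_mean_log2_sd > 0, cfg$array_noise_sd >= 0,
            cfg$array_affinity_sd >= 0,
            cfg$effect_log2_range[1] > 0,
            cfg$effect_log2_range[2] >= cfg$effect_log2_range[1],
            cfg$effect_sign_balance >= 0, cfg$effect_sign_balance <= 1)
  class(cfg) <- "sim_config"
  cfg
}

# Design grid of biological samples: substrate x time x bio_rep.
.bio_design <- function(cfg) {
  d <- expand.grid(bio_rep = seq_len(cfg$n_bio),
                   time_h = cfg$times,
                   substrate = c("populus", "switchgrass"),
                   stringsAsFactors = FALSE)
  d <- d[, c("substrate", "time_h", "bio_rep")]
  d$condition <- paste0(d$substrate, "_", format(d$time_h, trim = TRUE), "h")
  d
}

#' Simulate a paired RNA-seq + microarray experiment with known truth
#'
#' Counts for gene g in RNA-seq sample j are negative-binomial with mean
#' `s_j * mu_g * 2^beta(g, cond(j))` and dispersion `nb_dispersion`
#' (`Var = mu + alpha mu^2`). Gene baselines `mu_g` are lognormal; library
#' size factors `s_j` are geometrically spaced with max/min equal to
#' `libsize_spread` and geometric mean 1. Array intensities for the same
#' biological samples are `log2(mu_g * 2^beta) + affinity_g +
#' N(0, array_noise_sd)` per technical replicate; the probe-affinity offset
#' `affinity_g` is shared across samples. Differential genes (fraction
#' `de_fraction`) receive substrate, time, and interaction effects, each
#' active with probability 1/2 (at least one active), magnitudes uniform on
#' `effect_log2_range`, signs up with probability `effect_sign_balance`.
#'
#' @param cfg a [sim_config()].
#' @return list with `counts` (`expr_matrix`, raw counts), `intensities`
#'   (`expr_matrix`, log2 intensities), and `truth` (class `sim_truth`):
#'   `size_factor` (per RNA-seq sample, geometric mean 1), `de_genes`
#'   (data.frame gene x contrast signed log2 effects, DE genes only),
#'   `effects` (full gene x contrast effect matrix), `gene_lengths`, and
#'   `group_log2` (true log2 group means).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  bio <- .bio_design(cfg)
  if (nrow(bio) == 0 || cfg$n_bio < 1) stop("degenerate design")
  g_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))

  # gene baselines: lognormal around libsize_base / n_genes
  set.seed(stream_seed(cfg$seed, "gene_means"))
  log2_mu <- stats::rnorm(cfg$n_genes,
                          mean = log2(cfg$libsize_base / cfg$n_genes),
                          sd = cfg$gene_mean_log2_sd)
  # recentre so expected library size is libsize_base
  mu <- 2^log2_mu
  mu <- mu * cfg$libsize_base / sum(mu)

  set.seed(stream_seed(cfg$seed, "gene_lengths"))
  lens <- sample(seq(cfg$gene_length_range_bp[1], cfg$gene_length_range_bp[2]),
                 cfg$n_genes, replace = TRUE)
  names(lens) <- g_ids

  # condition effects (log2): substrate, time, interaction components
  set.seed(stream_seed(cfg$seed, "effects"))
  n_de <- round(cfg$de_fraction * cfg$n_genes)
  de_idx <- if (n_de > 0) sort(sample.int(cfg$n_genes, n_de)) else integer(0)
  draw_mag <- function(n) stats::runif(n, cfg$effect_log2_range[1],
                                       cfg$effect_log2_range[2])
  draw_sign <- function(n)
    ifelse(stats::runif(n) < cfg$effect_sign_balance, 1, -1)
  comp <- matrix(0, cfg$n_genes, 3,
                 dimnames = list(g_ids, c("substrate", "time", "interaction")))
  if (n_de > 0) {
    active <- matrix(stats::runif(n_de * 3) < 0.5, n_de, 3)
    none <- rowSums(active) == 0
    if (any(none)) {  # every DE gene carries at least one component
      pick <- sample.int(3, sum(none), replace = TRUE)
      active[cbind(which(none), pick)] <- TRUE
    }
    vals <- matrix(draw_mag(n_de * 3) * draw_sign(n_de * 3), n_de, 3)
    comp[de_idx, ] <- vals * active
  }
  # group coding: effect relative to (switchgrass, late) baseline
  groups <- unique(bio$condition)  # populus_12h populus_37h switch_12h switch_37h
  grp <- unique(bio[, c("substrate", "time_h", "condition")])
  beta <- sapply(seq_len(nrow(grp)), function(i) {
    is_pop <- grp$substrate[i] == "populus"
    is_early <- grp$time_h[i] == min(cfg$times)
    comp[, "substrate"] * is_pop + comp[, "time"] * is_early +
      comp[, "interaction"] * (is_pop & is_early)
  })
  colnames(beta) <- grp$condition
  rownames(beta) <- g_ids

  # per-contrast true effects (left - right), the four study contrasts
  ctr <- default_contrasts(times = cfg$times)
  eff <- sapply(seq_len(nrow(ctr)), function(i)
    beta[, ctr$left[i]] - beta[, ctr$right[i]])
  colnames(eff) <- ctr$name

  # library size factors: geometric spacing, geometric mean 1
  n_s <- nrow(bio)
  if (n_s == 1) {
    sf <- 1
  } else {
    lg <- seq(-log2(cfg$libsize_spread) / 2, log2(cfg$libsize_spread) / 2,
              length.out = n_s)
    set.seed(stream_seed(cfg$seed, "size_factors"))
    sf <- 2^sample(lg)  # random assignment of depths to samples
    sf <- sf / geomean(sf)
  }

  # RNA-seq counts, sample by sample (appending samples extends the stream)
  set.seed(stream_seed(cfg$seed, "counts"))
  counts <- matrix(0L, cfg$n_genes, n_s)
  for (j in seq_len(n_s)) {
    mu_j <- sf[j] * mu * 2^beta[, bio$condition[j]]
    counts[, j] <- stats::rnbinom(cfg$n_genes, mu = mu_j,
                                  size = 1 / cfg$nb_dispersion)
  }
  seq_ids <- sprintf("rnaseq_%s_b%d", bio$condition, bio$bio_rep)
  dimnames(counts) <- list(g_ids, seq_ids)
  seq_sheet <- data.frame(sample_id = seq_ids, substrate = bio$substrate,
                          time_h = bio$time_h, bio_rep = bio$bio_rep,
                          tech_rep = 1L, platform = "rnaseq",
                          stringsAsFactors = FALSE)
  counts_em <- expression_matrix(counts, seq_sheet, "raw_count")

  # array intensities: shared mu and beta, gene affinity offset, tech reps
  set.seed(stream_seed(cfg$seed, "affinity"))
  affinity <- stats::rnorm(cfg$n_genes, 0, cfg$array_affinity_sd)
  arr <- bio[rep(seq_len(n_s), each = cfg$n_tech_array), , drop = FALSE]
  arr$tech_rep <- rep(seq_len(cfg$n_tech_array), times = n_s)
  set.seed(stream_seed(cfg$seed, "array_noise"))
  inten <- matrix(0, cfg$n_genes, nrow(arr))
  for (j in seq_len(nrow(arr))) {
    signal <- log2(mu) + beta[, arr$condition[j]] + affinity
    inten[, j] <- signal + stats::rnorm(cfg$n_genes, 0, cfg$array_noise_sd)
  }
  arr_ids <- sprintf("array_%s_b%d_t%d", arr$condition, arr$bio_rep,
                     arr$tech_rep)
  dimnames(inten) <- list(g_ids, arr_ids)
  arr_sheet <- data.frame(sample_id = arr_ids, substrate = arr$substrate,
                          time_h = arr$time_h, bio_rep = arr$bio_rep,
                          tech_rep = arr$tech_rep, platform = "array",
                          stringsAsFactors = FALSE)
  inten_em <- expression_matrix(inten, arr_sheet, "log2_intensity")

  de_tab <- eff[de_idx, , drop = FALSE]
  truth <- structure(list(size_factor = stats::setNames(sf, seq_ids),
                          de_genes = de_tab,
                          effects = eff,
                          gene_lengths = lens,
                          group_log2 = log2(mu) + beta,
                          config = cfg),
                     class = "sim_truth")
  list(counts = counts_em, intensities = inten_em, truth = truth)
}

#' Simulate a null experiment (no differential expression)
#'
#' Identical to [simulate_experiment()] with `de_fraction` forced to 0.
#' @param cfg a [sim_config()].
#' @return as [simulate_experiment()]; `truth$de_genes` has zero rows.
#' @export
simulate_null <- function(cfg = sim_config()) {
  cfg$de_fraction <- 0
  simulate_experiment(cfg)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", length(x$gene_lengths), " genes; ",
      nrow(x$de_genes), " DE genes; size factors span ",
      signif(max(x$size_factor) / min(x$size_factor), 3), "-fold\n", sep = "")
  invisible(x)
}
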