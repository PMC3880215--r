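#' Scaling normalization of RNA-seq counts and LOESS array normalization
#'
#' Six methods share a common result container (`norm_result`):
#' * `rpm` — reads per million mapped reads; linear value
#'   `x * 1e6 / N_j` with `N_j` the column total.
#' * `rpkm` — reads per kilobase per million; `x * 1e9 / (N_j * L_g)` with
#'   gene length `L_g` in bp.
#' * `uqs` — upper-quartile scaling: equalizes the 75th percentile of the
#'   nonzero counts of each sample.
#' * `tmm` — trimmed mean of M values against a reference sample: a doubly
#'   trimmed, precision-weighted mean of per-gene log ratios.
#' * `kdmm` — kernel-density mode of M values against a geometric-mean
#'   pseudo-reference: the location of the peak of a Gaussian-kernel density
#'   fitted to the per-gene log2 ratios.
#' * `loess` — microarray intensity normalization: one round of locally
#'   weighted regression of each sample's deviation on the per-gene mean
#'   intensity, subtracted.
#'
#' Zero handling: genes with zero counts in every sample are removed before
#' any analysis. Remaining zero cells either receive a pseudocount (default
#' 1) on the normalized linear scale before the log2 transform, or are
#' treated as missing (`zero_policy = "missing"`) and excluded pairwise
#' downstream.
#'
#' All percentiles use linear interpolation between order statistics (R
#' quantile type 7); ties at percentile or trimming boundaries are broken by
#' stable input gene order.
#'
#' @name normalization
NULL

# remove genes with zero counts in all samples (pre-analysis filter)
drop_all_zero <- function(em) {
  keep <- rowSums(em$values) > 0
  if (!all(keep))
    message(sum(!keep), " gene(s) with no read counts removed before analysis")
  subset_matrix(em, genes = keep)
}

# log2 transform of a normalized linear matrix with the zero policy applied
# to cells whose *raw* count was zero.
log2_linear <- function(linear, raw_zero, pseudocount, zero_policy) {
  if (zero_policy == "pseudocount") {
    linear[raw_zero] <- linear[raw_zero] + pseudocount
    log2(linear)
  } else {
    linear[raw_zero] <- NA_real_
    log2(linear)
  }
}

new_norm_result <- function(method, factors, normalized, reference_id,
                            params) {
  stopifnot(all(factors > 0))
  structure(list(method = method, factors = factors, normalized = normalized,
                 reference_id = reference_id, params = params),
            class = "norm_result")
}

#' @export
print.norm_result <- function(x, ...) {
  cat("<norm_result> method ", x$method, "; ", ncol(x$normalized$values),
      " samples, ", nrow(x$normalized$values), " genes\n", sep = "")
  cat("  factors: ", paste(signif(x$factors, 4), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Per-sample size factors implied by a normalization
#'
#' Returns the depth-inclusive relative size factor per sample (geometric
#' mean 1): the quantity comparable to the simulator's true library-size
#' factors. For RPM/RPKM this is the relative library size; for UQS and KDMM
#' it is the stored factor; for TMM it is the library size times the
#' composition factor, rescaled.
#'
#' @param x a `norm_result`.
#' @return named numeric vector, geometric mean 1.
#' @export
size_factors <- function(x) {
  stopifnot(inherits(x, "norm_result"))
  switch(x$method,
         RPM = , RPKM = {
           n <- x$params$lib_sizes
           n / geomean(n)
         },
         TMM = x$params$effective_factors,
         LOESS = rep(1, length(x$factors)),
         x$factors)
}

#' Reads-per-million normalization
#' @param counts an `expr_matrix` of raw counts.
#' @param pseudocount value added on the normalized linear scale to cells
#'   with raw count zero before log2.
#' @param zero_policy `"pseudocount"` or `"missing"`.
#' @return a `norm_result`; `factors` are `N_j / 1e6`.
#' @export
normalize_rpm <- function(counts, pseudocount = 1,
                          zero_policy = c("pseudocount", "missing")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(counts, "expr_matrix"),
            counts$value_kind == "raw_count")
  em <- drop_all_zero(counts)
  N <- colSums(em$values)
  if (any(N <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(em$values)[N <= 0], collapse = ", "))
  linear <- sweep(em$values, 2, 1e6 / N, `*`)
  norm <- expression_matrix(
    log2_linear(linear, em$values == 0, pseudocount, zero_policy),
    em$samples, "log2_count")
  new_norm_result("RPM", stats::setNames(N / 1e6, colnames(em$values)), norm,
                  "none",
                  list(pseudocount = pseudocount, zero_policy = zero_policy,
                       lib_sizes = N))
}

#' Reads-per-kilobase-per-million normalization
#' @inheritParams normalize_rpm
#' @param lengths data.frame with `gene_id` and `length_bp` (see
#'   [read_gene_lengths()]); genes missing from the annotation are dropped
#'   with a logged count rather than given a default length.
#' @return a `norm_result`.
#' @export
normalize_rpkm <- function(counts, lengths, pseudocount = 1,
                           zero_policy = c("pseudocount", "missing")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(counts, "expr_matrix"),
            counts$value_kind == "raw_count")
  em <- drop_all_zero(counts)
  idx <- match(rownames(em$values), lengths$gene_id)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " gene(s) without annotated length dropped")
    em <- subset_matrix(em, genes = !is.na(idx))
    idx <- idx[!is.na(idx)]
  }
  L <- lengths$length_bp[idx]
  N <- colSums(em$values)
  if (any(N <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(em$values)[N <= 0], collapse = ", "))
  linear <- sweep(em$values / L, 2, 1e9 / N, `*`)
  norm <- expression_matrix(
    log2_linear(linear, em$values == 0, pseudocount, zero_policy),
    em$samples, "log2_count")
  new_norm_result("RPKM", stats::setNames(N / 1e6, colnames(em$values)),
                  norm, "none",
                  list(pseudocount = pseudocount, zero_policy = zero_policy,
                       lib_sizes = N, n_dropped_no_length = sum(is.na(idx))))
}

# 75th percentile of the nonzero counts of each column (type-7 quantile)
upper_quartiles <- function(values) {
  apply(values, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) return(0)
    unname(stats::quantile(nz, 0.75, type = 7))
  })
}

#' Upper-quartile scaling normalization
#'
#' The scaling factor of sample j is its 75th percentile of nonzero gene
#' counts divided by the geometric mean of those percentiles across samples,
#' so that post-normalization upper quartiles are equal.
#'
#' @inheritParams normalize_rpm
#' @return a `norm_result`; `factors` have geometric mean 1.
#' @export
normalize_uqs <- function(counts, pseudocount = 1,
                          zero_policy = c("pseudocount", "missing")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(counts, "expr_matrix"),
            counts$value_kind == "raw_count")
  em <- drop_all_zero(counts)
  q <- upper_quartiles(em$values)
  if (any(q <= 0))
    stop("zero upper quartile for sample(s): ",
         paste(colnames(em$values)[q <= 0], collapse = ", "))
  s <- q / geomean(q)
  linear <- sweep(em$values, 2, s, `/`)
  norm <- expression_matrix(
    log2_linear(linear, em$values == 0, pseudocount, zero_policy),
    em$samples, "log2_count")
  new_norm_result("UQS", stats::setNames(s, colnames(em$values)), norm,
                  "none",
                  list(pseudocount = pseudocount, zero_policy = zero_policy,
                       upper_quartiles = q, lib_sizes = colSums(em$values)))
}

# TMM log2 factor of sample j against reference r (shared library sizes).
# Genes positive in both; double trim on M (trim_m each tail) and
# A (trim_a each tail); precision-weighted mean of retained M.
tmm_pair_log2 <- function(xj, xr, Nj, Nr, trim_m = 0.30, trim_a = 0.05,
                          min_genes = 20) {
  keep <- xj > 0 & xr > 0
  xj <- xj[keep]; xr <- xr[keep]
  M <- log2((xj / Nj) / (xr / Nr))
  A <- 0.5 * log2((xj / Nj) * (xr / Nr))
  n <- length(M)
  if (n < min_genes) stop("fewer than ", min_genes, " usable genes for TMM")
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (sum(sel) < min_genes)
    stop("fewer than ", min_genes, " genes survive TMM trimming")
  v <- (Nj - xj[sel]) / (Nj * xj[sel]) + (Nr - xr[sel]) / (Nr * xr[sel])
  sum(M[sel] / v) / sum(1 / v)
}

#' Trimmed-mean-of-M-values normalization
#'
#' For each sample against a reference sample, per-gene log2 ratios (M) and
#' average log2 abundances (A) of library-size-scaled counts are computed on
#' genes positive in both samples; the top and bottom `trim_m` of M and
#' `trim_a` of A are discarded and the factor is `2^` the
#' precision-weighted mean of the retained M (weights are inverse asymptotic
#' binomial variances). Stored `factors` are composition factors rescaled to
#' geometric mean 1; the normalized matrix divides counts by the
#' depth-inclusive effective factor (`N_j` times the composition factor,
#' rescaled), available via [size_factors()].
#'
#' @inheritParams normalize_rpm
#' @param ref reference sample id, or `"auto"`: the sample whose nonzero
#'   75th percentile is closest to the across-sample mean of those
#'   percentiles.
#' @param trim_m,trim_a trim fraction per tail for M and A.
#' @param min_genes minimum genes that must survive trimming.
#' @return a `norm_result`.
#' @export
normalize_tmm <- function(counts, ref = "auto", trim_m = 0.30, trim_a = 0.05,
                          min_genes = 20, pseudocount = 1,
                          zero_policy = c("pseudocount", "missing")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(counts, "expr_matrix"),
            counts$value_kind == "raw_count")
  em <- drop_all_zero(counts)
  ids <- colnames(em$values)
  N <- colSums(em$values)
  if (identical(ref, "auto")) {
    q <- upper_quartiles(em$values)
    ref <- ids[which.min(abs(q - mean(q)))]
  }
  if (!ref %in% ids) stop("reference sample '", ref, "' not in matrix")
  r <- match(ref, ids)
  logf <- vapply(seq_along(ids), function(j) {
    if (j == r) return(0)
    tmm_pair_log2(em$values[, j], em$values[, r], N[j], N[r],
                  trim_m, trim_a, min_genes)
  }, numeric(1))
  f <- 2^logf
  f <- f / geomean(f)
  eff <- N * f
  eff <- eff / geomean(eff)
  linear <- sweep(em$values, 2, eff, `/`)
  norm <- expression_matrix(
    log2_linear(linear, em$values == 0, pseudocount, zero_policy),
    em$samples, "log2_count")
  new_norm_result("TMM", stats::setNames(f, ids), norm, ref,
                  list(pseudocount = pseudocount, zero_policy = zero_policy,
                       trim_m = trim_m, trim_a = trim_a,
                       min_genes = min_genes, lib_sizes = N,
                       effective_factors = stats::setNames(eff, ids)))
}

# Location statistic of a set of M values via Gaussian-kernel density.
# mode: argmax of the KDE on a dense grid, refined by golden-section search
# on the exact KDE in the winning grid cell. mean: the density mean of a
# symmetric-kernel KDE, which equals the arithmetic mean of the M values.
kdmm_location <- function(m, bandwidth = "silverman",
                          statistic = c("mode", "mean"), grid_n = 2048) {
  statistic <- match.arg(statistic)
  m <- m[is.finite(m)]
  if (length(m) < 2) stop("too few finite M values for a density fit")
  if (statistic == "mean") return(mean(m))
  # degenerate unimodal case (e.g. a sample exactly proportional to the
  # pseudo-reference): all M equal, the mode is that value
  if (diff(range(m)) < 1e-8) return(mean(m))
  h <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(m)
       else as.numeric(bandwidth)
  if (!is.finite(h) || h <= 0) stop("non-finite kernel bandwidth")
  d <- stats::density(m, bw = h, kernel = "gaussian", n = grid_n)
  if (any(!is.finite(d$y))) stop("non-finite density estimate")
  i <- which.max(d$y)
  kde <- function(x) sum(stats::dnorm(x, mean = m, sd = h))
  lo <- d$x[max(1, i - 1)]; hi <- d$x[min(grid_n, i + 1)]
  opt <- stats::optimize(kde, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  opt$maximum
}

#' Kernel-density mode of M values normalization
#'
#' A pseudo-reference is the per-gene geometric mean of counts across
#' samples, over genes positive in every sample. Per sample, the M values
#' `log2(x_gj / ref_g)` are summarized by the location of the peak of a
#' Gaussian-kernel density (Silverman's rule bandwidth by default); the
#' scaling factor is `2^` that location, rescaled to geometric mean 1.
#' `statistic = "mean"` uses the density mean instead, which for a
#' symmetric kernel equals the arithmetic mean of M.
#'
#' @inheritParams normalize_rpm
#' @param bandwidth `"silverman"` (Silverman's rule of thumb) or a positive
#'   number (log2 units).
#' @param statistic `"mode"` (default) or `"mean"`.
#' @param min_positive minimum number of genes positive in all samples.
#' @return a `norm_result`.
#' @export
normalize_kdmm <- function(counts, bandwidth = "silverman",
                           statistic = c("mode", "mean"),
                           min_positive = 50, pseudocount = 1,
                           zero_policy = c("pseudocount", "missing")) {
  statistic <- match.arg(statistic)
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(counts, "expr_matrix"),
            counts$value_kind == "raw_count", ncol(counts$values) >= 2)
  em <- drop_all_zero(counts)
  pos <- rowSums(em$values > 0) == ncol(em$values)
  if (sum(pos) < min_positive)
    stop("fewer than ", min_positive, " genes positive in all samples")
  x <- em$values[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(x)))
  logs <- vapply(seq_len(ncol(x)), function(j)
    kdmm_location(log2(x[, j] / ref), bandwidth, statistic), numeric(1))
  s <- 2^logs
  s <- s / geomean(s)
  linear <- sweep(em$values, 2, s, `/`)
  norm <- expression_matrix(
    log2_linear(linear, em$values == 0, pseudocount, zero_policy),
    em$samples, "log2_count")
  new_norm_result("KDMM", stats::setNames(s, colnames(em$values)), norm,
                  "pseudo-reference",
                  list(pseudocount = pseudocount, zero_policy = zero_policy,
                       bandwidth = bandwidth, statistic = statistic,
                       n_all_positive = sum(pos),
                       lib_sizes = colSums(em$values)))
}

#' LOESS normalization of log2 array intensities
#'
#' One round: for each sample, the deviation of its log2 intensities from
#' the per-gene all-sample mean is regressed on that mean by locally
#' weighted regression and the fitted intensity-dependent curve is
#' subtracted.
#'
#' @param intensities an `expr_matrix` with `value_kind = "log2_intensity"`.
#' @param span LOESS span (fraction of genes in each local window).
#' @param min_genes minimum number of genes for a determined fit.
#' @return a `norm_result`; `factors` are all 1 (the correction is a curve,
#'   not a scalar).
#' @export
normalize_loess <- function(intensities, span = 0.3, min_genes = 100) {
  stopifnot(inherits(intensities, "expr_matrix"),
            intensities$value_kind == "log2_intensity")
  y <- intensities$values
  if (nrow(y) < min_genes)
    stop("LOESS normalization needs at least ", min_genes, " genes")
  abar <- rowMeans(y)
  out <- y
  for (j in seq_len(ncol(y))) {
    fit <- limma::loessFit(y[, j] - abar, abar, span = span)
    out[, j] <- y[, j] - fit$fitted
  }
  norm <- expression_matrix(out, intensities$samples, "log2_intensity")
  new_norm_result("LOESS",
                  stats::setNames(rep(1, ncol(y)), colnames(y)), norm,
                  "per-gene mean", list(span = span))
}

#' Normalize counts by a named method
#' @param counts an `expr_matrix` of raw counts.
#' @param method one of `"rpm"`, `"rpkm"`, `"uqs"`, `"tmm"`, `"kdmm"`.
#' @param lengths gene annotation (required for `"rpkm"`).
#' @param ... passed to the method function.
#' @return a `norm_result`.
#' @export
normalize_counts <- function(counts,
                             method = c("rpm", "rpkm", "uqs", "tmm", "kdmm"),
                             lengths = NULL, ...) {
  method <- match.arg(method)
  switch(method,
         rpm = normalize_rpm(counts, ...),
         rpkm = {
           if (is.null(lengths)) stop("rpkm requires gene lengths")
           normalize_rpkm(counts, lengths, ...)
         },
         uqs = normalize_uqs(counts, ...),
         tmm = normalize_tmm(counts, ...),
         kdmm = normalize_kdmm(counts, ...))
}

#' Summarize normalized value distributions across methods
#'
#' Per sample and method: the 5/25/50/75/95 percentiles, mean and SD of the
#' normalized log2 values, plus the median shift relative to the
#' un-normalized log2 values when `raw` is supplied. Methods whose mean
#' absolute median shift exceeds `shift_threshold` are flagged as markedly
#' shifting the distribution.
#'
#' @param results list of `norm_result` objects.
#' @param raw optional raw-count `expr_matrix` to measure shifts against.
#' @param shift_threshold flag threshold in log2 units.
#' @param pseudocount pseudocount for the raw log2 baseline.
#' @return data.frame with one row per method x sample, plus attribute
#'   `"flagged_methods"`.
#' @export
compare_distributions <- function(results, raw = NULL, shift_threshold = 0.5,
                                  pseudocount = 1) {
  stopifnot(length(results) >= 1)
  base_med <- NULL
  if (!is.null(raw)) {
    em <- drop_all_zero(raw)
    lv <- log2_linear(em$values + 0, em$values == 0, pseudocount,
                      "pseudocount")
    base_med <- apply(lv, 2, stats::median)
  }
  rows <- lapply(results, function(r) {
    v <- r$normalized$values
    qs <- t(apply(v, 2, stats::quantile, c(.05, .25, .5, .75, .95),
                  na.rm = TRUE))
    df <- data.frame(method = r$method, sample_id = colnames(v),
                     q05 = qs[, 1], q25 = qs[, 2], q50 = qs[, 3],
                     q75 = qs[, 4], q95 = qs[, 5],
                     mean = colMeans(v, na.rm = TRUE),
                     sd = apply(v, 2, stats::sd, na.rm = TRUE),
                     stringsAsFactors = FALSE)
    if (!is.null(base_med))
      df$median_shift <- df$q50 - base_med[match(df$sample_id,
                                                 names(base_med))]
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  flagged <- character(0)
  if (!is.null(base_med)) {
    sh <- tapply(abs(out$median_shift), out$method, mean)
    flagged <- names(sh)[sh > shift_threshold]
  }
  attr(out, "flagged_methods") <- flagged
  out
}
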