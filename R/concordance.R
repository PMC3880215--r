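#' Pearson correlation between biological replicates within each condition
#'
#' For every (substrate, time, platform) condition, the Pearson correlation
#' of log2 values between each pair of biological replicates, with missing
#' cells excluded pairwise. A constant replicate vector yields `NA` with a
#' warning.
#'
#' @param em an `expr_matrix` of log2 values (collapse technical replicates
#'   first for arrays).
#' @return data.frame with columns `platform`, `condition`, `rep_a`,
#'   `rep_b`, `pearson_r`.
#' @export
replicate_correlation <- function(em) {
  stopifnot(inherits(em, "expr_matrix"), em$value_kind != "raw_count")
  if (any(em$samples$tech_rep != 1L)) em <- collapse_technical(em)
  s <- em$samples
  key <- paste(s$platform, condition_label(s), sep = "|")
  out <- list()
  for (k in unique(key)) {
    ix <- which(key == k)
    if (length(ix) < 2) next
    for (a in seq_along(ix)[-length(ix)]) for (b in seq((a + 1), length(ix))) {
      va <- em$values[, ix[a]]; vb <- em$values[, ix[b]]
      ok <- is.finite(va) & is.finite(vb)
      r <- if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) {
        warning("constant replicate vector; correlation undefined")
        NA_real_
      } else stats::cor(va[ok], vb[ok])
      out[[length(out) + 1]] <- data.frame(
        platform = s$platform[ix[a]],
        condition = condition_label(s[ix[a], , drop = FALSE]),
        rep_a = s$sample_id[ix[a]], rep_b = s$sample_id[ix[b]],
        pearson_r = r, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no condition has two biological replicates")
  do.call(rbind, out)
}

#' Cross-platform Spearman correlation per matched condition
#'
#' Restricts both matrices to shared gene ids, averages biological (and
#' technical) replicates within each condition on each platform, and
#' reports the Spearman rank correlation (average ranks for ties) between
#' platforms for each condition present in both.
#'
#' @param counts_log2 log2 RNA-seq `expr_matrix`.
#' @param intens_log2 log2 array `expr_matrix`.
#' @return data.frame with columns `condition`, `spearman_rho`, `n_genes`.
#' @export
cross_platform_correlation <- function(counts_log2, intens_log2) {
  stopifnot(inherits(counts_log2, "expr_matrix"),
            inherits(intens_log2, "expr_matrix"))
  shared <- intersect(rownames(counts_log2$values),
                      rownames(intens_log2$values))
  if (length(shared) < 10)
    stop("fewer than 10 shared genes between platforms")
  avg_by_condition <- function(em) {
    em <- subset_matrix(em, genes = shared)
    cond <- condition_label(em$samples)
    vapply(unique(cond), function(g)
      rowMeans(em$values[, cond == g, drop = FALSE], na.rm = TRUE),
      numeric(length(shared)))
  }
  a <- avg_by_condition(counts_log2)
  b <- avg_by_condition(intens_log2)
  conds <- intersect(colnames(a), colnames(b))
  if (!length(conds)) stop("no condition present on both platforms")
  rho <- vapply(conds, function(g) {
    ok <- is.finite(a[, g]) & is.finite(b[, g])
    stats::cor(a[ok, g], b[ok, g], method = "spearman")
  }, numeric(1))
  data.frame(condition = conds, spearman_rho = unname(rho),
             n_genes = length(shared), stringsAsFactors = FALSE)
}

#' Overlap (Venn) analysis of gene-level call sets
#'
#' Pairwise intersection counts for any number of named call sets, plus the
#' seven exclusive region counts when exactly three sets are given.
#'
#' @param call_sets named list of character vectors (gene ids called by
#'   each method/platform).
#' @return list with `sizes`, `pairwise` (symmetric count matrix), and for
#'   three sets `regions` (named exclusive-region counts) and
#'   `region_genes`.
#' @export
overlap_analysis <- function(call_sets) {
  stopifnot(is.list(call_sets), length(call_sets) >= 2,
            !is.null(names(call_sets)), all(nzchar(names(call_sets))))
  sets <- lapply(call_sets, function(s) unique(as.character(s)))
  nm <- names(sets)
  k <- length(sets)
  pw <- matrix(0L, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k))
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  out <- list(sizes = lengths(sets), pairwise = pw)
  if (k == 3) {
    u <- unique(unlist(sets))
    member <- sapply(sets, function(s) u %in% s)
    code <- member %*% c(1, 2, 4)
    labels <- c(paste0(nm[1], "_only"), paste0(nm[2], "_only"),
                paste0(nm[1], "_", nm[2], "_only"), paste0(nm[3], "_only"),
                paste0(nm[1], "_", nm[3], "_only"),
                paste0(nm[2], "_", nm[3], "_only"),
                paste0(nm[1], "_", nm[2], "_", nm[3]))
    regions <- stats::setNames(integer(7), labels)
    region_genes <- stats::setNames(vector("list", 7), labels)
    for (c0 in 1:7) {
      regions[c0] <- sum(code == c0)
      region_genes[[c0]] <- sort(u[code == c0])
    }
    out$regions <- regions
    out$region_genes <- region_genes
  }
  out
}

#' Expression rank percentiles for a gene list
#'
#' Replicates are averaged within condition; each gene's percentile is its
#' ascending rank (average ranks for ties) divided by the number of genes,
#' times 100, so the most highly expressed gene scores 100.
#'
#' @param em a log2 `expr_matrix` (e.g. the `normalized` slot of a
#'   `norm_result`).
#' @param genes gene ids to report; genes absent from the matrix are
#'   returned with `NA` percentiles.
#' @return data.frame: one row per requested gene, one percentile column
#'   per condition.
#' @export
rank_percentiles <- function(em, genes) {
  if (inherits(em, "norm_result")) em <- em$normalized
  stopifnot(inherits(em, "expr_matrix"), em$value_kind != "raw_count")
  if (any(em$samples$tech_rep != 1L)) em <- collapse_technical(em)
  cond <- condition_label(em$samples)
  n <- nrow(em$values)
  pct <- vapply(unique(cond), function(g) {
    v <- rowMeans(em$values[, cond == g, drop = FALSE], na.rm = TRUE)
    rank(v, ties.method = "average") / n * 100
  }, numeric(n))
  rownames(pct) <- rownames(em$values)
  found <- genes %in% rownames(pct)
  if (any(!found))
    message(sum(!found), " requested gene(s) absent from the matrix")
  out <- matrix(NA_real_, length(genes), ncol(pct),
                dimnames = list(genes, colnames(pct)))
  out[genes[found], ] <- pct[genes[found], ]
  data.frame(gene = genes, out, row.names = NULL, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Two-way hierarchical clustering of genes across platforms and methods
#'
#' Gene profiles from each normalization result are restricted to shared
#' genes, row-standardized within each platform/method block (per gene:
#' mean 0, SD 1; constant rows become 0), concatenated, and clustered by
#' Ward-linkage (`ward.D2`) hierarchical clustering on Euclidean distances,
#' with the tree cut to exactly `k` clusters. Columns are clustered the
#' same way for display ordering.
#'
#' @param results list of `norm_result` objects (and/or log2
#'   `expr_matrix` objects).
#' @param k number of gene clusters (default 10).
#' @return list with `gene_cluster` (named integer vector, values 1..k),
#'   `gene_order`, `sample_order`, and `k`.
#' @export
two_way_cluster <- function(results, k = 10) {
  stopifnot(length(results) >= 1, k >= 2)
  mats <- lapply(results, function(r) {
    if (inherits(r, "norm_result")) r <- r$normalized
    stopifnot(inherits(r, "expr_matrix"))
    r$values
  })
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) < k) stop("k exceeds the number of shared genes")
  std <- lapply(seq_along(mats), function(i) {
    m <- mats[[i]][shared, , drop = FALSE]
    mu <- rowMeans(m, na.rm = TRUE)
    sd <- apply(m, 1, stats::sd, na.rm = TRUE)
    sd[sd == 0 | !is.finite(sd)] <- 1
    z <- (m - mu) / sd
    z[!is.finite(z)] <- 0
    colnames(z) <- paste0(names(results)[i] %||% paste0("block", i), ".",
                          colnames(z))
    z
  })
  x <- do.call(cbind, std)
  # sort rows by id so the partition cannot depend on input gene order
  x <- x[order(rownames(x)), , drop = FALSE]
  hr <- stats::hclust(stats::dist(x), method = "ward.D2")
  hc <- stats::hclust(stats::dist(t(x)), method = "ward.D2")
  cl <- stats::cutree(hr, k = k)
  list(gene_cluster = cl, gene_order = rownames(x)[hr$order],
       sample_order = colnames(x)[hc$order], k = k)
}

#' Assemble a cross-platform concordance report
#'
#' Bundles per-method differential-expression summaries, pairwise overlap
#' counts, replicate Pearson correlations, cross-platform Spearman
#' correlations, and gene cluster assignments into one serializable report.
#'
#' @param de_tables named list of `de_table` objects (one per
#'   method/platform).
#' @param norm_results named list of `norm_result` objects used for
#'   clustering (optional).
#' @param counts_log2,intens_log2 optional log2 matrices for correlation
#'   blocks.
#' @param k clusters for [two_way_cluster()].
#' @param percentile_genes optional gene list for [rank_percentiles()]
#'   (computed on the first element of `norm_results`).
#' @return list of class `concordance_report`.
#' @export
concordance_report <- function(de_tables, norm_results = NULL,
                               counts_log2 = NULL, intens_log2 = NULL,
                               k = 10, percentile_genes = NULL) {
  stopifnot(is.list(de_tables), length(de_tables) >= 1,
            !is.null(names(de_tables)))
  summaries <- lapply(de_tables, function(d) {
    s <- call_differential(d)
    list(n_any_sig = s$n_any_sig, n_sig_fold = s$n_sig_fold)
  })
  calls <- lapply(de_tables, de_calls)
  rep <- list(method_summary = summaries)
  if (length(calls) >= 2) rep$overlap <- overlap_analysis(calls)
  if (!is.null(counts_log2)) {
    rep$replicate_pearson <- replicate_correlation(counts_log2)
    if (!is.null(intens_log2)) {
      rep$replicate_pearson_array <-
        replicate_correlation(intens_log2)
      rep$cross_platform_spearman <-
        cross_platform_correlation(counts_log2, intens_log2)
    }
  }
  if (!is.null(norm_results) && length(norm_results) >= 1) {
    ksafe <- min(k, length(Reduce(intersect,
      lapply(norm_results, function(r) rownames(r$normalized$values)))))
    rep$clusters <- two_way_cluster(norm_results, k = ksafe)
    if (!is.null(percentile_genes))
      rep$rank_percentiles <- rank_percentiles(norm_results[[1]],
                                               percentile_genes)
  }
  class(rep) <- c("concordance_report", "list")
  rep
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  for (m in names(x$method_summary))
    cat(sprintf("  %-10s any-sig %d, sig+fold %d\n", m,
                x$method_summary[[m]]$n_any_sig,
                x$method_summary[[m]]$n_sig_fold))
  if (!is.null(x$cross_platform_spearman))
    cat("  cross-platform Spearman: ",
        paste(signif(x$cross_platform_spearman$spearman_rho, 3),
              collapse = " "), "\n", sep = "")
  invisible(x)
}
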