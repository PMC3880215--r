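#' The four study contrasts over the 2 x 2 condition design
#'
#' Contrasts are differences of condition means on the log2 scale, left
#' minus right: early vs late on each substrate, and populus vs switchgrass
#' at each time point.
#'
#' @param times the two time points in hours (earlier first).
#' @return data.frame with columns `name`, `left`, `right` (condition
#'   labels `substrate_<time>h`).
#' @export
default_contrasts <- function(times = c(12, 37)) {
  t1 <- paste0(format(min(times), trim = TRUE), "h")
  t2 <- paste0(format(max(times), trim = TRUE), "h")
  pop <- function(t) paste0("populus_", t)
  swg <- function(t) paste0("switchgrass_", t)
  data.frame(
    name = c(paste0("populus_", t1, "_vs_populus_", t2),
             paste0("populus_", t1, "_vs_switchgrass_", t1),
             paste0("populus_", t2, "_vs_switchgrass_", t2),
             paste0("switchgrass_", t1, "_vs_switchgrass_", t2)),
    left = c(pop(t1), pop(t1), pop(t2), swg(t1)),
    right = c(pop(t2), swg(t1), swg(t2), swg(t2)),
    stringsAsFactors = FALSE)
}

#' Average technical replicates into one value per biological sample
#'
#' Arithmetic mean of log2 values over technical replicates within each
#' (substrate, time, bio_rep, platform) cell; the result carries
#' `tech_rep = 1`. Idempotent; RNA-seq matrices (tech_rep all 1) pass
#' through unchanged.
#'
#' @param em an `expr_matrix` of log2 values.
#' @return an `expr_matrix` with one column per biological sample.
#' @export
collapse_technical <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (em$value_kind == "raw_count")
    stop("collapse_technical expects log2 values")
  s <- em$samples
  key <- paste(s$substrate, s$time_h, s$bio_rep, s$platform, sep = "|")
  groups <- split(seq_len(ncol(em$values)), key)
  if (any(lengths(groups) == 0)) stop("biological sample with no replicates")
  ord <- order(vapply(groups, min, integer(1)))  # preserve input order
  groups <- groups[ord]
  vals <- vapply(groups, function(ix)
    rowMeans(em$values[, ix, drop = FALSE], na.rm = TRUE),
    numeric(nrow(em$values)))
  vals <- matrix(vals, nrow = nrow(em$values), ncol = length(groups))
  first <- vapply(groups, function(ix) ix[1], integer(1))
  sheet <- s[first, , drop = FALSE]
  sheet$tech_rep <- 1L
  sheet$sample_id <- sprintf("%s_%sh_b%d_%s", sheet$substrate,
                             format(sheet$time_h, trim = TRUE),
                             sheet$bio_rep, sheet$platform)
  colnames(vals) <- sheet$sample_id
  rownames(vals) <- rownames(em$values)
  expression_matrix(vals, sheet, em$value_kind)
}

#' Per-gene cell-means ANOVA with FDR and fold-change calling
#'
#' Fits, for every gene, a cell-means model on the four (substrate, time)
#' groups with a pooled residual variance; each contrast is tested by a
#' t-statistic on the difference of group means (two-sided, residual
#' df = n - 4). P-values are Benjamini-Hochberg adjusted per contrast
#' across genes. A gene is significant in a contrast when `fdr_q < alpha`,
#' and fold-passing when `|log2_ratio| >= lfc`. Technical replicates must
#' be collapsed first (see [collapse_technical()]); missing cells (zero
#' policy "missing") are excluded per gene with df reduced accordingly.
#'
#' @param x a `norm_result` or a log2 `expr_matrix`.
#' @param contrasts data.frame as [default_contrasts()].
#' @param alpha FDR threshold (default 0.05).
#' @param lfc absolute log2 ratio threshold (default 1).
#' @return an object of class `de_table`: a data.frame with columns `gene`,
#'   `contrast`, `log2_ratio` (left minus right), `p_value`, `fdr_q`,
#'   `sig_flag`, `fold_flag`, `zero_var`; attributes `alpha`, `lfc`,
#'   `method`.
#' @export
fit_anova <- function(x, contrasts = NULL, alpha = 0.05, lfc = 1) {
  method <- "unspecified"
  if (inherits(x, "norm_result")) {
    method <- x$method
    x <- x$normalized
  }
  stopifnot(inherits(x, "expr_matrix"), x$value_kind != "raw_count",
            alpha > 0, alpha < 1, lfc >= 0)
  if (any(x$samples$tech_rep != 1L))
    x <- collapse_technical(x)
  cond <- condition_label(x$samples)
  if (is.null(contrasts))
    contrasts <- default_contrasts(times = sort(unique(x$samples$time_h)))
  used <- union(contrasts$left, contrasts$right)
  missing_cond <- setdiff(used, unique(cond))
  if (length(missing_cond))
    stop("condition(s) absent from data: ",
         paste(missing_cond, collapse = ", "))
  tab <- table(cond)
  if (any(tab[used] < 2))
    stop("conditions with fewer than 2 biological replicates: ",
         paste(names(tab[used])[tab[used] < 2], collapse = ", "))

  v <- x$values
  groups <- unique(cond)
  k <- length(groups)
  obs <- !is.na(v)
  ind <- sapply(groups, function(g) as.numeric(cond == g))  # samples x k
  v0 <- v; v0[!obs] <- 0
  n_g <- obs %*% ind                     # genes x k, per-gene group sizes
  sum_g <- v0 %*% ind
  if (any(n_g == 0))
    stop("a gene has no observations in some condition; cannot fit")
  mean_g <- sum_g / n_g
  ss_g <- (v0^2) %*% ind - n_g * mean_g^2
  ss_within <- rowSums(ss_g)
  n_tot <- rowSums(n_g)
  df <- n_tot - k
  if (any(df <= 0)) stop("non-positive residual degrees of freedom")
  s2 <- pmax(ss_within, 0) / df
  zero_var <- s2 <= .Machine$double.eps * 100

  res <- vector("list", nrow(contrasts))
  for (i in seq_len(nrow(contrasts))) {
    l <- match(contrasts$left[i], groups)
    r <- match(contrasts$right[i], groups)
    delta <- mean_g[, l] - mean_g[, r]
    se <- sqrt(s2 * (1 / n_g[, l] + 1 / n_g[, r]))
    tstat <- delta / se
    p <- 2 * stats::pt(-abs(tstat), df)
    p[zero_var] <- 1
    q <- stats::p.adjust(p, method = "BH")
    res[[i]] <- data.frame(gene = rownames(v),
                           contrast = contrasts$name[i],
                           log2_ratio = unname(delta),
                           p_value = unname(p), fdr_q = unname(q),
                           sig_flag = unname(q < alpha),
                           fold_flag = unname(abs(delta) >= lfc),
                           zero_var = unname(zero_var),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (any(zero_var))
    warning(sum(zero_var), " gene(s) with zero pooled variance; p set to 1")
  structure(out, class = c("de_table", "data.frame"),
            alpha = alpha, lfc = lfc, method = method,
            contrasts = contrasts)
}

#' @export
print.de_table <- function(x, ...) {
  cat("<de_table> method ", attr(x, "method"), "; ",
      length(unique(x$gene)), " genes x ",
      length(unique(x$contrast)), " contrasts; alpha = ", attr(x, "alpha"),
      ", |log2| >= ", attr(x, "lfc"), "\n", sep = "")
  s <- call_differential(x)
  cat("  significant in >= 1 contrast: ", s$n_any_sig,
      "; significant and fold-passing: ", s$n_sig_fold, "\n", sep = "")
  invisible(x)
}

#' @export
summary.de_table <- function(object, ...) {
  agg <- stats::aggregate(cbind(sig = sig_flag,
                                sig_fold = sig_flag & fold_flag) ~ contrast,
                          data = object, FUN = sum)
  agg
}

#' Summarize a differential-expression table into headline counts
#'
#' Counts (i) genes significant (FDR < alpha) in at least one contrast and
#' (ii) genes that in at least one contrast are simultaneously significant
#' and beyond the fold threshold — the two columns of a per-method summary
#' table.
#'
#' @param de a `de_table`.
#' @return list with `n_any_sig`, `n_sig_fold`, and the corresponding gene
#'   id vectors `genes_any_sig`, `genes_sig_fold`.
#' @export
call_differential <- function(de) {
  stopifnot(inherits(de, "de_table"))
  any_sig <- tapply(de$sig_flag, de$gene, any)
  both <- tapply(de$sig_flag & de$fold_flag, de$gene, any)
  list(n_any_sig = sum(any_sig),
       n_sig_fold = sum(both),
       genes_any_sig = sort(names(any_sig)[any_sig]),
       genes_sig_fold = sort(names(both)[both]))
}

#' Gene-level call set of a differential-expression table
#'
#' The genes a method "calls": significant and fold-passing in at least one
#' contrast (the unit used for cross-method overlap counts).
#'
#' @param de a `de_table`.
#' @return character vector of gene ids.
#' @export
de_calls <- function(de) call_differential(de)$genes_sig_fold
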