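#' Gene-by-sample expression matrix with sample metadata
#'
#' The central container: a numeric gene x sample grid together with one row
#' of sample metadata per column. Values are raw read counts, log2-transformed
#' counts, or log2 fluorescence intensities, recorded in `value_kind`.
#'
#' @param values numeric matrix, rows = genes, columns = samples; `rownames`
#'   are gene ids and `colnames` sample ids.
#' @param samples data.frame with columns `sample_id`, `substrate`
#'   (`"populus"` or `"switchgrass"`), `time_h` (positive hours), `bio_rep`
#'   (integer >= 1), `tech_rep` (integer >= 1; 1 for RNA-seq), `platform`
#'   (`"rnaseq"` or `"array"`), one row per column of `values`, in column
#'   order.
#' @param value_kind one of `"raw_count"`, `"log2_count"`, `"log2_intensity"`.
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `samples`, `value_kind`.
#' @export
expression_matrix <- function(values,
                              samples,
                              value_kind = c("raw_count", "log2_count",
                                             "log2_intensity")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  samples <- validate_sample_sheet(samples)
  if (nrow(samples) != ncol(values))
    stop("sample sheet has ", nrow(samples), " rows but matrix has ",
         ncol(values), " columns")
  if (!identical(samples$sample_id, colnames(values)))
    stop("sample sheet ids must match matrix column names in order")
  if (value_kind == "raw_count") {
    if (any(!is.finite(values)) || any(values < 0) ||
        any(values != floor(values)))
      stop("raw counts must be finite nonnegative integers")
  }
  structure(list(values = values, samples = samples, value_kind = value_kind),
            class = "expr_matrix")
}

validate_sample_sheet <- function(samples) {
  required <- c("sample_id", "substrate", "time_h", "bio_rep", "tech_rep",
                "platform")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop("sample sheet missing columns: ", paste(missing, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  samples$substrate <- as.character(samples$substrate)
  samples$platform <- as.character(samples$platform)
  samples$time_h <- as.numeric(samples$time_h)
  samples$bio_rep <- as.integer(samples$bio_rep)
  samples$tech_rep <- as.integer(samples$tech_rep)
  if (!all(samples$substrate %in% c("populus", "switchgrass")))
    stop("substrate must be 'populus' or 'switchgrass'")
  if (!all(samples$platform %in% c("rnaseq", "array")))
    stop("platform must be 'rnaseq' or 'array'")
  if (any(!is.finite(samples$time_h)) || any(samples$time_h <= 0))
    stop("time_h must be positive")
  if (any(samples$bio_rep < 1L) || any(samples$tech_rep < 1L))
    stop("bio_rep and tech_rep must be >= 1")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in sample sheet")
  key <- with(samples, paste(substrate, time_h, bio_rep, tech_rep, platform))
  if (anyDuplicated(key))
    stop("(substrate, time_h, bio_rep, tech_rep, platform) must be unique")
  rownames(samples) <- NULL
  samples
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$value_kind, "]\n", sep = "")
  cat("  platforms: ", paste(unique(x$samples$platform), collapse = ", "),
      "; conditions: ",
      paste(unique(condition_label(x$samples)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or sample
#' @param x an `expr_matrix`.
#' @param genes character vector of gene ids, or logical/integer row index.
#' @param samples logical/integer column index.
#' @return an `expr_matrix`.
#' @export
subset_matrix <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  s <- x$samples
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    s <- s[samples, , drop = FALSE]
    rownames(s) <- NULL
  }
  expression_matrix(v, s, x$value_kind)
}
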