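#' Read a gene-by-sample matrix with its sample sheet
#'
#' The matrix file is tab-separated, UTF-8, decimal point `"."`: a header row
#' of sample ids and a first column of gene ids. The sample sheet is a TSV
#' with one row per sample id (columns `sample_id`, `substrate`, `time_h`,
#' `bio_rep`, `tech_rep`, `platform`). Every matrix column must be described
#' in the sheet; sheet rows are reordered to the matrix column order.
#'
#' @param path matrix TSV path.
#' @param sample_sheet sample-sheet TSV path.
#' @param value_kind value kind of the matrix cells (see
#'   [expression_matrix()]).
#' @return an `expr_matrix`.
#' @export
read_matrix <- function(path, sample_sheet,
                        value_kind = c("raw_count", "log2_count",
                                       "log2_intensity")) {
  value_kind <- match.arg(value_kind)
  raw <- utils::read.delim(path, check.names = FALSE, header = TRUE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("matrix file needs a gene id column and >= 1 sample")
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = dimnames(cells)))
  bad <- which(is.na(num) & !(is.na(cells) | cells %in% c("NA", "")),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' in %s",
                 gene_ids[bad[1, 1]], colnames(cells)[bad[1, 2]], path))
  rownames(num) <- gene_ids
  sheet <- read_sample_sheet(sample_sheet)
  absent <- setdiff(colnames(num), sheet$sample_id)
  if (length(absent))
    stop("sample sheet has no metadata for column(s): ",
         paste(absent, collapse = ", "))
  sheet <- sheet[match(colnames(num), sheet$sample_id), , drop = FALSE]
  expression_matrix(num, sheet, value_kind)
}

#' Read and validate a sample sheet TSV
#' @param path sample sheet TSV path.
#' @return validated data.frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' Write an expression matrix (and optionally its sample sheet) as TSV
#' @param x an `expr_matrix`.
#' @param path output TSV path for the matrix.
#' @param sample_sheet optional path for the sample sheet TSV.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, sample_sheet = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet))
    utils::write.table(x$samples, sample_sheet, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read gene lengths from GFF3 or two-column TSV
#'
#' GFF3 lengths follow the 1-based inclusive convention: `end - start + 1`
#' for each `gene` feature (strand is irrelevant to length). The TSV dialect
#' has two columns, `gene_id` and `length_bp`, with a header.
#'
#' @param path annotation path.
#' @param format `"tsv"` or `"gff3"`.
#' @return data.frame with columns `gene_id`, `length_bp` (and `product`
#'   where available).
#' @export
read_gene_lengths <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    ids <- gr$ID
    if (is.null(ids) || anyNA(ids)) {
      lt <- gr$locus_tag
      if (!is.null(lt)) ids[is.na(ids)] <- lt[is.na(ids)]
    }
    if (is.null(ids) || anyNA(ids))
      stop("GFF3 gene features must carry an ID (or locus_tag) attribute")
    ann <- data.frame(gene_id = as.character(ids),
                      length_bp = BiocGenerics::width(gr),
                      stringsAsFactors = FALSE)
    prod <- gr$product
    if (!is.null(prod)) ann$product <- as.character(prod)
  } else {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "length_bp") %in% names(ann)))
      stop("length TSV must have columns gene_id and length_bp")
    ann$gene_id <- as.character(ann$gene_id)
    ann$length_bp <- as.numeric(ann$length_bp)
  }
  if (any(!is.finite(ann$length_bp)) || any(ann$length_bp <= 0))
    stop("gene lengths must be positive")
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(ann$gene_id[duplicated(ann$gene_id)]), collapse = ", "))
  rownames(ann) <- NULL
  ann
}

#' Write an analysis report to disk
#'
#' Tables (data.frames, including differential-expression tables) are written
#' as TSV at full precision; nested reports (lists) as JSON. Rounding, where
#' applied, happens only in printed human-readable summaries, never in files.
#'
#' @param report a data.frame or list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (is.data.frame(report)) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (is.list(report)) {
    jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  } else {
    stop("report must be a data.frame or a list")
  }
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path JSON path.
#' @return list.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Drop S3 classes recursively so jsonlite serializes plain structures.
unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
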