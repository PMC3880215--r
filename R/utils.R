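#' @keywords internal
"_PACKAGE"

# Geometric mean of strictly positive values.
geomean <- function(x) {
  stopifnot(all(is.finite(x)), all(x > 0))
  exp(mean(log(x)))
}

# Condition label (substrate x time) for a sample sheet.
condition_label <- function(samples) {
  paste0(samples$substrate, "_", format(samples$time_h, trim = TRUE), "h")
}

# Deterministic sub-seed expansion: one global seed yields a fixed table of
# per-stream seeds so that adding draws to one stream never perturbs another.
.streams <- c("gene_means", "gene_lengths", "effects", "size_factors",
              "counts", "affinity", "array_noise", "spare")

stream_seed <- function(seed, stream) {
  stream <- match.arg(stream, .streams)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(.streams))
  s[match(stream, .streams)]
}

# round() in R is round-half-to-even, which is the rounding rule used for
# all printed-precision comparisons in this package.
round_even <- function(x, digits = 0) round(x, digits)

`%||%` <- function(a, b) if (is.null(a)) b else a
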