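#' Read a fermentation summary table
#'
#' The packaged default is the published batch-fermentation summary for
#' Clostridium thermocellum grown on dilute-acid pretreated switchgrass and
#' Populus at 5 g/L loading: mean acetic acid (g/L), ethanol (g/L), and
#' residual glucose (mg per g biomass) with their SDs at 0, 12, and 37
#' hours post-inoculation. All Results-style summaries (glucose conversion,
#' product ratios) are recomputed from this table.
#'
#' @param path TSV path; default the packaged table.
#' @return data.frame with columns `substrate`, `time_h`, `acetic_gL`,
#'   `acetic_sd`, `ethanol_gL`, `ethanol_sd`, `glucose_mg_per_g`,
#'   `glucose_sd`.
#' @export
read_fermentation_table <- function(path = system.file(
  "extdata", "table1_fermentation.tsv", package = "normconcord")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("substrate", "time_h", "acetic_gL", "ethanol_gL",
            "glucose_mg_per_g")
  if (!all(need %in% names(tab)))
    stop("fermentation table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  if (any(tab[need[-1]] < 0, na.rm = TRUE))
    stop("concentrations must be nonnegative")
  for (s in unique(tab$substrate))
    if (!any(tab$substrate == s & tab$time_h == 0))
      stop("time 0 row missing for substrate ", s)
  tab
}

.ferm_row <- function(tab, substrate, time_h) {
  row <- tab[tab$substrate == substrate & tab$time_h == time_h, ,
             drop = FALSE]
  if (nrow(row) != 1)
    stop("no unique row for (", substrate, ", ", time_h, " h)")
  row
}

#' Percent glucose conversion over a fermentation
#'
#' `100 * (glucose(0) - glucose(t_end)) / glucose(0)` from the mean
#' residual-glucose values; exact arithmetic, rounded only for display.
#'
#' @param tab fermentation table ([read_fermentation_table()]).
#' @param substrate `"populus"` or `"switchgrass"`.
#' @param t_end end time in hours (default 37).
#' @return percent conversion (numeric scalar).
#' @export
glucose_conversion <- function(tab, substrate, t_end = 37) {
  g0 <- .ferm_row(tab, substrate, 0)$glucose_mg_per_g
  gt <- .ferm_row(tab, substrate, t_end)$glucose_mg_per_g
  if (g0 <= 0) stop("glucose at time 0 must be positive")
  100 * (g0 - gt) / g0
}

#' Fermentation product ratios between or within substrates
#'
#' Modes `"combined"`, `"acetic"`, `"ethanol"` divide the product level(s)
#' of `numerator_substrate` by the other substrate's at time `t`
#' (`combined` = acetic + ethanol). Mode `"acetic_to_ethanol"` is the
#' within-substrate acetic:ethanol ratio of `numerator_substrate`; because
#' it is computed from table means rounded to one decimal, it carries a
#' `"note"` attribute flagging that published within-substrate ratios
#' derive from unrounded instrument data and are not reproducible from the
#' rounded table.
#'
#' @param tab fermentation table.
#' @param t time in hours.
#' @param numerator_substrate substrate in the numerator.
#' @param mode one of `"combined"`, `"acetic"`, `"ethanol"`,
#'   `"acetic_to_ethanol"`.
#' @return the ratio (numeric scalar, possibly with a `"note"` attribute).
#' @export
product_ratio <- function(tab, t = 37, numerator_substrate = "populus",
                          mode = c("combined", "acetic", "ethanol",
                                   "acetic_to_ethanol")) {
  mode <- match.arg(mode)
  other <- setdiff(c("populus", "switchgrass"), numerator_substrate)
  num <- .ferm_row(tab, numerator_substrate, t)
  if (mode == "acetic_to_ethanol") {
    if (num$ethanol_gL <= 0) stop("zero denominator")
    r <- num$acetic_gL / num$ethanol_gL
    attr(r, "note") <- paste(
      "computed from table means rounded at the printed precision;",
      "published acetic:ethanol ratios derive from unrounded instrument",
      "data and are not reproducible from this table")
    return(r)
  }
  den <- .ferm_row(tab, other, t)
  nv <- switch(mode,
               combined = num$acetic_gL + num$ethanol_gL,
               acetic = num$acetic_gL,
               ethanol = num$ethanol_gL)
  dv <- switch(mode,
               combined = den$acetic_gL + den$ethanol_gL,
               acetic = den$acetic_gL,
               ethanol = den$ethanol_gL)
  if (dv <= 0) stop("zero denominator")
  nv / dv
}

#' Percent of predicted genes covered by a platform
#'
#' @param n_detected genes with data on the platform.
#' @param n_predicted predicted genes in the genome annotation.
#' @return list with `percent` (exact), `percent_1dp` (one decimal,
#'   round-half-to-even), `percent_int` (integer rounding).
#' @export
platform_coverage <- function(n_detected, n_predicted) {
  stopifnot(n_predicted > 0, n_detected >= 0, n_detected <= n_predicted)
  p <- 100 * n_detected / n_predicted
  list(percent = p, percent_1dp = round_even(p, 1),
       percent_int = round_even(p, 0))
}
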