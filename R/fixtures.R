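pg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "phenogrowth")
  if (path == "") pg_error(sprintf("bundled data file '%s' not found", file), "pg_io")
  path
}

#' Reference trait means from a two-genotype wheat growth study
#'
#' Published per-genotype means and standard errors (n = 5 plants) of leaf
#' area (LA, cm^2), leaf dry weight (LDW, mg), above-ground biomass (BIO, mg)
#' and image-derived side-projected area (SPA, mm^2) for two spring wheat
#' genotypes ('Yecora-Rojo', early heading; 'Seri-82', late heading) sampled
#' destructively at 21, 25, 30, 35, 39, 44, 49 and 53 days after planting.
#'
#' @return Data frame with columns `genotype`, `trait`, `unit`, `dap`,
#'   `mean`, `se`.
#' @export
wheat_trait_means <- function() {
  utils::read.csv(pg_extdata("wheat_trait_means.csv"), stringsAsFactors = FALSE)
}

#' Published interval RGR values for the reference study
#'
#' The study's printed relative growth rates for LDW and BIO
#' (mg g^-1 d^-1) and SPA (mm^2 mm^-2 d^-1) over the seven consecutive
#' sampling intervals, kept verbatim as printed (`printed` is character to
#' preserve the printed precision).
#'
#' @return Data frame with columns `genotype`, `trait`, `dap_start`,
#'   `dap_end`, `printed`, `unit`.
#' @export
wheat_rgr_reference <- function() {
  utils::read.csv(pg_extdata("wheat_rgr_reference.csv"),
                  colClasses = c(printed = "character"),
                  stringsAsFactors = FALSE)
}

#' Published SPA regression rows for the reference study
#'
#' The study's printed simple-regression summaries of LA, LDW and BIO on SPA
#' per genotype: slope, intercept, R^2 (percent) and Pearson r.
#'
#' @return Data frame with columns `genotype`, `response`, `slope`,
#'   `intercept`, `r2_percent`, `pearson_r`.
#' @export
wheat_regression_reference <- function() {
  utils::read.csv(pg_extdata("wheat_regression_reference.csv"),
                  stringsAsFactors = FALSE)
}

#' Published RGR cross-validation correlations
#'
#' The study's printed Pearson correlations between biomass-based and
#' SPA-based interval RGR (seven intervals per genotype), and the printed
#' upper bound of the regression R^2.
#'
#' @return Data frame with columns `genotype`, `pearson_r`; attribute
#'   `max_r2_percent` (93).
#' @export
wheat_rgr_correlation_reference <- function() {
  out <- data.frame(genotype = c("Yecora-Rojo", "Seri-82"),
                    pearson_r = c(0.97, 0.91))
  attr(out, "max_r2_percent") <- 93
  out
}

#' Round half-up to a fixed number of decimals
#'
#' Commercial (half-away-from-zero) rounding, the convention used when
#' comparing recomputed values against printed tables, where 372.28 prints
#' as 372.3.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

printed_decimals <- function(s) {
  dot <- regexpr(".", s, fixed = TRUE)
  ifelse(dot > 0, nchar(s) - dot, 0L)
}

#' Compare computed values against printed reference values
#'
#' Rounds each computed value half-up to the precision of the corresponding
#' printed string and tests equality at that precision.
#'
#' @param computed Numeric vector.
#' @param printed Character vector of printed values (e.g. `"372.3"`,
#'   `"99"`).
#' @return Logical vector: does each computed value reproduce the printed
#'   one at its printed precision?
#' @export
matches_printed <- function(computed, printed) {
  d <- printed_decimals(printed)
  mapply(function(x, dd, p) round_half_up(x, dd) == as.numeric(p),
         computed, d, printed)
}
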