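# Bundled reference results from field mapping of PEDS in maize x teosinte
# advanced backcross populations: per-environment phenotype distributions,
# single-QTL mapping summaries, and epistatic-QTL summaries.  Used by the
# worked examples and by the reproduction script as published points of
# comparison.

#' Reference PEDS class distributions
#'
#' Observed per-environment distributions of PEDS over the classes 0%,
#' (0,10], ..., (90,100] in BC3F2 field populations, with totals and
#' reported means.
#'
#' @return data.frame, one row per environment.
#' @export
peds_reference_distribution <- function() {
  utils::read.csv(
    system.file("extdata", "bc3f2_peds_distribution.csv", package = "pedsqtl"),
    stringsAsFactors = FALSE
  )
}

#' Expand a binned PEDS distribution to per-plant values
#'
#' Plants in the 0% class get PEDS 0; plants in the class (a, b] get the
#' class midpoint.  Exact within-class values are unknown, so moments other
#' than the class counts (in particular the PEDS>0 ratio, which depends
#' only on the 0% count) are approximate.
#'
#' @param row one row of [peds_reference_distribution()].
#' @return Numeric vector of length `row$total`.
#' @export
expand_peds_distribution <- function(row) {
  mids <- seq(5, 95, by = 10)
  counts <- as.numeric(row[paste0("c", seq(0, 90, 10), "_", seq(10, 100, 10))])
  c(rep(0, row$peds_eq_0), rep(mids, counts))
}

#' Reference single-QTL and epistatic-QTL mapping summaries
#'
#' Published LOD, PVE and effect estimates for the PEDS QTL (`qPEDS1.1`,
#' `qPEDS3.1`, ...) and the epistatic pairs detected in the BC3F2/BC4F2
#' populations across environments.
#'
#' @return data.frame.
#' @export
qtl_reference <- function() {
  utils::read.delim(
    system.file("extdata", "qtl_mapping_reference.tsv", package = "pedsqtl"),
    stringsAsFactors = FALSE
  )
}

#' @rdname qtl_reference
#' @export
epistasis_reference <- function() {
  utils::read.delim(
    system.file("extdata", "epistasis_reference.tsv", package = "pedsqtl"),
    stringsAsFactors = FALSE
  )
}
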