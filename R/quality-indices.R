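#' Forage quality indices
#'
#' Standard hay-quality calculations from detergent-fibre analysis:
#' digestible dry matter `DDM% = 88.9 - 0.779 * ADF%`, dry-matter intake
#' `DMI% of body weight = 120 / NDF%`, relative feed value
#' `RFV = DDM * DMI / 1.29`, and crude protein `CP% = 6.25 * N%`.
#' Percentages are on the 0-100 scale, not fractions. Values are
#' returned at full precision; round only when reporting (an RFV of
#' 158.94 prints as 158.9 or 159 depending on house style, but the
#' computation never rounds).
#'
#' RFV interpretation: about 100 for full-bloom alfalfa reference hay,
#' above 151 is "Prime".
#'
#' @param adf acid detergent fibre, % of dry matter, in `[0, 100)`.
#' @param ndf neutral detergent fibre, % of dry matter, > 0.
#' @param nitrogen Kjeldahl nitrogen, % of dry matter, >= 0.
#' @return numeric vector of the index values.
#' @examples
#' ddm(22.0)        # 71.762
#' rfv(22.0, 42.0)  # 158.94: "Prime" forage
#' @export
ddm <- function(adf) {
  if (any(!is.finite(adf)) || any(adf < 0) || any(adf >= 100))
    stop("adf must lie in [0, 100)")
  88.9 - 0.779 * adf
}

#' @rdname ddm
#' @export
dmi <- function(ndf) {
  if (any(!is.finite(ndf)) || any(ndf <= 0))
    stop("ndf must be > 0")
  120 / ndf
}

#' @rdname ddm
#' @export
rfv <- function(adf, ndf) {
  ddm(adf) * dmi(ndf) / 1.29
}

#' @rdname ddm
#' @export
crude_protein <- function(nitrogen) {
  if (any(!is.finite(nitrogen)) || any(nitrogen < 0))
    stop("nitrogen must be >= 0")
  6.25 * nitrogen
}

#' Recompute the RFV column of a trait table
#'
#' Vectorized over the table's `adf` and `ndf` columns; adds or
#' overwrites `rfv`.
#'
#' @param table a data frame with `adf` and `ndf` columns (% of DM).
#' @return the table with its `rfv` column recomputed.
#' @export
add_quality_indices <- function(table) {
  if (!all(c("adf", "ndf") %in% names(table)))
    stop("table must contain 'adf' and 'ndf' columns")
  table$rfv <- rfv(table$adf, table$ndf)
  table
}
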