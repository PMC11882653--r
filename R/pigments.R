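# Chlorophyll quantification from DMSO thallus extracts measured at 665 and
# 649 nm. The coefficient sets are named and traceable rather than anonymous
# constants: "arnon" is the classical acetone-derived linear combination
# applied to DMSO extracts at 665/649 nm (the adaptation of Arnon's
# equations used throughout the lichen DMSO literature), "barnes_dmso" is
# the DMSO-specific recalibration (Barnes et al. 1992). Concentrations are
# ug chlorophyll per ml of extract.

#' Chlorophyll coefficient sets
#'
#' Linear coefficients giving `conc = c665 * A665 + c649 * A649` (ug/ml)
#' for chlorophyll a and b.
#'
#' @param set `"arnon"` (default) or `"barnes_dmso"`.
#' @return List with `name`, and `a`/`b` coefficient pairs
#'   `(c665, c649)`.
#' @export
chl_coefficients <- function(set = c("arnon", "barnes_dmso")) {
  set <- match.arg(set)
  switch(set,
    arnon = list(name = "arnon",
                 a = c(c665 = 12.70, c649 = -2.69),
                 b = c(c665 = -4.68, c649 = 22.90)),
    barnes_dmso = list(name = "barnes_dmso",
                       a = c(c665 = 12.19, c649 = -3.45),
                       b = c(c665 = -5.32, c649 = 21.99)))
}

#' Chlorophyll content per mg dry mass
#'
#' Content (ug per mg DM) is concentration (ug/ml) times extract volume
#' divided by extracted dry mass. When several measurements are supplied for
#' the same thallus (the protocol extracts each thallus twice), their
#' contents are summed.
#'
#' @param m A [pigment_measurement()] or a list of them (one sample).
#' @param coeffs A coefficient set from [chl_coefficients()].
#' @return List with `chl_a`, `chl_b`, `chl_ab` (a+b), `ratio_ab_a`
#'   (`chl_ab / chl_a`, the published summary ratio), and `flagged`
#'   (`TRUE` when any computed concentration was negative - a turbid or
#'   failed extract).
#' @export
chlorophyll_content <- function(m, coeffs = chl_coefficients()) {
  if (inherits(m, "pigment_measurement")) m <- list(m)
  one <- function(x) {
    conc_a <- coeffs$a[["c665"]] * x$a665 + coeffs$a[["c649"]] * x$a649
    conc_b <- coeffs$b[["c665"]] * x$a665 + coeffs$b[["c649"]] * x$a649
    c(a = conc_a * x$extract_volume_ml / x$dm_mg,
      b = conc_b * x$extract_volume_ml / x$dm_mg)
  }
  per <- vapply(m, one, numeric(2))
  flagged <- any(per < 0)
  if (flagged)
    warning("negative chlorophyll concentration: turbid or failed extract",
            call. = FALSE)
  chl_a <- sum(per["a", ]); chl_b <- sum(per["b", ])
  list(chl_a = chl_a, chl_b = chl_b, chl_ab = chl_a + chl_b,
       ratio_ab_a = if (chl_a != 0) (chl_a + chl_b) / chl_a else NA_real_,
       flagged = flagged)
}
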