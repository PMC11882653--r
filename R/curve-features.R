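# Extraction of the core parameters from a drying run: the central
# computation. All threshold crossings use linear interpolation between
# measured points; no smoothing is applied by default, keeping every
# estimator transparent. Dark respiration is carried negative internally
# (assimilation sign convention) and reported as a positive magnitude in
# the core-parameter record.

#' Thallus water content as % of dry mass
#'
#' @param mass_mg Current thallus mass, mg.
#' @param dry_mass_mg Oven-dry mass, mg (> 0).
#' @return `100 * (mass - dry) / dry`, % of DM. Vectorised.
#' @export
water_content_pct <- function(mass_mg, dry_mass_mg) {
  if (any(dry_mass_mg <= 0)) validation_error("dry_mass_mg must be > 0")
  if (any(mass_mg < dry_mass_mg - 1e-9))
    validation_error("mass below dry mass: water content would be negative")
  100 * (mass_mg - dry_mass_mg) / dry_mass_mg
}

#' Thallus water content in mm rainfall equivalent
#'
#' 1 mm of rain over 1 cm2 is 100 mg of water, so
#' `wc_mm = (mass - dry) / (100 * area)`.
#'
#' @inheritParams water_content_pct
#' @param area_cm2 Planform thallus area, cm2 (> 0).
#' @return Water content, mm H2O precipitation equivalent. Vectorised.
#' @export
water_content_mm <- function(mass_mg, dry_mass_mg, area_cm2) {
  if (any(area_cm2 <= 0)) validation_error("area_cm2 must be > 0")
  if (any(mass_mg < dry_mass_mg - 1e-9))
    validation_error("mass below dry mass: water content would be negative")
  (mass_mg - dry_mass_mg) / (100 * area_cm2)
}

#' Specific thallus mass
#' @inheritParams water_content_mm
#' @return Dry mass per area, mg cm-2.
#' @export
stm <- function(dry_mass_mg, area_cm2) {
  if (any(area_cm2 <= 0)) validation_error("area_cm2 must be > 0")
  if (any(dry_mass_mg <= 0)) validation_error("dry_mass_mg must be > 0")
  dry_mass_mg / area_cm2
}

#' Water holding capacity in mm rainfall equivalent
#' @param full_wet_mass_mg Fully hydrated mass, mg.
#' @inheritParams water_content_mm
#' @return WHC, mm H2O per cm2.
#' @export
whc <- function(full_wet_mass_mg, dry_mass_mg, area_cm2)
  water_content_mm(full_wet_mass_mg, dry_mass_mg, area_cm2)

#' Water content of one light curve
#'
#' @param curve A [light_curve()].
#' @param sample The owning [thallus_sample()].
#' @param convention `"midpoint"` (mean of the bracketing masses; default)
#'   or `"endpoint"` (mass after the curve).
#' @return List with `wc_pct` and `wc_mm`.
#' @export
curve_wc <- function(curve, sample, convention = c("midpoint", "endpoint")) {
  convention <- match.arg(convention)
  m <- switch(convention,
              midpoint = (curve$mass_before_mg + curve$mass_after_mg) / 2,
              endpoint = curve$mass_after_mg)
  list(wc_pct = water_content_pct(m, sample$dry_mass_mg),
       wc_mm = water_content_mm(m, sample$dry_mass_mg, sample$area_cm2))
}

#' Light compensation point of a curve
#'
#' The irradiance at which net photosynthesis crosses zero, linearly
#' interpolated between the bracketing PPFD steps; an exact zero reading is
#' its own compensation point. With several crossings the first
#' (lowest-PPFD) one is used.
#'
#' @param curve A [light_curve()].
#' @return PPFD, umol photons m-2 s-1; `NA` (with a `"reason"` attribute)
#'   when the curve never reaches positive NP (inactive sample).
#' @export
lcp <- function(curve) {
  a <- curve$assim
  if (all(a > 0))
    validation_error(sprintf(
      "curve %d: all assimilation values positive - dark reading must respire",
      curve$curve_index))
  if (all(a < 0))
    return(structure(NA_real_, reason = "inactive: NP never positive"))
  if (a[1L] > 0)   # noisy dark reading above zero: compensation at zero light
    return(structure(0, reason = "dark reading positive"))
  i <- which(a >= 0)[1L]
  if (a[i] == 0) return(curve$ppfd[i])
  p0 <- curve$ppfd[i - 1L]; p1 <- curve$ppfd[i]
  p0 + (p1 - p0) * (0 - a[i - 1L]) / (a[i] - a[i - 1L])
}

#' Light saturation point of a curve
#'
#' The lowest irradiance at which NP reaches 90% (by default) of the curve
#' maximum, linearly interpolated between the bracketing steps.
#'
#' @param curve A [light_curve()].
#' @param frac Saturation fraction of the curve maximum.
#' @return PPFD, umol photons m-2 s-1; `NA` when the curve maximum is not
#'   positive.
#' @export
lsp <- function(curve, frac = 0.9) {
  a <- curve$assim
  m <- max(a)
  if (m <= 0) return(structure(NA_real_, reason = "no positive NP"))
  x <- interp_up_crossing(curve$ppfd, a, frac * m)
  if (is.na(x)) curve$ppfd[1L] else x
}

#' Water-content response of NP and DR at saturating light
#'
#' For each curve of a run: NP is the maximum assimilation over steps at or
#' above the reference saturating irradiance (a plateau estimate, robust to
#' per-step noise), DR is the PPFD = 0 reading (negative), and the water
#' content follows the chosen mass convention. Rows are ordered wettest
#' first: these are the published NP/DR-vs-WC response curves.
#'
#' @param run A [drying_run()].
#' @param lsp_ref Reference saturating irradiance, normally the light
#'   saturation point of the run's best curve (see
#'   [compile_core_parameters()]).
#' @param convention Mass convention for [curve_wc()].
#' @return data.frame with columns `curve_index`, `wc_pct`, `wc_mm`, `np`,
#'   `dr`, sorted by `wc_pct` descending.
#' @export
np_wc_response <- function(run, lsp_ref, convention = "midpoint") {
  if (!is_scalar_number(lsp_ref)) validation_error("lsp_ref must be a finite number")
  rows <- lapply(run$curves, function(cv) {
    sat <- cv$ppfd >= lsp_ref
    if (!any(sat))
      validation_error(sprintf(
        "curve %d has no PPFD step at or above the reference LSP (%g)",
        cv$curve_index, lsp_ref))
    wc <- curve_wc(cv, run$sample, convention)
    data.frame(curve_index = cv$curve_index, wc_pct = wc$wc_pct,
               wc_mm = wc$wc_mm, np = max(cv$assim[sat]), dr = cv$assim[1L])
  })
  out <- do.call(rbind, rows)
  out[order(-out$wc_pct), , drop = FALSE]
}

#' Optimal water-content bounds at a fraction of MaxNP
#'
#' MinWC is the lowest-WC upward crossing of `threshold * MaxNP`, MaxWC the
#' highest-WC downward crossing, both linearly interpolated on the measured
#' response; OptWC is exactly their difference. When the driest (wettest)
#' measured point is itself at or above the threshold the bound cannot be
#' bracketed and is censored at that point, with the corresponding flag set.
#'
#' @param response Output of [np_wc_response()].
#' @param threshold Fraction of MaxNP (default 0.9).
#' @return List with `min_wc_pct`, `max_wc_pct`, `opt_wc_pct`, the same in
#'   mm, `max_np`, and `censored_low`/`censored_high` flags.
#' @export
optimal_wc_bounds <- function(response, threshold = 0.9) {
  if (!is.data.frame(response) || nrow(response) == 0L)
    validation_error("optimal_wc_bounds: empty response table")
  o <- response[order(response$wc_pct), , drop = FALSE]
  max_np <- max(o$np)
  if (max_np <= 0)
    validation_error("optimal_wc_bounds: no positive NP in response")
  thr <- threshold * max_np
  min_pct <- interp_up_crossing(o$wc_pct, o$np, thr)
  max_pct <- interp_down_crossing(o$wc_pct, o$np, thr)
  censored_low <- is.na(min_pct); censored_high <- is.na(max_pct)
  if (censored_low) min_pct <- o$wc_pct[1L]
  if (censored_high) max_pct <- o$wc_pct[nrow(o)]
  # mm is an exact linear rescaling of pct for a given sample (wc_mm =
  # wc_pct * STM / 1e4), so interpolate once and rescale.
  scale <- o$wc_mm[1L] / o$wc_pct[1L]
  if (!is.finite(scale) || o$wc_pct[1L] == 0)
    scale <- (o$wc_mm[nrow(o)] - o$wc_mm[1L]) / (o$wc_pct[nrow(o)] - o$wc_pct[1L])
  list(min_wc_pct = min_pct, max_wc_pct = max_pct,
       opt_wc_pct = max_pct - min_pct,
       min_wc_mm = min_pct * scale, max_wc_mm = max_pct * scale,
       opt_wc_mm = (max_pct - min_pct) * scale,
       max_np = max_np,
       censored_low = censored_low, censored_high = censored_high)
}

new_core_parameters <- function(lcp, lsp, max_np, dr_max, cge,
                                min_wc_pct, max_wc_pct, stm, whc_mm,
                                chl_a = NA_real_, chl_ab = NA_real_,
                                censored_low = FALSE, censored_high = FALSE) {
  structure(list(
    lcp = lcp, lsp = lsp, max_np = max_np, dr_max = dr_max, cge = cge,
    min_wc_pct = min_wc_pct, max_wc_pct = max_wc_pct,
    opt_wc_pct = max_wc_pct - min_wc_pct,
    min_wc_mm = min_wc_pct * stm / 1e4,
    max_wc_mm = max_wc_pct * stm / 1e4,
    # defined as the difference of the mm bounds so the identity
    # OptWC = MaxWC - MinWC is exact in both unit systems
    opt_wc_mm = max_wc_pct * stm / 1e4 - min_wc_pct * stm / 1e4,
    stm = stm, whc_mm = whc_mm, chl_a = chl_a, chl_ab = chl_ab,
    censored_low = censored_low, censored_high = censored_high),
    class = "core_parameters")
}

#' @export
print.core_parameters <- function(x, ...) {
  cat(sprintf(
    paste0("<core_parameters> MaxNP %.2f, DR %.2f, CGE %.2f | LCP %.1f, LSP %.0f | ",
           "WC %% [%.1f, %.1f] (opt %.1f) | mm [%.3f, %.3f] | STM %.1f, WHC %.2f\n"),
    x$max_np, x$dr_max, x$cge, x$lcp, x$lsp, x$min_wc_pct, x$max_wc_pct,
    x$opt_wc_pct, x$min_wc_mm, x$max_wc_mm, x$stm, x$whc_mm))
  invisible(x)
}

#' @export
as.data.frame.core_parameters <- function(x, ...) {
  data.frame(lcp = x$lcp, lsp = x$lsp, max_np = x$max_np, dr_max = x$dr_max,
             cge = x$cge, min_wc_mm = x$min_wc_mm, max_wc_mm = x$max_wc_mm,
             opt_wc_mm = x$opt_wc_mm, min_wc_pct = x$min_wc_pct,
             max_wc_pct = x$max_wc_pct, opt_wc_pct = x$opt_wc_pct,
             stm = x$stm, whc_mm = x$whc_mm, chl_a = x$chl_a,
             chl_ab = x$chl_ab, censored_low = x$censored_low,
             censored_high = x$censored_high)
}

#' Extract all core parameters from one drying run
#'
#' Orchestration: the reference curve is the one with the highest measured
#' NP (the near-optimal-WC curve); its light saturation point becomes the
#' reference saturating irradiance, LCP and LSP are read from it, the NP/DR
#' water-content response is built, the 90%-of-MaxNP bounds located, and
#' morphology (STM, WHC) and optional chlorophyll contents attached. CGE is
#' MaxNP over the magnitude of dark respiration on the MaxNP curve; `dr_max`
#' is the deepest dark respiration of the run.
#'
#' @param run A [drying_run()].
#' @param pigments Optional list of [pigment_measurement()]s for this
#'   sample (summed when the thallus was extracted twice).
#' @param threshold Fraction of MaxNP defining the optimal-WC bounds.
#' @param drop_first Drop the wettest curve (guards dark respiration against
#'   resaturation-burst contamination)?
#' @param convention Mass convention, `"midpoint"` or `"endpoint"`.
#' @param coeffs Chlorophyll coefficient set, see [chl_coefficients()].
#' @return A `core_parameters` object.
#' @export
compile_core_parameters <- function(run, pigments = NULL, threshold = 0.9,
                                    drop_first = FALSE,
                                    convention = "midpoint",
                                    coeffs = chl_coefficients()) {
  if (drop_first) {
    if (length(run$curves) < 4L)
      validation_error("drop_first needs a run with >= 4 curves")
    run$curves <- run$curves[-1L]
  }
  peak <- vapply(run$curves, function(cv) max(cv$assim), numeric(1))
  ref <- run$curves[[which.max(peak)]]
  lsp_ref <- lsp(ref)
  if (is.na(lsp_ref))
    validation_error(sprintf("sample %s: no curve with positive NP",
                             run$sample$sample_id))
  # LCP needs a visible dark respiration; with noisy data the best curve's
  # dark reading can sit above zero, so fall back to the highest-NP curve
  # whose dark reading respires.
  lcp_curve <- ref
  if (lcp_curve$assim[1L] >= 0) {
    dark_ok <- vapply(run$curves, function(cv) cv$assim[1L] < 0, logical(1))
    if (any(dark_ok)) {
      cand <- run$curves[dark_ok]
      lcp_curve <- cand[[which.max(peak[dark_ok])]]
    }
  }
  lcp_ref <- lcp(lcp_curve)
  resp <- np_wc_response(run, lsp_ref, convention)
  b <- optimal_wc_bounds(resp, threshold)
  i_max <- which.max(resp$np)
  dr_at_max <- resp$dr[i_max]
  cge <- if (dr_at_max < 0) b$max_np / abs(dr_at_max) else NA_real_
  chl <- if (!is.null(pigments)) chlorophyll_content(pigments, coeffs)
         else list(chl_a = NA_real_, chl_ab = NA_real_)
  out <- new_core_parameters(
    lcp = lcp_ref, lsp = lsp_ref, max_np = b$max_np,
    dr_max = max(0, -min(resp$dr)), cge = cge,
    min_wc_pct = b$min_wc_pct, max_wc_pct = b$max_wc_pct,
    stm = stm(run$sample$dry_mass_mg, run$sample$area_cm2),
    whc_mm = whc(run$sample$full_wet_mass_mg, run$sample$dry_mass_mg,
                 run$sample$area_cm2),
    chl_a = chl$chl_a, chl_ab = chl$chl_ab,
    censored_low = b$censored_low, censored_high = b$censored_high)
  out
}

#' Extract core parameters for a collection of runs
#'
#' @param runs Named list of [drying_run()]s.
#' @param pigments Optional list of [pigment_measurement()]s (matched to
#'   runs by `sample_id`).
#' @param ... Passed to [compile_core_parameters()].
#' @return data.frame, one row per sample, in the canonical column order of
#'   [write_core_parameters()].
#' @export
extract_core_parameters <- function(runs, pigments = NULL, ...) {
  rows <- lapply(runs, function(run) {
    pg <- if (!is.null(pigments))
      Filter(function(p) p$sample_id == run$sample$sample_id, pigments)
    if (length(pg) == 0L) pg <- NULL
    cp <- compile_core_parameters(run, pigments = pg, ...)
    cbind(data.frame(sample_id = run$sample$sample_id,
                     species_code = run$sample$species_code,
                     site = run$sample$site, stringsAsFactors = FALSE),
          as.data.frame(cp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
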