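# Tabular readers and writers. Interchange formats are plain UTF-8 CSV/TSV
# (delimiter chosen by file extension: .tsv/.tab/.txt tab, otherwise comma),
# decimal point ".". Gas exchange is stored long ("tidy"): one row per
# (sample, curve, PPFD step).

GAS_EXCHANGE_COLS <- c("sample_id", "curve_index", "ppfd", "assim",
                       "mass_before_mg", "mass_after_mg")
SAMPLE_COLS <- c("sample_id", "species_code", "site", "dry_mass_mg",
                 "area_cm2", "full_wet_mass_mg")

#' Read a sample metadata table
#'
#' @param path CSV/TSV with columns `sample_id`, `species_code`, `site`,
#'   `dry_mass_mg`, `area_cm2`, `full_wet_mass_mg`.
#' @return Named list of [thallus_sample()] objects.
#' @export
read_samples <- function(path) {
  df <- read_delim_table(path, SAMPLE_COLS)
  if (nrow(df) == 0L) schema_error(sprintf("%s: no sample rows", path))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    validation_error(sprintf("duplicate sample_id: %s",
                             paste(unique(dup), collapse = ", ")))
  out <- lapply(seq_len(nrow(df)), function(i)
    thallus_sample(df$sample_id[i], df$species_code[i], df$site[i],
                   df$dry_mass_mg[i], df$area_cm2[i], df$full_wet_mass_mg[i]))
  names(out) <- df$sample_id
  out
}

#' Write a sample metadata table
#'
#' @param samples List of [thallus_sample()]s.
#' @param path Output CSV/TSV path.
#' @export
write_samples <- function(samples, path) {
  df <- do.call(rbind, lapply(samples, function(s)
    data.frame(sample_id = s$sample_id, species_code = s$species_code,
               site = s$site, dry_mass_mg = s$dry_mass_mg,
               area_cm2 = s$area_cm2, full_wet_mass_mg = s$full_wet_mass_mg,
               stringsAsFactors = FALSE)))
  write_delim_table(df, path)
}

#' Read a long-format gas-exchange table into drying runs
#'
#' Rows are grouped by sample and curve, curves ordered by `curve_index`,
#' and every type invariant is enforced; violations are reported with the
#' offending sample/curve named.
#'
#' @param path CSV/TSV with columns `sample_id`, `curve_index`, `ppfd`,
#'   `assim`, `mass_before_mg`, `mass_after_mg`.
#' @param samples Named list of [thallus_sample()]s (from [read_samples()]);
#'   every sample_id in the table must be present.
#' @return Named list of [drying_run()] objects.
#' @export
read_gas_exchange <- function(path, samples) {
  df <- read_delim_table(path, GAS_EXCHANGE_COLS)
  if (nrow(df) == 0L) schema_error(sprintf("%s: no data rows", path))
  bad <- !vapply(df[c("curve_index", "ppfd", "assim", "mass_before_mg",
                      "mass_after_mg")], is.numeric, logical(1))
  if (any(bad))
    schema_error(sprintf("%s: non-numeric column(s): %s", path,
                         paste(names(bad)[bad], collapse = ", ")))
  unknown <- setdiff(unique(df$sample_id), names(samples))
  if (length(unknown))
    validation_error(sprintf("gas-exchange table references unknown sample(s): %s",
                             paste(unknown, collapse = ", ")))
  runs <- lapply(split(df, df$sample_id), function(d) {
    curves <- lapply(split(d, d$curve_index), function(cd) {
      cd <- cd[order(cd$ppfd), , drop = FALSE]
      light_curve(cd$curve_index[1L], cd$ppfd, cd$assim,
                  cd$mass_before_mg[1L], cd$mass_after_mg[1L])
    })
    curves <- curves[order(vapply(curves, function(cv) cv$curve_index, integer(1)))]
    drying_run(samples[[d$sample_id[1L]]], curves)
  })
  runs[order(names(runs))]
}

#' Write drying runs to a long-format gas-exchange table
#'
#' @param runs List of [drying_run()]s.
#' @param path Output CSV/TSV path.
#' @export
write_gas_exchange <- function(runs, path) {
  rows <- lapply(runs, function(run) {
    do.call(rbind, lapply(run$curves, function(cv)
      data.frame(sample_id = run$sample$sample_id,
                 curve_index = cv$curve_index,
                 ppfd = cv$ppfd, assim = cv$assim,
                 mass_before_mg = cv$mass_before_mg,
                 mass_after_mg = cv$mass_after_mg,
                 stringsAsFactors = FALSE)))
  })
  write_delim_table(do.call(rbind, rows), path)
}

CORE_PARAM_COLS <- c("sample_id", "species_code", "site",
                     "lcp", "lsp", "max_np", "dr_max", "cge",
                     "min_wc_mm", "max_wc_mm", "opt_wc_mm",
                     "min_wc_pct", "max_wc_pct", "opt_wc_pct",
                     "stm", "whc_mm", "chl_a", "chl_ab",
                     "censored_low", "censored_high")

#' Write a core-parameter table
#'
#' One row per sample, stable column order, units recorded in `#` header
#' comment lines along with any provenance metadata supplied.
#'
#' @param params data.frame as returned by [extract_core_parameters()].
#' @param path Output path (TSV recommended).
#' @param meta Named list of provenance keys (seed, thresholds, ...) written
#'   as `# key: value` header lines.
#' @export
write_core_parameters <- function(params, path, meta = list()) {
  if (!is.data.frame(params) || nrow(params) == 0L)
    validation_error("write_core_parameters: empty core-parameter collection")
  miss <- setdiff(CORE_PARAM_COLS, names(params))
  if (length(miss))
    schema_error(sprintf("core-parameter table missing column(s): %s",
                         paste(miss, collapse = ", ")))
  hdr <- c("units: lcp/lsp umol photons m-2 s-1; max_np/dr_max nmol g-1 DM s-1; wc_mm mm H2O; wc_pct % of DM; stm mg cm-2; whc_mm mm H2O; chl ug per mg DM",
           sprintf("%s: %s", names(meta), vapply(meta, format, character(1))))
  write_delim_table(params[CORE_PARAM_COLS], path, header_comments = hdr)
}

#' Read a core-parameter table written by [write_core_parameters()]
#'
#' @param path Input path.
#' @return data.frame in the canonical column order.
#' @export
read_core_parameters <- function(path) {
  df <- read_delim_table(path, CORE_PARAM_COLS)
  num_cols <- setdiff(CORE_PARAM_COLS,
                      c("sample_id", "species_code", "site",
                        "censored_low", "censored_high"))
  for (cn in num_cols) df[[cn]] <- as.numeric(df[[cn]])
  df$censored_low <- as.logical(df$censored_low)
  df$censored_high <- as.logical(df$censored_high)
  df[CORE_PARAM_COLS]
}

#' Read a pigment absorbance table
#'
#' @param path CSV/TSV with columns `sample_id`, `a665`, `a649`,
#'   `extract_volume_ml`, `dm_mg`; two rows per sample when the thallus was
#'   extracted twice (contents are summed downstream).
#' @return List of [pigment_measurement()]s (possibly several per sample).
#' @export
read_pigments <- function(path) {
  df <- read_delim_table(path, c("sample_id", "a665", "a649",
                                 "extract_volume_ml", "dm_mg"))
  lapply(seq_len(nrow(df)), function(i)
    pigment_measurement(df$sample_id[i], df$a665[i], df$a649[i],
                        df$extract_volume_ml[i], df$dm_mg[i]))
}

#' Read a habitat-association rank table
#'
#' @param path CSV/TSV with columns `species_code`, `rank`.
#' @return Validated rank data.frame (see [habitat_ranks()]).
#' @export
read_habitat_ranks <- function(path) {
  df <- read_delim_table(path, c("species_code", "rank"))
  habitat_ranks(df$species_code, df$rank)
}
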