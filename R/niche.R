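# Desk-scale realised-niche summaries: occurrence cleaning, nearest-cell
# climate joins against a small in-memory grid or pre-extracted cell table,
# and per-species precipitation-breadth metrics. Bulk occurrence/climate
# retrieval is explicitly the user's job; these tools are download-free.

#' Clean an occurrence table
#'
#' Removes, in order: rows with missing coordinates or year, rows with
#' out-of-range coordinates (lat outside [-90, 90], lon outside
#' [-180, 180]), rows outside the year window (inclusive at both ends),
#' exact duplicate (species, lat, lon, year) rows, and - when a land mask
#' is supplied - rows the mask marks as non-terrestrial. Darwin-Core-style
#' column names (`decimalLatitude`, `decimalLongitude`) are accepted.
#'
#' @param records data.frame with columns `species`, `lat`, `lon`, `year`.
#' @param year_range Inclusive year window (default 1979-2013).
#' @param land_mask Optional predicate `function(lon, lat)` returning TRUE
#'   for terrestrial points.
#' @return List with `records` (cleaned data.frame) and `audit` (named
#'   counts per filter stage; stages sum to the input row count).
#' @export
clean_occurrences <- function(records, year_range = c(1979, 2013),
                              land_mask = NULL) {
  nm <- names(records)
  ren <- c(decimalLatitude = "lat", decimalLongitude = "lon")
  for (old in names(ren)) if (old %in% nm && !(ren[[old]] %in% nm))
    names(records)[names(records) == old] <- ren[[old]]
  need <- c("species", "lat", "lon", "year")
  miss <- setdiff(need, names(records))
  if (length(miss))
    schema_error(sprintf("occurrence table missing column(s): %s",
                         paste(miss, collapse = ", ")))
  n0 <- nrow(records)
  ok_coord <- !is.na(records$lat) & !is.na(records$lon) & !is.na(records$year)
  missing_removed <- sum(!ok_coord)
  r <- records[ok_coord, , drop = FALSE]

  in_range <- r$lat >= -90 & r$lat <= 90 & r$lon >= -180 & r$lon <= 180
  erroneous_removed <- sum(!in_range)
  r <- r[in_range, , drop = FALSE]

  in_years <- r$year >= year_range[1L] & r$year <= year_range[2L]
  year_removed <- sum(!in_years)
  r <- r[in_years, , drop = FALSE]

  dup <- duplicated(r[c("species", "lat", "lon", "year")])
  duplicates_removed <- sum(dup)
  r <- r[!dup, , drop = FALSE]

  mask_removed <- 0L
  if (!is.null(land_mask)) {
    on_land <- mapply(land_mask, r$lon, r$lat)
    mask_removed <- sum(!on_land)
    r <- r[on_land, , drop = FALSE]
  }
  rownames(r) <- NULL
  list(records = r,
       audit = c(input = n0, retained = nrow(r),
                 missing_removed = missing_removed,
                 erroneous_removed = erroneous_removed,
                 year_removed = year_removed,
                 duplicates_removed = duplicates_removed,
                 mask_removed = mask_removed))
}

#' Construct a gridded climate lookup
#'
#' A small regular lon/lat grid held in memory, built either from axis
#' vectors plus a value matrix or from a pre-extracted long table of cell
#' centres (`lon`, `lat`, `value`), which is the recommended download-free
#' exchange format.
#'
#' @param lon,lat Cell-centre coordinate vectors (strictly monotone).
#' @param values Matrix `length(lon) x length(lat)` of climate values.
#' @param table Alternatively, a data.frame with columns `lon`, `lat`,
#'   `value` covering a full regular grid.
#' @return Object of class `climate_grid`.
#' @export
climate_grid <- function(lon = NULL, lat = NULL, values = NULL, table = NULL) {
  if (!is.null(table)) {
    miss <- setdiff(c("lon", "lat", "value"), names(table))
    if (length(miss))
      schema_error(sprintf("climate table missing column(s): %s",
                           paste(miss, collapse = ", ")))
    lon <- sort(unique(table$lon)); lat <- sort(unique(table$lat))
    values <- matrix(NA_real_, length(lon), length(lat))
    values[cbind(match(table$lon, lon), match(table$lat, lat))] <- table$value
  }
  if (is.null(lon) || is.null(lat) || is.null(values))
    validation_error("climate_grid: supply lon/lat/values or a table")
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0))
    validation_error("climate_grid: axes must be strictly increasing")
  if (!is.matrix(values) || nrow(values) != length(lon) ||
      ncol(values) != length(lat))
    validation_error("climate_grid: values must be a length(lon) x length(lat) matrix")
  structure(list(lon = lon, lat = lat, values = values), class = "climate_grid")
}

# Nearest index on an axis; equidistant points break toward the lower index.
nearest_index <- function(coord, axis) {
  vapply(coord, function(z) {
    d <- abs(axis - z)
    which(d == min(d))[1L]
  }, integer(1))
}

#' Join climate values onto occurrence records
#'
#' Nearest-cell join; records outside the grid's coverage (further than one
#' cell spacing beyond the edge) are flagged `in_coverage = FALSE` with a
#' missing value, never silently dropped. Ties (a point equidistant between
#' two cell centres) break deterministically toward the lower-indexed cell.
#'
#' @param records Cleaned occurrence data.frame (`lon`, `lat` columns).
#' @param grid A [climate_grid()].
#' @param value_name Name of the appended value column.
#' @return `records` with appended `value_name` and `in_coverage` columns.
#' @export
join_climate <- function(records, grid, value_name = "climate_value") {
  if (!inherits(grid, "climate_grid")) validation_error("grid must be a climate_grid")
  if (nrow(records) == 0L) validation_error("join_climate: no records")
  step_lon <- if (length(grid$lon) > 1L) min(diff(grid$lon)) else Inf
  step_lat <- if (length(grid$lat) > 1L) min(diff(grid$lat)) else Inf
  ii <- nearest_index(records$lon, grid$lon)
  jj <- nearest_index(records$lat, grid$lat)
  covered <- abs(grid$lon[ii] - records$lon) <= step_lon / 2 + 1e-12 &
    abs(grid$lat[jj] - records$lat) <= step_lat / 2 + 1e-12
  vals <- grid$values[cbind(ii, jj)]
  vals[!covered] <- NA_real_
  if (!any(covered)) validation_error("join_climate: no record falls inside the grid")
  records[[value_name]] <- vals
  records$in_coverage <- covered
  records
}

#' Per-species niche-breadth summaries and rank trend
#'
#' Summarises the climate values per species (median, interquartile range,
#' 5-95% range width) and tests for a monotone trend between habitat rank
#' and breadth with a Spearman rank correlation (the published qualitative
#' claim is a negative trend: narrower precipitation range for the most
#' strongly rainforest-associated species).
#'
#' @param records data.frame with `species` and a climate value column.
#' @param ranks Rank table from [habitat_ranks()] (matched on `species` =
#'   `species_code`).
#' @param value_name Climate value column name.
#' @param min_n Minimum records per species to enter the summaries.
#' @return List with `summary` (per-species data.frame) and `trend`
#'   (Spearman rho and p between rank and 5-95% breadth; `NULL` when fewer
#'   than 3 species qualify).
#' @export
niche_breadth <- function(records, ranks, value_name = "climate_value",
                          min_n = 5L) {
  if (!value_name %in% names(records))
    schema_error(sprintf("records lack value column '%s'", value_name))
  v <- records[[value_name]]
  keep <- is.finite(v)
  records <- records[keep, , drop = FALSE]; v <- v[keep]
  sp <- split(v, records$species)
  flagged <- names(sp)[vapply(sp, length, integer(1)) < min_n]
  sp <- sp[!(names(sp) %in% flagged)]
  if (length(sp) == 0L) validation_error("niche_breadth: no species with enough data")
  summ <- do.call(rbind, lapply(names(sp), function(s) {
    x <- sp[[s]]
    q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE,
                         type = 7)
    data.frame(species = s, n = length(x), median = q[3L],
               iqr = q[4L] - q[2L], breadth_5_95 = q[5L] - q[1L],
               stringsAsFactors = FALSE)
  }))
  summ$rank <- ranks$rank[match(summ$species, ranks$species_code)]
  trend <- NULL
  ok <- is.finite(summ$rank)
  if (sum(ok) >= 3L) {
    ct <- suppressWarnings(
      stats::cor.test(summ$rank[ok], summ$breadth_5_95[ok], method = "spearman"))
    trend <- list(rho = unname(ct$estimate), p = ct$p.value,
                  n_species = sum(ok))
  }
  list(summary = summ, trend = trend, flagged = flagged)
}
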