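# Internal helpers shared across modules.

#' hydroniche: lichen fundamental-niche quantification from gas exchange
#'
#' @description Core-parameter extraction from hydration-resolved CO2
#'   gas-exchange drying runs, a calibrated protocol simulator, species
#'   comparison statistics and ordinal habitat-association inference.
#' @keywords internal
"_PACKAGE"

abort_hn <- function(msg, class) {
  stop(structure(class = c(class, "hydroniche_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

schema_error <- function(msg) abort_hn(msg, "hydroniche_schema_error")
validation_error <- function(msg) abort_hn(msg, "hydroniche_validation_error")
io_error <- function(msg) abort_hn(msg, "hydroniche_io_error")

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
# Mersenne-Twister / Inversion pinned so runs are reproducible across platforms.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is_scalar_number(seed))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# First upward crossing of `threshold` by y(x) scanning left to right,
# linearly interpolated. x strictly increasing. Returns NA when y starts
# at/above threshold (nothing to cross).
interp_up_crossing <- function(x, y, threshold) {
  at <- y >= threshold
  if (at[1L]) return(NA_real_)
  i <- which(at)[1L]
  if (is.na(i)) return(NA_real_)
  x0 <- x[i - 1L]; x1 <- x[i]; y0 <- y[i - 1L]; y1 <- y[i]
  if (y1 == y0) return(x1)
  x0 + (x1 - x0) * (threshold - y0) / (y1 - y0)
}

# Last downward crossing (highest x where y falls below threshold, scanning
# from the right). NA when the rightmost point is still at/above threshold.
interp_down_crossing <- function(x, y, threshold) {
  n <- length(y)
  at <- y >= threshold
  if (at[n]) return(NA_real_)
  i <- which(at)
  if (length(i) == 0L) return(NA_real_)
  i <- i[length(i)]                       # last point still above
  x0 <- x[i]; x1 <- x[i + 1L]; y0 <- y[i]; y1 <- y[i + 1L]
  if (y1 == y0) return(x0)
  x0 + (x1 - x0) * (threshold - y0) / (y1 - y0)
}

delim_for_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

read_delim_table <- function(path, required = character()) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim_for_path(path),
                      comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) schema_error(sprintf("cannot parse %s: %s", path,
                                             conditionMessage(e))))
  miss <- setdiff(required, names(df))
  if (length(miss))
    schema_error(sprintf("%s: missing required column(s): %s", path,
                         paste(miss, collapse = ", ")))
  df
}

write_delim_table <- function(df, path, header_comments = character()) {
  con <- tryCatch(suppressWarnings(file(path, open = "wt", encoding = "UTF-8")),
                  error = function(e) io_error(sprintf("cannot open %s for writing", path)))
  on.exit(close(con))
  if (length(header_comments))
    writeLines(paste0("# ", header_comments), con)
  utils::write.table(df, con, sep = delim_for_path(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
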