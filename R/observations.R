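#' Bleaching severity score from percent of corals bleached
#'
#' Standard four-level severity coding of survey records: 0 = no bleaching
#' (0%), 1 = mild (1-10%), 2 = moderate (11-50%), 3 = severe (>50%).
#' Non-integer percentages fall in the bin of their ceiling-ward boundary:
#' (0, 10] -> 1, (10, 50] -> 2, (50, 100] -> 3.
#'
#' @param percent Numeric vector of percent bleached, 0-100.
#' @return Integer severity scores in `{0, 1, 2, 3}`.
#' @examples
#' severity_from_percent(c(0, 10, 11, 50, 51))  # 0 1 2 2 3
#' @export
severity_from_percent <- function(percent) {
  if (any(is.na(percent)) || any(percent < 0 | percent > 100))
    stop("percent bleached must be within [0, 100]")
  as.integer(cut(percent, breaks = c(-Inf, 0, 10, 50, 100), labels = FALSE)) - 1L
}

#' Transform severity scores to open-interval proportions
#'
#' Severity scores are divided by 3 to give proportions `y` in `[0, 1]`, then
#' shrunk off the boundary with the Smithson-Verkuilen adjustment
#' `(y * (n - 1) + 0.5) / n`, where `n` is the sample size of the modelled
#' dataset. The result lies strictly inside (0, 1), as a beta likelihood
#' requires, and converges to `score/3` as `n` grows.
#'
#' @param scores Integer severity scores in `{0, 1, 2, 3}`.
#' @param n Sample size used in the adjustment; defaults to
#'   `length(scores)`; must be >= 2.
#' @return Numeric proportions in (0, 1).
#' @examples
#' transform_scores(0:3, n = 237)
#' @export
transform_scores <- function(scores, n = length(scores)) {
  if (!all(scores %in% 0:3)) stop("severity scores must be integers 0-3")
  if (n < 2) stop("sample size n must be >= 2")
  y <- scores / 3
  (y * (n - 1) + 0.5) / n
}

#' Read bleaching observation records from CSV
#'
#' Schema: `record_id`, `date` (ISO-8601 `YYYY-MM-DD`, or `YYYY-MM` for
#' month-only records), `day_known` (logical; optional, inferred from the
#' date format when absent), `lat`, `lon`, `severity` (0-3), and optional
#' `percent` which, when present, must be bin-consistent with `severity`.
#' Month-only dates are resolved to the 15th of the month and flagged.
#'
#' @param path CSV path.
#' @return `data.frame` with columns `record_id`, `date` (`Date`),
#'   `day_known`, `lat`, `lon`, `severity`.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "date", "lat", "lon", "severity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("observation CSV missing columns: ",
                         paste(miss, collapse = ", "))
  raw <- as.character(df$date)
  month_only <- grepl("^\\d{4}-\\d{2}$", raw)
  if (is.null(df$day_known)) df$day_known <- !month_only
  df$day_known <- as.logical(df$day_known) & !month_only
  raw[month_only] <- paste0(raw[month_only], "-15")
  df$date <- as.Date(raw)
  if (anyNA(df$date)) stop("unparseable observation dates")
  if (!all(df$severity %in% 0:3)) stop("severity must be an integer 0-3")
  if (!is.null(df$percent)) {
    ok <- is.na(df$percent) | severity_from_percent(df$percent) == df$severity
    if (!all(ok))
      stop("percent column inconsistent with severity bins for records: ",
           paste(utils::head(df$record_id[!ok], 5), collapse = ", "))
  }
  df[c("record_id", "date", "day_known", "lat", "lon", "severity")]
}

#' Write observation records (optionally with attached covariates) to CSV
#'
#' @param obs Observation `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  obs$date <- format(obs$date)
  utils::write.csv(obs, path, row.names = FALSE)
  invisible(path)
}

#' Attach DHW covariates to bleaching observations
#'
#' Each record is assigned the DHW of the grid cell that encapsulates its
#' coordinates (half-open cell convention, see [grid_cell_key()]) on its
#' survey date; records with only month precision use the DHW of the 15th of
#' that month.
#'
#' @param obs Observation `data.frame` as from [read_observations()].
#' @param dhw_list List of `dhw_series`, one per cell.
#' @param res Grid resolution in degrees (default 0.05).
#' @return `obs` with `dhw` and `cell_id` columns added.
#' @export
attach_dhw <- function(obs, dhw_list, res = 0.05) {
  keys <- vapply(dhw_list, function(s) grid_cell_key(s$lat, s$lon, res), "")
  if (anyDuplicated(keys)) stop("dhw_list contains cells with duplicate grid keys")
  okey <- grid_cell_key(obs$lat, obs$lon, res)
  idx <- match(okey, keys)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("no DHW cell covers observation %s at (%.4f, %.4f)",
                 obs$record_id[bad], obs$lat[bad], obs$lon[bad]))
  }
  dd <- obs$date
  dd[!obs$day_known] <- as.Date(format(dd[!obs$day_known], "%Y-%m-15"))
  # daily_series guarantees unbroken daily cadence, so date lookup is O(1)
  dhw <- vapply(seq_len(nrow(obs)), function(i) {
    s <- dhw_list[[idx[i]]]
    j <- as.integer(dd[i]) - as.integer(s$dates[1L]) + 1L
    if (j < 1L || j > length(s$dates))
      stop(sprintf("DHW series for cell %s does not cover %s (record %s)",
                   s$cell_id, format(dd[i]), obs$record_id[i]))
    v <- s$dhw[j]
    if (is.na(v))
      stop(sprintf("DHW missing on %s in cell %s (record %s)",
                   format(dd[i]), s$cell_id, obs$record_id[i]))
    v
  }, numeric(1))
  obs$cell_id <- vapply(dhw_list[idx], `[[`, "", "cell_id")
  obs$dhw <- dhw
  obs
}
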