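#' Read a daily snow-depth series
#'
#' Reads daily snow depths from either a generic two-column CSV
#' (`date`, `snow_cm`; ISO-8601 dates) or a DWD "KL daily" historical climate
#' file (semicolon-separated, date column `MESS_DATUM` as `YYYYMMDD`, snow
#' depth column `SHK_TAG` in cm, sentinel `-999` meaning missing). Records are
#' sorted by date; duplicated dates and negative non-sentinel depths are
#' rejected. Missing depths are kept as `NA`, never silently zeroed.
#'
#' @param path Path to the file.
#' @param dialect `"generic_csv"` or `"dwd_kl_daily"`.
#' @return A data frame of class `snow_series` with columns `date` (`Date`)
#'   and `snow_cm` (numeric, `NA` allowed).
#' @export
read_daily_snow <- function(path, dialect = c("generic_csv", "dwd_kl_daily")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "generic_csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("date", "snow_cm") %in% names(df)))
      stop("generic snow CSV needs columns date, snow_cm", call. = FALSE)
    out <- data.frame(date = as.Date(df$date),
                      snow_cm = as.numeric(df$snow_cm))
  } else {
    df <- read.csv(path, sep = ";", stringsAsFactors = FALSE,
                   strip.white = TRUE)
    names(df) <- trimws(names(df))
    if (!all(c("MESS_DATUM", "SHK_TAG") %in% names(df)))
      stop("DWD KL daily file needs columns MESS_DATUM and SHK_TAG",
           call. = FALSE)
    depth <- as.numeric(df$SHK_TAG)
    depth[depth <= -999] <- NA_real_  # DWD missing-value sentinel
    out <- data.frame(date = as.Date(as.character(df$MESS_DATUM),
                                     format = "%Y%m%d"),
                      snow_cm = depth)
  }
  snow_series(out$date, out$snow_cm)
}

#' Construct a validated snow series
#'
#' @param date Vector of dates (`Date` or coercible).
#' @param snow_cm Numeric snow depths in cm; `NA` marks missing days.
#' @return A `snow_series` data frame sorted by date.
#' @export
snow_series <- function(date, snow_cm) {
  date <- as.Date(date)
  if (anyNA(date)) stop("unparseable dates in snow series", call. = FALSE)
  if (anyDuplicated(date))
    stop("duplicated dates in snow series", call. = FALSE)
  snow_cm <- as.numeric(snow_cm)
  if (any(snow_cm < 0, na.rm = TRUE))
    stop("negative snow depth in series (only the DWD -999 sentinel is ",
         "interpreted as missing)", call. = FALSE)
  o <- order(date)
  structure(data.frame(date = date[o], snow_cm = snow_cm[o]),
            class = c("snow_series", "data.frame"))
}

#' Snow-days covariate per occasion
#'
#' Counts, for every occasion of a calendar, the days within the 14-day
#' interval whose snow depth is at least `depth_threshold` cm. This count is
#' the covariate used on both the survival and the detection scale: a proxy
#' for how long prey stayed inaccessible under snow during the fortnight.
#'
#' @param series A [snow_series()].
#' @param calendar An `occasion_calendar`.
#' @param depth_threshold Depth (cm) from which a day counts as snow-covered.
#' @param missing Policy for days absent from the series or recorded as `NA`:
#'   `"error"` (strict, default) or `"zero"` (count as snow-free, with one
#'   warning).
#' @return Integer vector of per-occasion snow-day counts in `[0, 14]`.
#' @export
snow_days_by_occasion <- function(series, calendar, depth_threshold = 1,
                                  missing = c("error", "zero")) {
  missing <- match.arg(missing)
  stopifnot(inherits(series, "snow_series"),
            inherits(calendar, "occasion_calendar"))
  if (depth_threshold < 0) stop("depth_threshold must be >= 0", call. = FALSE)
  depth <- setNames(series$snow_cm, format(series$date, "%Y-%m-%d"))
  n_missing <- 0L
  counts <- vapply(seq_len(nrow(calendar)), function(k) {
    days <- calendar$start_date[k] + 0:13
    d <- depth[format(days, "%Y-%m-%d")]
    n_missing <<- n_missing + sum(is.na(d))
    if (anyNA(d) && missing == "error")
      stop("snow series does not cover occasion ", k,
           " (missing days under strict policy)", call. = FALSE)
    sum(d >= depth_threshold, na.rm = TRUE)
  }, numeric(1))
  if (n_missing > 0L && missing == "zero")
    warning(n_missing, " missing snow days counted as snow-free",
            call. = FALSE)
  as.integer(counts)
}

#' Attach snow-day counts to a calendar
#'
#' @param calendar An `occasion_calendar`.
#' @param snow_days Integer vector, one count in `[0, 14]` per occasion.
#' @return The calendar with its `snow_days` column filled.
#' @export
set_snow_days <- function(calendar, snow_days) {
  stopifnot(inherits(calendar, "occasion_calendar"))
  if (length(snow_days) != nrow(calendar))
    stop("snow_days must have one value per occasion", call. = FALSE)
  if (any(is.na(snow_days)) || any(snow_days < 0 | snow_days > 14))
    stop("snow_days must lie in [0, 14]", call. = FALSE)
  calendar$snow_days <- as.integer(snow_days)
  calendar
}

#' Standardize the snow-days covariate
#'
#' Affine transform `z = (snow_days - center) / scale`. The center and scale
#' are stored as attributes so the transform is invertible and can be recorded
#' in the run manifest; derived-demography scenarios need them to map
#' scenario snow-day totals back onto the fitted covariate scale.
#'
#' @param snow_days Per-occasion snow-day counts.
#' @param center,scale Affine parameters; `scale` must be positive.
#' @return Numeric vector of class `snow_z` with attributes `center`, `scale`.
#' @seealso [snow_standardization()] for the package's default policy.
#' @export
standardize_snow <- function(snow_days, center, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale <= 0)
    stop("scale must be a positive number", call. = FALSE)
  structure(as.numeric((snow_days - center) / scale),
            center = center, scale = scale, class = "snow_z")
}

#' Invert a standardized snow covariate
#'
#' @param z A `snow_z` vector from [standardize_snow()].
#' @return The snow-day counts that produced `z`.
#' @export
unstandardize_snow <- function(z) {
  as.numeric(z) * attr(z, "scale") + attr(z, "center")
}

#' Default standardization policy for the snow covariate
#'
#' Returns `center = 0` and `scale` equal to the standard deviation of
#' snow-day counts over the winter-season occasions. Dividing by the winter SD
#' puts the regression coefficient on a per-winter-SD scale while keeping
#' `z = 0` exactly at zero snow days, so the winter intercept remains
#' interpretable as snow-free winter survival. (Mean-centering over winter
#' occasions would shift that interpretation to survival at average snow
#' cover; callers who want a full z-score can pass `center = mean(...)` to
#' [standardize_snow()] themselves.)
#'
#' @param snow_days Per-occasion snow-day counts.
#' @param calendar The `occasion_calendar` the counts belong to.
#' @return A list with elements `center` (0) and `scale` (winter SD).
#' @export
snow_standardization <- function(snow_days, calendar) {
  stopifnot(inherits(calendar, "occasion_calendar"),
            length(snow_days) == nrow(calendar))
  w <- snow_days[calendar$season == "winter"]
  if (length(w) < 2L)
    stop("calendar has fewer than two winter occasions", call. = FALSE)
  s <- sd(w)
  if (!is.finite(s) || s == 0)
    stop("winter snow-day counts have zero variance; supply an explicit ",
         "scale to standardize_snow()", call. = FALSE)
  list(center = 0, scale = s)
}
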