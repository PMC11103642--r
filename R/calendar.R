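#' Season window definitions
#'
#' Year-agnostic calendar windows delimiting the four biological seasons of a
#' juvenile bird's first year: the post-fledging period (summer), natal
#' dispersal (autumn), the stationary winter period, and the first breeding
#' season (spring). The default windows are summer 15 May--1 August, autumn
#' 2 August--23 October, winter 24 October--12 March, and spring
#' 13 March--15 June. Spring and summer deliberately overlap by four weeks
#' (15 May--15 June) so that staggered fledging dates and staggered onset of
#' first reproduction can both be accommodated; see
#' [season_of_date()] for how the overlap is resolved.
#'
#' @param summer,autumn,winter,spring Character vectors of length 2 giving the
#'   first and last day of each window as `"MM-DD"` strings. Windows may wrap
#'   across the year end (as winter does by default).
#' @return An object of class `season_definition`: a named list of the four
#'   windows.
#' @examples
#' season_definition()
#' @export
season_definition <- function(summer = c("05-15", "08-01"),
                              autumn = c("08-02", "10-23"),
                              winter = c("10-24", "03-12"),
                              spring = c("03-13", "06-15")) {
  def <- list(summer = summer, autumn = autumn, winter = winter,
              spring = spring)
  for (nm in names(def)) {
    w <- def[[nm]]
    if (length(w) != 2L || !all(grepl("^[0-9]{2}-[0-9]{2}$", w)))
      stop("season window '", nm, "' must be two \"MM-DD\" strings",
           call. = FALSE)
  }
  structure(def, class = "season_definition")
}

# is month-day string md inside window w (possibly wrapping the year end)?
.md_in_window <- function(md, w) {
  if (w[1] <= w[2]) md >= w[1] & md <= w[2] else md >= w[1] | md <= w[2]
}

#' Season of a calendar date
#'
#' Maps a date to exactly one season label under a [season_definition()]. For
#' dates inside the deliberate spring/summer overlap window the label is
#' decided by the `overlap` argument: `"summer"` (default) reads the window as
#' the start of the post-fledging season of a new cohort, `"spring"` reads it
#' as the tail of the first breeding season of the previous cohort.
#'
#' @param date A `Date` (or something coercible) vector.
#' @param season_def A [season_definition()].
#' @param overlap Label to use for dates that fall in more than one window,
#'   `"summer"` or `"spring"`.
#' @return Character vector of season labels, one per date.
#' @examples
#' season_of_date(as.Date("2009-06-01"))  # "summer"
#' season_of_date(as.Date("2009-10-24"))  # "winter"
#' season_of_date(as.Date("2010-03-12"))  # "winter"
#' season_of_date(as.Date("2010-03-13"))  # "spring"
#' @export
season_of_date <- function(date, season_def = season_definition(),
                           overlap = c("summer", "spring")) {
  overlap <- match.arg(overlap)
  date <- as.Date(date)
  md <- format(date, "%m-%d")
  vapply(md, function(d) {
    hit <- names(season_def)[vapply(season_def,
                                    function(w) .md_in_window(d, w),
                                    logical(1))]
    if (length(hit) == 1L) return(hit)
    if (length(hit) == 0L)
      stop("date with month-day ", d, " falls in no season window",
           call. = FALSE)
    if (setequal(hit, c("summer", "spring"))) return(overlap)
    stop("date with month-day ", d, " falls in windows ",
         paste(hit, collapse = ", "),
         "; only the spring/summer overlap is resolvable", call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

#' Build a biweekly occasion calendar
#'
#' Constructs the time axis of the analysis: `n_occasions` contiguous 14-day
#' occasions, half-open intervals `[start, start + 14)`, anchored at
#' `origin_date`. Each occasion is assigned a season from the date of its
#' midpoint (day 8 of the fortnight), a tracking-effort regime, and an empty
#' `snow_days` slot to be filled from a daily snow series (see
#' [snow_days_by_occasion()]).
#'
#' The spring/summer overlap is resolved by `overlap_rule`:
#' * `"first_summer"` (default): occasion midpoints before the first 2 August
#'   on or after `origin_date` are labelled summer (the calendar's first
#'   post-fledging season), later overlap occasions spring. Appropriate for a
#'   single cohort tracked from fledging into its first breeding season.
#' * `"summer"` / `"spring"`: resolve every overlap occasion to that label.
#'   `"summer"` is the appropriate choice for a multi-cohort study calendar in
#'   which new fledglings are released in the overlap window every year.
#'
#' @param origin_date Start date of occasion 1.
#' @param n_occasions Number of occasions (positive integer).
#' @param effort_spec Optional list with integer vectors `none` and/or
#'   `reduced` giving the occasion indices with zero and reduced tracking
#'   effort; all other occasions get full effort.
#' @param season_def A [season_definition()].
#' @param overlap_rule How to resolve the spring/summer overlap; see Details.
#' @return A data frame of class `occasion_calendar` with columns `occasion`,
#'   `start_date`, `season`, `effort`, `snow_days` and attributes
#'   `origin_date`, `season_def`, `overlap_rule`.
#' @examples
#' cal <- build_occasion_calendar("2009-05-15", 10)
#' head(cal)
#' @export
build_occasion_calendar <- function(origin_date, n_occasions,
                                    effort_spec = NULL,
                                    season_def = season_definition(),
                                    overlap_rule = c("first_summer",
                                                     "summer", "spring")) {
  overlap_rule <- match.arg(overlap_rule)
  origin <- as.Date(origin_date)
  if (is.na(origin)) stop("invalid origin_date", call. = FALSE)
  if (length(n_occasions) != 1L || is.na(n_occasions) || n_occasions < 1 ||
      n_occasions != round(n_occasions))
    stop("n_occasions must be a positive integer", call. = FALSE)
  n_occasions <- as.integer(n_occasions)

  start <- origin + 14L * (seq_len(n_occasions) - 1L)
  mid <- start + 7L

  if (overlap_rule == "first_summer") {
    # first 2 August on or after the origin
    yr <- as.integer(format(origin, "%Y"))
    first_aug <- as.Date(paste0(yr, "-08-02"))
    if (first_aug < origin) first_aug <- as.Date(paste0(yr + 1L, "-08-02"))
    season <- ifelse(mid < first_aug,
                     season_of_date(mid, season_def, overlap = "summer"),
                     season_of_date(mid, season_def, overlap = "spring"))
  } else {
    season <- season_of_date(mid, season_def, overlap = overlap_rule)
  }

  effort <- rep("full", n_occasions)
  if (!is.null(effort_spec)) {
    if (!is.list(effort_spec) ||
        !all(names(effort_spec) %in% c("none", "reduced")))
      stop("effort_spec must be a list with elements 'none' and/or 'reduced'",
           call. = FALSE)
    idx <- unlist(effort_spec, use.names = FALSE)
    if (length(idx) &&
        (any(idx < 1 | idx > n_occasions | idx != round(idx))))
      stop("effort_spec indices must lie in 1..n_occasions", call. = FALSE)
    if (anyDuplicated(idx))
      stop("effort_spec assigns an occasion to more than one regime",
           call. = FALSE)
    if (!is.null(effort_spec$none)) effort[effort_spec$none] <- "none"
    if (!is.null(effort_spec$reduced)) effort[effort_spec$reduced] <- "reduced"
  }

  structure(
    data.frame(occasion = seq_len(n_occasions),
               start_date = start,
               season = season,
               effort = effort,
               snow_days = NA_integer_,
               stringsAsFactors = FALSE),
    class = c("occasion_calendar", "data.frame"),
    origin_date = origin,
    season_def = season_def,
    overlap_rule = overlap_rule
  )
}

#' Default effort regimes of the field study
#'
#' Occasion indices, on the default 79-occasion calendar anchored at
#' 15 May 2009, reproducing the field effort structure: four occasions with no
#' radio-tracking in the first winter / early spring, three occasions with
#' reduced effort in mid-winter of year 1 and three in late winter of year 2,
#' and full effort everywhere else.
#'
#' @return A list with integer vectors `none` and `reduced`, suitable as the
#'   `effort_spec` argument of [build_occasion_calendar()].
#' @export
study_effort_spec <- function() {
  list(none = 18:21, reduced = c(15:17, 46:48))
}

#' The default multi-cohort study calendar
#'
#' Convenience constructor for the calendar used throughout the package's
#' analysis scripts: 79 biweekly occasions from 15 May 2009 (spanning to late
#' May 2012, covering three summer release windows and three winters), with
#' the study's effort regimes ([study_effort_spec()]) and the spring/summer
#' overlap resolved to summer so that every cohort's releases fall in
#' summer-labelled occasions.
#'
#' @param origin_date Start date of occasion 1.
#' @param n_occasions Number of occasions.
#' @param effort_spec Effort specification; see [build_occasion_calendar()].
#' @return An `occasion_calendar`.
#' @export
study_calendar <- function(origin_date = "2009-05-15", n_occasions = 79,
                           effort_spec = study_effort_spec()) {
  build_occasion_calendar(origin_date, n_occasions,
                          effort_spec = effort_spec,
                          overlap_rule = "summer")
}

#' Occasion containing a tagging date
#'
#' @param tagging_date Date (or coercible) of tagging/release; vectorized.
#' @param calendar An `occasion_calendar`.
#' @return Integer occasion index whose half-open interval contains the date.
#' @examples
#' cal <- build_occasion_calendar("2009-05-15", 4)
#' release_occasion("2009-06-05", cal)  # 2
#' @export
release_occasion <- function(tagging_date, calendar) {
  stopifnot(inherits(calendar, "occasion_calendar"))
  d <- as.Date(tagging_date)
  origin <- attr(calendar, "origin_date")
  idx <- as.integer(floor(as.numeric(d - origin) / 14)) + 1L
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > nrow(calendar)))
    stop("tagging date outside the calendar span", call. = FALSE)
  idx
}

#' Season run lengths along a calendar
#'
#' @param calendar An `occasion_calendar`.
#' @return A data frame with columns `season` and `length` giving consecutive
#'   runs of identical season labels.
#' @export
season_run_lengths <- function(calendar) {
  r <- rle(calendar$season)
  data.frame(season = r$values, length = r$lengths,
             stringsAsFactors = FALSE)
}

#' Read a calendar configuration file
#'
#' Builds an [build_occasion_calendar()] from a YAML or JSON configuration
#' with fields `origin_date`, `n_occasions`, optional `effort_spec` (mapping
#' with `none`/`reduced` index lists), optional `seasons` (mapping of season
#' name to a two-element `MM-DD` window) and optional `overlap_rule`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `occasion_calendar`.
#' @export
calendar_from_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sd <- season_definition()
  if (!is.null(cfg$seasons)) {
    sd <- do.call(season_definition, lapply(cfg$seasons, unlist))
  }
  es <- if (!is.null(cfg$effort_spec)) {
    lapply(cfg$effort_spec, function(x) as.integer(unlist(x)))
  } else NULL
  build_occasion_calendar(cfg$origin_date, cfg$n_occasions,
                          effort_spec = es, season_def = sd,
                          overlap_rule = cfg$overlap_rule %||% "first_summer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read an occasions table
#'
#' `write_occasions()` serializes a calendar to `occasions.csv` with columns
#' `occasion`, `start_date` (ISO-8601), `season`, `effort`, `snow_days`
#' (occasion indices are 1-based). `read_occasions()` reads such a file back
#' and re-validates contiguity of the 14-day grid.
#'
#' @param calendar An `occasion_calendar`.
#' @param path File path.
#' @return `read_occasions()` returns an `occasion_calendar`.
#' @export
write_occasions <- function(calendar, path) {
  df <- as.data.frame(calendar)
  df$start_date <- format(df$start_date, "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_occasions
#' @export
read_occasions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("occasion", "start_date", "season", "effort", "snow_days")
  if (!all(need %in% names(df)))
    stop("occasions file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$start_date <- as.Date(df$start_date)
  if (!identical(df$occasion, seq_len(nrow(df))))
    stop("occasion indices must be 1..T with no gaps", call. = FALSE)
  if (nrow(df) > 1 &&
      !all(diff(df$start_date) == 14))
    stop("occasions must be contiguous 14-day intervals", call. = FALSE)
  structure(df,
            class = c("occasion_calendar", "data.frame"),
            origin_date = df$start_date[1],
            season_def = season_definition(),
            overlap_rule = "unknown")
}
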