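#' Encounter-history data container
#'
#' Bundles everything the CJS likelihood needs: the binary detection matrix,
#' release occasions, individual covariates, the occasion calendar, and the
#' standardized snow covariate. Validates the CJS conditioning (every
#' individual is detected at its release occasion) and the structural-zero
#' contract (no detections in occasions with zero tracking effort).
#'
#' @param y Integer matrix `individuals x occasions` of detections (0/1).
#' @param f Integer vector of release occasion indices, one per individual.
#' @param covariates Data frame with one row per individual and columns
#'   `mass_z` (standardized age-corrected body mass), `sex` (female 0,
#'   male 1), `fed` (supplementary feeding flag 0/1).
#' @param calendar An `occasion_calendar` with as many rows as `y` has
#'   columns.
#' @param z Standardized snow covariate, one value per occasion (a `snow_z`
#'   from [standardize_snow()] or a plain numeric vector).
#' @return An object of class `cjs_data`.
#' @export
cjs_data <- function(y, f, covariates, calendar, z) {
  stopifnot(inherits(calendar, "occasion_calendar"))
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  n <- nrow(y)
  T <- ncol(y)
  if (T != nrow(calendar))
    stop("y must have one column per calendar occasion", call. = FALSE)
  if (length(z) != T)
    stop("snow covariate must have one value per occasion", call. = FALSE)
  if (length(f) != n)
    stop("f must have one release occasion per individual", call. = FALSE)
  f <- as.integer(f)
  if (n > 0) {
    if (any(f < 1L | f > T))
      stop("release occasions outside the calendar", call. = FALSE)
    if (!all(y %in% c(0L, 1L)))
      stop("y must be a 0/1 matrix", call. = FALSE)
    if (any(y[cbind(seq_len(n), f)] != 1L))
      stop("every individual must be detected at its release occasion",
           call. = FALSE)
    none <- which(calendar$effort == "none")
    if (length(none) && any(y[, none, drop = FALSE] == 1L))
      stop("detections recorded in occasions with zero tracking effort",
           call. = FALSE)
    if (!is.data.frame(covariates) || nrow(covariates) != n ||
        !all(c("mass_z", "sex", "fed") %in% names(covariates)))
      stop("covariates must be a data frame with one row per individual and ",
           "columns mass_z, sex, fed", call. = FALSE)
  } else {
    covariates <- data.frame(mass_z = numeric(0), sex = integer(0),
                             fed = integer(0))
  }
  structure(list(y = y, f = f, covariates = covariates,
                 calendar = calendar, z = as.numeric(z),
                 snow_scaling = list(center = attr(z, "center") %||% 0,
                                     scale = attr(z, "scale") %||% 1)),
            class = "cjs_data")
}

#' @export
print.cjs_data <- function(x, ...) {
  cat("<cjs_data> ", nrow(x$y), " individuals x ", ncol(x$y),
      " biweekly occasions\n", sep = "")
  cat("  effort: ", sum(x$calendar$effort == "full"), " full, ",
      sum(x$calendar$effort == "reduced"), " reduced, ",
      sum(x$calendar$effort == "none"), " none\n", sep = "")
  invisible(x)
}

#' Write / read an encounter-history dataset
#'
#' `write_encounter_data()` writes `encounters.csv` (individual id followed by
#' one 0/1 column per occasion; cells in zero-effort occasions are written as
#' -9 to flag that they are structurally unobservable, as documented in the
#' file header comment), `individuals.csv` (covariates and release indices)
#' and `occasions.csv`. `read_encounter_data()` reads the three files back
#' into a [cjs_data()]; -9 cells are restored as 0.
#'
#' @param data A `cjs_data`.
#' @param dir Directory to write into / read from (created if needed).
#' @return `read_encounter_data()` returns a `cjs_data`.
#' @export
write_encounter_data <- function(data, dir) {
  stopifnot(inherits(data, "cjs_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  y <- data$y
  none <- which(data$calendar$effort == "none")
  if (length(none)) y[, none] <- -9L
  enc <- data.frame(individual = seq_len(nrow(y)), y)
  names(enc) <- c("individual", paste0("occ", seq_len(ncol(y))))
  con <- file(file.path(dir, "encounters.csv"), "w")
  writeLines(paste("# 0 = not detected, 1 = detected,",
                   "-9 = structurally unobservable (zero tracking effort)"),
             con)
  write.csv(enc, con, row.names = FALSE, quote = FALSE)
  close(con)
  ind <- cbind(individual = seq_len(nrow(y)), data$covariates,
               release = data$f)
  write.csv(ind, file.path(dir, "individuals.csv"), row.names = FALSE,
            quote = FALSE)
  write_occasions(data$calendar, file.path(dir, "occasions.csv"))
  invisible(dir)
}

#' @rdname write_encounter_data
#' @export
read_encounter_data <- function(dir) {
  cal <- read_occasions(file.path(dir, "occasions.csv"))
  enc <- read.csv(file.path(dir, "encounters.csv"), comment.char = "#",
                  stringsAsFactors = FALSE)
  ind <- read.csv(file.path(dir, "individuals.csv"),
                  stringsAsFactors = FALSE)
  y <- as.matrix(enc[, -1, drop = FALSE])
  y[y == -9L] <- 0L
  sdays <- cal$snow_days
  z <- if (all(is.na(sdays))) rep(0, nrow(cal)) else {
    sc <- snow_standardization(sdays, cal)
    standardize_snow(sdays, sc$center, sc$scale)
  }
  cjs_data(y, ind$release,
           ind[, c("mass_z", "sex", "fed")], cal, z)
}
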