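## Study designs: areas, wetlands per area, sampled years, visits per area-year.

#' Construct a study design
#'
#' A study design describes the nested sampling layout: the set of protected
#' areas (with latitude and number of monitored wetlands), the global span of
#' calendar years, the subset of years each area actually sampled, and how
#' many visits were made per area-year.
#'
#' @param areas data.frame with columns `area` (identifier), `latitude`
#'   (degrees north), `n_wetlands` (positive count) and a list column
#'   `sampled_years` of integer vectors.
#' @param years global year span (integer vector).  Defaults to the full range
#'   of all sampled years.
#' @param visits visits per area-year: a single integer applied everywhere, or
#'   a named list `area -> named integer vector (year -> count)`.
#'
#' @return an object of class `study_design` with elements `areas`,
#'   `years`, `sampled_years` (named list) and `visits` (named list of named
#'   integer vectors over each area's sampled years).
#' @export
study_design <- function(areas, years = NULL, visits = 3L) {
  stopifnot(is.data.frame(areas),
            all(c("area", "latitude", "n_wetlands", "sampled_years") %in% names(areas)))
  ids <- as.character(areas$area)
  if (anyDuplicated(ids)) stop("duplicate area identifiers")
  if (any(areas$n_wetlands < 1)) stop("n_wetlands must be >= 1 for every area")
  sy <- lapply(areas$sampled_years, function(v) sort(unique(as.integer(v))))
  names(sy) <- ids
  if (any(vapply(sy, length, 0L) == 0L)) stop("every area needs a nonempty sampled_years set")
  if (is.null(years)) years <- seq(min(unlist(sy)), max(unlist(sy)))
  years <- sort(unique(as.integer(years)))
  bad <- !vapply(sy, function(v) all(v %in% years), TRUE)
  if (any(bad)) stop("sampled_years outside the global span for area(s): ",
                     paste(ids[bad], collapse = ", "))
  vis <- vector("list", length(ids)); names(vis) <- ids
  for (id in ids) {
    if (is.list(visits)) {
      v <- visits[[id]]
      if (is.null(v)) stop("visits missing for area ", id)
      if (!setequal(names(v), as.character(sy[[id]])))
        stop("visit counts must be defined exactly for the sampled years of area ", id)
      vis[[id]] <- as.integer(v[as.character(sy[[id]])])
    } else {
      vis[[id]] <- rep(as.integer(visits), length(sy[[id]]))
    }
    names(vis[[id]]) <- as.character(sy[[id]])
    if (any(vis[[id]] < 1L)) stop("visit counts must be >= 1 (area ", id, ")")
  }
  out <- list(
    areas = data.frame(area = ids,
                       latitude = as.numeric(areas$latitude),
                       n_wetlands = as.integer(areas$n_wetlands),
                       stringsAsFactors = FALSE),
    years = years, sampled_years = sy, visits = vis)
  class(out) <- "study_design"
  out
}

#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", nrow(x$areas), "areas,",
      sum(x$areas$n_wetlands), "wetlands, years",
      min(x$years), "-", max(x$years), "\n")
  invisible(x)
}

## "2004-2007;2009-2013" -> c(2004:2007, 2009:2013)
parse_year_ranges <- function(s) {
  parts <- strsplit(as.character(s), ";", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    p <- gsub("–|‐", "-", trimws(p))  # tolerate en-dash/hyphen variants
    r <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
    if (anyNA(r) || length(r) > 2) stop("cannot parse year range: ", p)
    out <- c(out, if (length(r) == 1) r else seq(r[1], r[2]))
  }
  sort(unique(out))
}

format_year_ranges <- function(v) {
  v <- sort(unique(as.integer(v)))
  grp <- cumsum(c(1L, diff(v) != 1L))
  paste(vapply(split(v, grp), function(g) {
    if (length(g) == 1) as.character(g) else paste0(g[1], "-", g[length(g)])
  }, ""), collapse = ";")
}

#' Read / write an area table
#'
#' The area file is comma-delimited with header
#' `area,latitude,n_wetlands,years`, where `years` is a semicolon-separated
#' list of year ranges, e.g. `2004-2007;2009-2013`.
#'
#' @param path file path.
#' @param visits passed on to [study_design()].
#' @return [read_area_table()] returns a `study_design`.
#' @export
read_area_table <- function(path, visits = 3L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("area", "latitude", "n_wetlands", "years")
  if (!all(need %in% names(df)))
    stop("area table must have columns ", paste(need, collapse = ", "))
  df$sampled_years <- lapply(df$years, parse_year_ranges)
  study_design(df, visits = visits)
}

#' @param design a `study_design`.
#' @rdname read_area_table
#' @export
write_area_table <- function(design, path) {
  df <- design$areas
  df$years <- vapply(design$sampled_years[df$area], format_year_ranges, "")
  write.csv(df[, c("area", "latitude", "n_wetlands", "years")], path,
            row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The 14-area monitoring design
#'
#' The design of the motivating regional vernal-pool monitoring program:
#' 14 federally protected areas in the northeastern United States, 11-111
#' monitored wetlands each, sampled in (subsets of) 2004-2013.  Per-area-year
#' visit counts are not part of the published summary ("two to four visits
#' were attempted"); the fixture defaults to 3 visits per area-year, the
#' midpoint of the stated range, and can be overridden.
#'
#' @param visits visits per area-year (default 3); see [study_design()].
#' @return a `study_design` with 14 areas.
#' @export
table1_design <- function(visits = 3L) {
  path <- system.file("extdata", "table1_areas.csv", package = "nestocc",
                      mustWork = TRUE)
  read_area_table(path, visits = visits)
}

#' Build centered year and latitude covariates
#'
#' The year covariate is centered to mean 0 over each area's *sampled* years
#' (so the area intercept is mid-study occupancy); the same centering is
#' reused when predicting into unsampled years.  Latitude is centered to mean
#' 0 across areas.
#'
#' @param design a `study_design`.
#' @return an object of class `covariate_frame`: list with `year`
#'   (data.frame `area`, `year`, `Y` for every area x global year) and
#'   `latitude` (data.frame `area`, `L`).
#' @export
build_covariates <- function(design) {
  stopifnot(inherits(design, "study_design"))
  ids <- design$areas$area
  one <- vapply(design$sampled_years, length, 0L) == 1L
  if (any(one))
    warning("area(s) with a single sampled year have a degenerate (all-zero) ",
            "year covariate: ", paste(ids[one], collapse = ", "))
  yr <- do.call(rbind, lapply(ids, function(id) {
    ctr <- mean(design$sampled_years[[id]])
    data.frame(area = id, year = design$years,
               Y = design$years - ctr, stringsAsFactors = FALSE)
  }))
  lat <- data.frame(area = ids,
                    L = design$areas$latitude - mean(design$areas$latitude),
                    stringsAsFactors = FALSE)
  out <- list(year = yr, latitude = lat)
  class(out) <- "covariate_frame"
  out
}

## sampled (area, year) pairs in a fixed order: area order of the design,
## years ascending.  This ordering defines the indexing of area-year
## detection random effects everywhere in the package.
area_year_table <- function(design) {
  do.call(rbind, lapply(design$areas$area, function(id) {
    data.frame(area = id, year = design$sampled_years[[id]],
               stringsAsFactors = FALSE)
  }))
}
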