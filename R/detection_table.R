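## Visit-level detection histories with per-area centered date covariate.

#' Construct a detection table
#'
#' A detection table holds one row per (area, wetland, year, visit) with a
#' binary detection and the visit date (integer day-of-year).  Dates are
#' centered to mean 0 within each area, so the date effect on detection only
#' absorbs within-area variation in survey timing.
#'
#' @param df data.frame with columns `area`, `wetland`, `year`, `visit`,
#'   `detection` (0/1) and `date` (day-of-year).
#' @return `df` with an added `date_centered` column, classed
#'   `detection_table`.  Zero-row input is allowed (an empty table).
#' @export
detection_table <- function(df) {
  need <- c("area", "wetland", "year", "visit", "detection", "date")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$area <- as.character(df$area)
  df$wetland <- as.character(df$wetland)
  df$year <- as.integer(df$year)
  df$visit <- as.integer(df$visit)
  if (nrow(df)) {
    bad <- !(df$detection %in% c(0, 1))
    if (any(bad)) stop("detection must be 0 or 1 (first bad row: ",
                       which(bad)[1], ")")
    if (anyNA(df$year) || anyNA(df$visit) || anyNA(df$date))
      stop("year, visit and date must be non-missing integers")
    key <- paste(df$area, df$wetland, df$year, df$visit, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop("duplicate (area, wetland, year, visit) key: ",
           gsub("\r", ", ", d, fixed = TRUE))
    }
    df$detection <- as.integer(df$detection)
    df$date <- as.numeric(df$date)
    df$date_centered <- df$date - ave(df$date, df$area)
    df <- df[order(df$area, df$year, df$wetland, df$visit), ]
    rownames(df) <- NULL
  } else {
    df$date_centered <- numeric(0)
  }
  class(df) <- c("detection_table", "data.frame")
  df
}

#' Read a detection-history file
#'
#' Delimited text with header `area,wetland,year,visit,detection,date`.
#' Detections must be 0/1 and keys unique; date centering is applied on read.
#'
#' @param path file path.
#' @return a [detection_table()].
#' @export
read_detection_table <- function(path) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse ", path, ": ",
                                          conditionMessage(e)))
  need <- c("area", "wetland", "year", "visit", "detection", "date")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  suppressWarnings({
    yr <- as.integer(df$year); vs <- as.integer(df$visit); dt <- as.numeric(df$date)
  })
  bad <- which(is.na(yr) | is.na(vs) | is.na(dt))
  if (length(bad)) stop("malformed row at line ", bad[1] + 1L, " of ", path)
  df$year <- yr; df$visit <- vs; df$date <- dt
  detection_table(df)
}

#' Write a detection table
#'
#' Writes the raw columns (without the derived `date_centered`), so a
#' write/read round trip reproduces the table exactly.
#'
#' @param x a `detection_table`.
#' @param path file path.
#' @export
write_detection_table <- function(x, path) {
  stopifnot(inherits(x, "detection_table"))
  write.csv(as.data.frame(x)[, c("area", "wetland", "year", "visit",
                                 "detection", "date")],
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Check a detection table against a study design
#'
#' Verifies that every record belongs to a known area, a year that area
#' sampled, and a visit index within that area-year's planned visit count.
#'
#' @param data a `detection_table`.
#' @param design a `study_design`.
#' @return `data`, invisibly; errors describe the first violation.
#' @export
validate_detections <- function(data, design) {
  stopifnot(inherits(data, "detection_table"), inherits(design, "study_design"))
  if (!nrow(data)) return(invisible(data))
  unk <- setdiff(unique(data$area), design$areas$area)
  if (length(unk)) stop("unknown area(s): ", paste(unk, collapse = ", "))
  for (id in unique(data$area)) {
    yrs <- unique(data$year[data$area == id])
    off <- setdiff(yrs, design$sampled_years[[id]])
    if (length(off)) stop("area ", id, " has records in unsampled year(s): ",
                          paste(off, collapse = ", "))
  }
  invisible(data)
}
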