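## Internal: collapse detection tables into the packed structures the
## compiled samplers consume.  Site-years (static) or whole wetland
## histories (dynamic) that are identical within an area are represented
## once with a multiplicity weight; occupancy and detection probabilities
## depend on (area, year) only, so this leaves the likelihood unchanged.

collapse_static <- function(data, design, covs) {
  ids <- design$areas$area
  ay <- area_year_table(design)
  ay_key <- paste(ay$area, ay$year)
  nAY <- nrow(ay)
  L <- covs$latitude$L[match(ids, covs$latitude$area)]
  ay_Y <- covs$year$Y[match(ay_key, paste(covs$year$area, covs$year$year))]
  ay_area0 <- match(ay$area, ids) - 1L

  if (nrow(data)) {
    aidx <- match(data$area, ids)
    if (anyNA(aidx)) stop("data contains areas not in the design")
    ord <- order(aidx, data$year, data$wetland, data$visit)
    d <- data[ord, ]
    site_id <- paste(d$area, d$year, d$wetland, sep = "\r")
    first <- !duplicated(site_id)
    site_f <- factor(site_id, levels = site_id[first])
    per_rec <- paste(d$visit, d$detection, d$date_centered, sep = ",")
    sig <- vapply(split(per_rec, site_f), paste0, "", collapse = ";")
    sy_ay <- match(paste(d$area, d$year)[first], ay_key)
    if (anyNA(sy_ay)) stop("data contains area-years not sampled in the design")
    prof_key <- paste(sy_ay, sig)
    repi <- which(!duplicated(prof_key))
    w <- tabulate(match(prof_key, prof_key[repi]), nbins = length(repi))
    po <- order(sy_ay[repi])
    repi <- repi[po]; w <- w[po]
    site_start <- c(which(first), nrow(d) + 1L)
    rows <- sequence(site_start[repi + 1L] - site_start[repi],
                     from = site_start[repi])
    len <- site_start[repi + 1L] - site_start[repi]
    prof_start <- c(0L, cumsum(len))
    rec_y <- d$detection[rows]
    rec_date <- d$date_centered[rows]
    prof_ay0 <- sy_ay[repi] - 1L
    gz <- rowsum(rec_y, rep(seq_along(repi), len))
    prof_allzero <- as.integer(as.vector(gz) == 0L)
  } else {
    w <- numeric(0); prof_start <- 0L; rec_y <- integer(0)
    rec_date <- numeric(0); prof_ay0 <- integer(0); prof_allzero <- integer(0)
  }
  ay_counts <- tabulate(prof_ay0 + 1L, nbins = nAY)
  area_counts <- tabulate(ay_area0[prof_ay0 + 1L] + 1L, nbins = length(ids))
  list(ay_area = ay_area0, ay_Y = as.numeric(ay_Y), L = as.numeric(L),
       prof_ay = as.integer(prof_ay0), prof_w = as.numeric(w),
       prof_allzero = prof_allzero,
       prof_start = as.integer(prof_start),
       rec_y = as.integer(rec_y), rec_date = as.numeric(rec_date),
       ay_prof_start = as.integer(c(0L, cumsum(ay_counts))),
       area_prof_start = as.integer(c(0L, cumsum(area_counts))),
       ay = ay, ids = ids)
}

collapse_dynamic <- function(data, design) {
  ids <- design$areas$area
  years <- design$years
  Tn <- length(years)
  ay <- area_year_table(design)
  ay_key <- paste(ay$area, ay$year)
  nAY <- nrow(ay)

  if (nrow(data)) {
    aidx <- match(data$area, ids)
    if (anyNA(aidx)) stop("data contains areas not in the design")
    ord <- order(aidx, data$wetland, data$year, data$visit)
    d <- data[ord, ]
    site_id <- paste(d$area, d$wetland, sep = "\r")
    first <- !duplicated(site_id)
    site_f <- factor(site_id, levels = site_id[first])
    per_rec <- paste(d$year, d$visit, d$detection, d$date_centered, sep = ",")
    sig <- vapply(split(per_rec, site_f), paste0, "", collapse = ";")
    s_area <- match(d$area[first], ids)
    prof_key <- paste(s_area, sig)
    repi <- which(!duplicated(prof_key))
    w <- tabulate(match(prof_key, prof_key[repi]), nbins = length(repi))
    po <- order(s_area[repi])
    repi <- repi[po]; w <- w[po]
    nS <- length(repi)
    site_start <- c(which(first), nrow(d) + 1L)
    len <- site_start[repi + 1L] - site_start[repi]
    rows <- sequence(len, from = site_start[repi])
    rec_y <- d$detection[rows]
    rec_date <- d$date_centered[rows]
    rec_t <- match(d$year[rows], years)
    if (anyNA(rec_t)) stop("observation in a year outside the global span")
    site_pos <- rep(seq_len(nS), len)
    m <- table(factor(site_pos, levels = seq_len(nS)),
               factor(rec_t, levels = seq_len(Tn)))
    sy_len <- as.integer(t(m))                 # site-major, then year
    sy_off <- c(0L, cumsum(sy_len))[seq_len(nS * Tn)]
    site_area0 <- s_area[repi] - 1L
    sy_area <- ids[rep(site_area0, each = Tn) + 1L]
    sy_year <- rep(years, times = nS)
    sy_ay0 <- match(paste(sy_area, sy_year), ay_key) - 1L
    sy_ay0[is.na(sy_ay0)] <- -1L
    if (any(sy_ay0 < 0 & sy_len > 0))
      stop("data contains area-years not sampled in the design")
    area_counts <- tabulate(site_area0 + 1L, nbins = length(ids))
  } else {
    nS <- 0L; w <- numeric(0); rec_y <- integer(0); rec_date <- numeric(0)
    sy_len <- integer(0); sy_off <- integer(0); sy_ay0 <- integer(0)
    site_area0 <- integer(0)
    area_counts <- integer(length(ids))
  }
  list(T = Tn, site_area = as.integer(site_area0), site_w = as.numeric(w),
       sy_off = as.integer(sy_off), sy_len = as.integer(sy_len),
       sy_ay = as.integer(sy_ay0),
       rec_y = as.integer(rec_y), rec_date = as.numeric(rec_date),
       area_site_start = as.integer(c(0L, cumsum(area_counts))),
       ay_area = as.integer(match(ay$area, ids) - 1L),
       ay_t = as.integer(match(ay$year, years) - 1L),
       ay = ay, ids = ids, years = years)
}

## restrict a design to one area (used by the per-area fixed-effects fits;
## the global year span is retained so the Markov chain still runs over it)
subset_design <- function(design, id) {
  i <- match(id, design$areas$area)
  if (is.na(i)) stop("unknown area: ", id)
  out <- list(areas = design$areas[i, , drop = FALSE],
              years = design$years,
              sampled_years = design$sampled_years[id],
              visits = design$visits[id])
  rownames(out$areas) <- NULL
  class(out) <- "study_design"
  out
}
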