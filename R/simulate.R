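## Synthetic detection-history generator with the exact generative structure
## the two models assume, plus a truth record for recovery tests.
##
## RNG layout: one master stream keyed by `seed` draws the global (year)
## effects; each area then gets its own sub-stream with a seed derived
## deterministically from the master seed and the area's position, so edits
## to one area's design leave every other area's draws unchanged.

area_seed <- function(seed, i) as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)

## visit dates for one area: one date per (sampled year, visit), shared by
## all wetlands surveyed in that visit (surveys of an area's pools happen in
## the same short window).  Uniform in a seasonal day-of-year window.
draw_visit_dates <- function(design, id, window) {
  yrs <- design$sampled_years[[id]]
  v <- design$visits[[id]]
  lapply(setNames(as.list(yrs), as.character(yrs)), function(y) {
    k <- v[as.character(y)]
    sort(round(runif(k, window[1], window[2])))
  })
}

assemble_records <- function(id, design, dates, z, p_fun) {
  yrs <- design$sampled_years[[id]]
  nw <- design$areas$n_wetlands[design$areas$area == id]
  wet <- sprintf("w%03d", seq_len(nw))
  rows <- list()
  ## center dates over all of this area's records: dates are shared across
  ## wetlands so the record mean equals the mean over (year, visit) values
  dmean <- mean(unlist(dates))
  for (y in yrs) {
    dts <- dates[[as.character(y)]]
    t_idx <- match(y, design$years)
    for (k in seq_along(dts)) {
      dc <- dts[k] - dmean
      p <- p_fun(y, dc)
      yv <- rbinom(nw, 1, z[, t_idx] * p)
      rows[[length(rows) + 1L]] <- data.frame(
        area = id, wetland = wet, year = y, visit = k,
        detection = yv, date = dts[k], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate from the static trend model
#'
#' For each area, a trend effect delta_i ~ Normal(mu, sigma) is drawn;
#' occupancy is psi_ij = plogis(alpha_i + (beta * L_i + delta_i) * Y_j) with
#' centered year and latitude covariates; latent states z are independent
#' Bernoulli(psi_ij) per wetland-year (drawn for every year of the global
#' span; observations are emitted only for sampled area-years); detections
#' are Bernoulli(z * p) with logit(p) = det_alpha + det_beta_date *
#' date_centered + delta_ij, delta_ij ~ Normal(0, sigma_p).
#'
#' @param design a [study_design()].
#' @param params a [static_gen_params()].
#' @param seed integer seed; the same seed reproduces the simulation exactly.
#' @param date_window day-of-year window from which shared visit dates are
#'   drawn uniformly (the published protocol does not specify within-season
#'   visit timing).
#' @return list with `detections` (a [detection_table()]) and `truth` (class
#'   `occ_truth`: latent states for all global years, realized random
#'   effects, and the true occupancy probabilities).
#' @export
simulate_static <- function(design, params = static_gen_params(), seed,
                            date_window = c(75, 135)) {
  stopifnot(inherits(design, "study_design"), inherits(params, "static_gen_params"))
  covs <- suppressWarnings(build_covariates(design))
  ids <- design$areas$area
  alpha <- expand_by(params$alpha_area, ids, "alpha_area")
  Tn <- length(design$years)
  det_list <- list(); z_list <- list(); psi_list <- list(); dd_list <- list()
  delta_trend <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    id <- ids[i]
    set.seed(area_seed(seed, i))
    nw <- design$areas$n_wetlands[i]
    L <- covs$latitude$L[covs$latitude$area == id]
    Y <- covs$year$Y[covs$year$area == id]
    di <- rnorm(1, params$mu_trend, params$sigma_trend)
    delta_trend[id] <- di
    psi <- plogis(alpha[id] + (params$beta_latitude * L + di) * Y)
    z <- matrix(rbinom(nw * Tn, 1, rep(psi, each = nw)), nrow = nw)
    dates <- draw_visit_dates(design, id, date_window)
    yrs <- design$sampled_years[[id]]
    dd <- setNames(rnorm(length(yrs), 0, params$sigma_p), as.character(yrs))
    det_list[[id]] <- assemble_records(id, design, dates, z, function(y, dc)
      plogis(params$det_alpha + params$det_beta_date * dc + dd[as.character(y)]))
    z_list[[id]] <- data.frame(area = id,
                               wetland = rep(sprintf("w%03d", seq_len(nw)), Tn),
                               year = rep(design$years, each = nw),
                               z = as.vector(z), stringsAsFactors = FALSE)
    psi_list[[id]] <- data.frame(area = id, year = design$years, psi = psi,
                                 stringsAsFactors = FALSE)
    dd_list[[id]] <- data.frame(area = id, year = yrs, value = unname(dd),
                                stringsAsFactors = FALSE)
  }
  truth <- structure(list(model = "static",
                          z = do.call(rbind, z_list),
                          psi = do.call(rbind, psi_list),
                          delta_trend = delta_trend,
                          delta_det = do.call(rbind, dd_list),
                          params = params, seed = seed),
                     class = "occ_truth")
  list(detections = detection_table(do.call(rbind, det_list)), truth = truth)
}

#' Simulate from the dynamic colonization/persistence model
#'
#' Year effects theta_j (one per transition interval, shared across areas)
#' are drawn from the master stream; each area then draws its colonization
#' and persistence effects delta_i, initial states z_1 ~ Bernoulli(psi_i1),
#' and propagates the two-state Markov chain over the *entire* global span
#' (occupancy keeps evolving while an area skips sampling; only the
#' observations are suppressed).  Detection is as in [simulate_static()].
#'
#' @inheritParams simulate_static
#' @param params a [dynamic_gen_params()].
#' @return list with `detections` and `truth` (which additionally records the
#'   realized transition probabilities `phi` and `gamma` per area and origin
#'   year).
#' @export
simulate_dynamic <- function(design, params = dynamic_gen_params(), seed,
                             date_window = c(75, 135)) {
  stopifnot(inherits(design, "study_design"), inherits(params, "dynamic_gen_params"))
  ids <- design$areas$area
  Tn <- length(design$years)
  psi1 <- expand_by(params$psi_init, ids, "psi_init")
  set.seed(as.integer(seed %% 2147483647))
  col_theta <- rnorm(Tn - 1, 0, params$col_sigma_year)
  per_theta <- rnorm(Tn - 1, 0, params$per_sigma_year)
  det_list <- list(); z_list <- list(); trans_list <- list(); dd_list <- list()
  col_delta <- setNames(numeric(length(ids)), ids)
  per_delta <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    id <- ids[i]
    set.seed(area_seed(seed, i))
    nw <- design$areas$n_wetlands[i]
    col_delta[id] <- rnorm(1, 0, params$col_sigma_area)
    per_delta[id] <- rnorm(1, 0, params$per_sigma_area)
    gam <- plogis(params$col_alpha + col_delta[id] + col_theta)
    phi <- plogis(params$per_alpha + per_delta[id] + per_theta)
    z <- matrix(0L, nrow = nw, ncol = Tn)
    z[, 1] <- rbinom(nw, 1, psi1[id])
    for (t in 2:Tn)
      z[, t] <- rbinom(nw, 1, ifelse(z[, t - 1] == 1, phi[t - 1], gam[t - 1]))
    dates <- draw_visit_dates(design, id, date_window)
    yrs <- design$sampled_years[[id]]
    dd <- setNames(rnorm(length(yrs), 0, params$sigma_p), as.character(yrs))
    det_list[[id]] <- assemble_records(id, design, dates, z, function(y, dc)
      plogis(params$det_alpha + params$det_beta_date * dc + dd[as.character(y)]))
    z_list[[id]] <- data.frame(area = id,
                               wetland = rep(sprintf("w%03d", seq_len(nw)), Tn),
                               year = rep(design$years, each = nw),
                               z = as.vector(z), stringsAsFactors = FALSE)
    trans_list[[id]] <- data.frame(area = id, year = design$years[-Tn],
                                   phi = phi, gamma = gam,
                                   stringsAsFactors = FALSE)
    dd_list[[id]] <- data.frame(area = id, year = yrs, value = unname(dd),
                                stringsAsFactors = FALSE)
  }
  truth <- structure(list(model = "dynamic",
                          z = do.call(rbind, z_list),
                          transitions = do.call(rbind, trans_list),
                          col_delta = col_delta, per_delta = per_delta,
                          col_theta = col_theta, per_theta = per_theta,
                          delta_det = do.call(rbind, dd_list),
                          params = params, seed = seed),
                     class = "occ_truth")
  list(detections = detection_table(do.call(rbind, det_list)), truth = truth)
}

#' Realized occupancy proportions per area-year
#'
#' Exact proportions of occupied wetlands (latent z = 1) per area and year,
#' including years an area did not sample (the latent states exist for the
#' whole global span).
#'
#' @param truth an `occ_truth` from [simulate_static()] or
#'   [simulate_dynamic()].
#' @return data.frame `area`, `year`, `occupancy`.
#' @export
truth_summary <- function(truth) {
  stopifnot(inherits(truth, "occ_truth"))
  out <- aggregate(z ~ area + year, data = truth$z, FUN = mean)
  names(out)[names(out) == "z"] <- "occupancy"
  out[order(out$area, out$year), c("area", "year", "occupancy")]
}
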