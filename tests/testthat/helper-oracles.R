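## Independent oracles and small fixtures used across the test files.

## Exhaustive latent-state oracle for the static model: enumerates every
## 0/1 configuration of the site-year occupancy states and sums the joint
## probability directly.  Never uses the package's marginalized likelihood.
oracle_static_loglik <- function(psis, hist_list, p_list) {
  n <- length(psis)
  stopifnot(length(hist_list) == n, length(p_list) == n)
  configs <- as.matrix(expand.grid(rep(list(0:1), n)))
  total <- 0
  for (r in seq_len(nrow(configs))) {
    pr <- 1
    for (s in seq_len(n)) {
      y <- hist_list[[s]]; p <- p_list[[s]]
      if (configs[r, s] == 1) {
        pr <- pr * psis[s] * prod(ifelse(y == 1, p, 1 - p))
      } else {
        pr <- pr * (1 - psis[s]) * as.numeric(all(y == 0))
      }
    }
    total <- total + pr
  }
  unname(log(total))
}

## Exhaustive path oracle for the dynamic model: sums over all 2^T latent
## occupancy paths of one site.
oracle_dynamic_loglik <- function(psi1, phi, gamma, hist_list, p_list) {
  Tn <- length(hist_list)
  paths <- as.matrix(expand.grid(rep(list(0:1), Tn)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    z <- paths[r, ]
    pr <- if (z[1] == 1) psi1 else 1 - psi1
    for (t in seq_len(Tn - 1)) {
      pr <- pr * if (z[t] == 1) {
        if (z[t + 1] == 1) phi[t] else 1 - phi[t]
      } else {
        if (z[t + 1] == 1) gamma[t] else 1 - gamma[t]
      }
    }
    for (t in seq_len(Tn)) {
      y <- hist_list[[t]]
      if (is.null(y)) next
      p <- p_list[[t]]
      pr <- pr * if (z[t] == 1) prod(ifelse(y == 1, p, 1 - p)) else
        as.numeric(all(y == 0))
    }
    total <- total + pr
  }
  unname(log(total))
}

## compact design builder: equal wetland counts and a shared year span
make_design <- function(n_areas = 2, n_wetlands = 2, years = 2004:2005,
                        visits = 2, latitudes = NULL,
                        sampled = NULL) {
  ar <- data.frame(area = paste0("A", seq_len(n_areas)),
                   latitude = if (is.null(latitudes))
                     seq(39, 45, length.out = n_areas) else latitudes,
                   n_wetlands = n_wetlands)
  ar$sampled_years <- if (is.null(sampled)) rep(list(years), n_areas) else sampled
  study_design(ar, years = years, visits = visits)
}

## assemble the packed parameter vector the compiled static likelihood uses
theta_static <- function(design, params) {
  ids <- design$areas$area
  ay <- nestocc:::area_year_table(design)
  dt <- if (params$nested)
    nestocc:::expand_by(params$delta_trend, ids, "delta_trend") else
    rep(0, length(ids))
  dd <- rep(0, nrow(ay))
  if (!is.null(params$delta_det)) {
    m <- match(paste(ay$area, ay$year),
               paste(params$delta_det$area, params$delta_det$year))
    dd <- ifelse(is.na(m), 0, params$delta_det$value[m])
  }
  unname(c(nestocc:::expand_by(params$alpha_area, ids, "alpha"), dt,
           params$beta_latitude, params$mu_trend,
           log(if (is.null(params$sigma_trend)) 1 else params$sigma_trend),
           params$det_alpha, params$det_beta_date,
           log(if (is.null(params$sigma_p)) 1 else params$sigma_p), dd))
}

## likewise for the compiled dynamic likelihood
theta_dynamic <- function(design, params) {
  ids <- design$areas$area
  years <- design$years
  Tn <- length(years)
  ay <- nestocc:::area_year_table(design)
  pick_vec <- function(x, nm) {
    if (is.null(x)) return(rep(0, length(nm)))
    out <- x[as.character(nm)]
    ifelse(is.na(out), 0, out)
  }
  dd <- rep(0, nrow(ay))
  if (!is.null(params$delta_det)) {
    m <- match(paste(ay$area, ay$year),
               paste(params$delta_det$area, params$delta_det$year))
    dd <- ifelse(is.na(m), 0, params$delta_det$value[m])
  }
  lg <- function(s) log(if (is.null(s)) 1 else s)
  unname(c(qlogis(nestocc:::expand_by(params$psi_init, ids, "psi_init")),
           params$col_alpha, pick_vec(params$col_delta, ids),
           pick_vec(params$col_theta, years[-Tn]),
           lg(params$col_sigma_area), lg(params$col_sigma_year),
           params$per_alpha, pick_vec(params$per_delta, ids),
           pick_vec(params$per_theta, years[-Tn]),
           lg(params$per_sigma_area), lg(params$per_sigma_year),
           params$det_alpha, params$det_beta_date, lg(params$sigma_p), dd))
}

## hand-built occ_fit with known draws, for testing derived quantities and
## predictive deviance against closed forms
manual_dyn_fit <- function(design, draw_mat, variant = "random",
                           use_det_re = FALSE, chains = 2) {
  structure(list(draws = rep(list(draw_mat), chains), model = "dynamic",
                 meta = list(variant = variant, design = design,
                             covs = suppressWarnings(build_covariates(design)),
                             use_det_re = use_det_re, chains = chains)),
            class = "occ_fit")
}

empty_detections <- function() {
  detection_table(data.frame(area = character(0), wetland = character(0),
                             year = integer(0), visit = integer(0),
                             detection = integer(0), date = numeric(0)))
}
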