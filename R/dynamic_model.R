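## Dynamic (first-order Markov) occupancy model: transition probabilities,
## two-state forward-algorithm likelihood, and derived annual occupancy.

#' Colonization and persistence probabilities for an area-year
#'
#' `phi_ij = plogis(per_alpha + delta_i + theta_j)` and likewise for
#' colonization from its own effect set.  `year` is the origin year of the
#' transition (occupancy in `year` determines the state in `year + 1`).
#'
#' @param params a [dynamic_params()].
#' @param area area identifier.
#' @param year origin calendar year of the transition.
#' @return named vector `c(phi = , gamma = )`.
#' @export
transition_probs <- function(params, area, year) {
  stopifnot(inherits(params, "dynamic_params"))
  y <- as.character(year)
  pick <- function(x, nm) if (is.null(x)) 0 else {
    if (!nm %in% names(x)) stop("no effect entry for ", nm)
    unname(x[nm])
  }
  phi <- plogis(params$per_alpha + pick(params$per_delta, area) +
                  pick(params$per_theta, y))
  gam <- plogis(params$col_alpha + pick(params$col_delta, area) +
                  pick(params$col_theta, y))
  c(phi = phi, gamma = gam)
}

## Forward recursion over the two-state chain.  e0/e1 are per-year emission
## probabilities of the observed history given z = 0 / z = 1 (1 for years
## without observations).  Returns the log marginal probability.
forward_loglik <- function(psi1, phi, gamma, e0, e1) {
  Tn <- length(e0)
  stopifnot(length(e1) == Tn, length(phi) == Tn - 1 || Tn == 1,
            length(gamma) == length(phi))
  f0 <- 1 - psi1; f1 <- psi1; ll <- 0
  for (t in seq_len(Tn)) {
    if (t > 1) {
      g1 <- f0 * gamma[t - 1] + f1 * phi[t - 1]
      f0 <- f0 + f1 - g1
      f1 <- g1
    }
    f0 <- f0 * e0[t]; f1 <- f1 * e1[t]
    s <- f0 + f1
    if (s <= 0) return(-Inf)
    if (s < 1e-12) { ll <- ll + log(s); f0 <- f0 / s; f1 <- f1 / s }
  }
  ll + log(f0 + f1)
}

#' Forward-algorithm log-likelihood of one wetland's multi-year history
#'
#' Initializes the occupancy distribution at (1 - psi1, psi1), and for each
#' year of the global span multiplies in the emission probability of that
#' year's detection history (an all-ones emission for years without
#' observations, which still advance the Markov chain) before propagating
#' through the transition matrix \[\[1-gamma, gamma\], \[1-phi, phi\]\].
#'
#' @param histories list over the global years (in order): each element a 0/1
#'   visit vector, or NULL for a year with no observations.
#' @param p list parallel to `histories` with per-visit detection
#'   probabilities.
#' @param psi1 initial occupancy probability.
#' @param phi,gamma persistence / colonization probabilities per transition
#'   interval (length `length(histories) - 1`).
#' @return log-probability of the full history.
#' @export
site_loglik_forward <- function(histories, p, psi1, phi, gamma) {
  Tn <- length(histories)
  e0 <- rep(1, Tn); e1 <- rep(1, Tn)
  for (t in seq_len(Tn)) {
    h <- histories[[t]]
    if (is.null(h) || length(h) == 0) next
    if (!all(h %in% c(0, 1))) stop("history values must be 0 or 1")
    pv <- p[[t]]
    if (length(pv) != length(h)) stop("p and history lengths differ in year ", t)
    e1[t] <- exp(sum(ifelse(h == 1, log(pv), log1p(-pv))))
    e0[t] <- as.numeric(all(h == 0))
  }
  forward_loglik(psi1, phi, gamma, e0, e1)
}

#' Log-likelihood of the dynamic model on a full detection table
#'
#' Sum of [site_loglik_forward()] over wetlands, with transition and
#' detection probabilities assembled from a complete [dynamic_params()].
#' Years are the global span of `design`; observations outside it are an
#' error.
#'
#' @param data a [detection_table()].
#' @param params a [dynamic_params()].
#' @param design a [study_design()].
#' @return scalar log-likelihood.
#' @export
dynamic_loglik <- function(data, params, design) {
  stopifnot(inherits(design, "study_design"))
  if (!nrow(data)) return(0)
  if (!all(data$year %in% design$years))
    stop("observation in a year outside the global span")
  years <- design$years
  Tn <- length(years)
  ids <- unique(data$area)
  psi1 <- expand_by(params$psi_init, ids, "psi_init")
  dd_at <- function(a, y) {
    if (is.null(params$delta_det)) return(0)
    m <- match(paste(a, y), paste(params$delta_det$area, params$delta_det$year))
    if (is.na(m)) stop("delta_det entry missing for ", a, " ", y)
    params$delta_det$value[m]
  }
  total <- 0
  for (a in ids) {
    tp <- vapply(years[-Tn], function(y) transition_probs(params, a, y),
                 c(phi = 0, gamma = 0))
    da <- data[data$area == a, ]
    for (w in unique(da$wetland)) {
      dw <- da[da$wetland == w, ]
      hist_l <- vector("list", Tn); p_l <- vector("list", Tn)
      for (t in seq_len(Tn)) {
        dv <- dw[dw$year == years[t], ]
        if (nrow(dv)) {
          dv <- dv[order(dv$visit), ]
          hist_l[[t]] <- dv$detection
          p_l[[t]] <- detection_prob(params$det_alpha, params$det_beta_date,
                                     dv$date_centered, dd_at(a, years[t]))
        }
      }
      total <- total + site_loglik_forward(hist_l, p_l, psi1[[a]],
                                           tp["phi", ], tp["gamma", ])
    }
  }
  unname(total)
}

#' Derived annual occupancy for one area
#'
#' psi_i1 is given; thereafter psi_(j+1) = psi_j * phi_ij + (1 - psi_j) *
#' gamma_ij, defined for sampled and unsampled years alike.
#'
#' @param params a [dynamic_params()].
#' @param area area identifier.
#' @param years global year span (ascending integer vector).
#' @return named numeric vector of occupancy probabilities, one per year.
#' @export
derived_occupancy <- function(params, area, years) {
  stopifnot(inherits(params, "dynamic_params"))
  Tn <- length(years)
  psi <- numeric(Tn)
  psi[1] <- expand_by(params$psi_init, area, "psi_init")[[1]]
  for (t in seq_len(Tn - 1)) {
    tp <- transition_probs(params, area, years[t])
    psi[t + 1] <- psi[t] * tp["phi"] + (1 - psi[t]) * tp["gamma"]
  }
  setNames(psi, years)
}
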