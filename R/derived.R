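## Derived quantities from a fitted dynamic model: annual occupancy per
## area (sampled and unsampled years alike), regional means, and average
## transition probabilities.

## per-draw transition probabilities: list of phi, gamma arrays with
## dimension (draws, area, interval); handles both variants
transition_draws <- function(fit, n = NULL, m = NULL) {
  stopifnot(inherits(fit, "occ_fit"), fit$model == "dynamic")
  design <- fit$meta$design
  ids <- design$areas$area
  years <- design$years
  Tn <- length(years)
  if (is.null(m)) m <- pool_draws(fit, n)
  nd <- nrow(m)
  phi <- array(0, c(nd, length(ids), Tn - 1))
  gam <- array(0, c(nd, length(ids), Tn - 1))
  fixed <- fit$meta$variant == "fixed"
  for (a in seq_along(ids)) {
    if (fixed) {
      pl <- m[, paste0("per_alpha[", ids[a], "]")]
      gl <- m[, paste0("col_alpha[", ids[a], "]")]
      for (t in seq_len(Tn - 1)) {
        phi[, a, t] <- plogis(pl)
        gam[, a, t] <- plogis(gl)
      }
    } else {
      pd <- m[, paste0("per_delta[", ids[a], "]")]
      gd <- m[, paste0("col_delta[", ids[a], "]")]
      for (t in seq_len(Tn - 1)) {
        phi[, a, t] <- plogis(m[, "per_alpha"] + pd +
                                m[, paste0("per_theta[", years[t], "]")])
        gam[, a, t] <- plogis(m[, "col_alpha"] + gd +
                                m[, paste0("col_theta[", years[t], "]")])
      }
    }
  }
  list(phi = phi, gamma = gam, ids = ids, years = years, draws = m)
}

## per-draw derived occupancy: array (draws, area, year)
psi_draws <- function(fit, n = NULL) {
  td <- transition_draws(fit, n)
  ids <- td$ids; years <- td$years; Tn <- length(years)
  nd <- nrow(td$draws)
  psi <- array(0, c(nd, length(ids), Tn),
               dimnames = list(NULL, ids, years))
  for (a in seq_along(ids)) {
    psi[, a, 1] <- plogis(td$draws[, paste0("psi1[", ids[a], "]")])
    for (t in seq_len(Tn - 1))
      psi[, a, t + 1] <- psi[, a, t] * td$phi[, a, t] +
        (1 - psi[, a, t]) * td$gamma[, a, t]
  }
  psi
}

#' Annual occupancy estimates per area
#'
#' Posterior summaries of the derived occupancy probability psi for every
#' area and every year of the global span, including years the area did not
#' sample (flagged in the `sampled` column); the Markov structure and the
#' cross-area random effects let the model interpolate and extrapolate into
#' those years, with credible intervals widening as the gap grows.
#'
#' @param fit a dynamic `occ_fit`.
#' @param n optional number of pooled posterior draws to use.
#' @return data.frame `area`, `year`, `mean`, `q2.5`, `q50`, `q97.5`,
#'   `sampled`.
#' @export
occupancy_by_area_year <- function(fit, n = NULL) {
  psi <- psi_draws(fit, n)
  design <- fit$meta$design
  ids <- design$areas$area
  years <- design$years
  out <- do.call(rbind, lapply(seq_along(ids), function(a) {
    qs <- apply(psi[, a, , drop = FALSE], 3, quantile,
                probs = c(0.025, 0.5, 0.975))
    data.frame(area = ids[a], year = years,
               mean = apply(psi[, a, , drop = FALSE], 3, mean),
               q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
               sampled = years %in% design$sampled_years[[ids[a]]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Regional mean occupancy per year
#'
#' For each posterior draw, the mean of the derived area-level occupancy
#' probabilities across areas (unweighted by default, treating the sampled
#' areas as representative of the region's public lands; `weights =
#' "wetlands"` weights areas by their wetland counts instead).
#'
#' @param fit a dynamic `occ_fit`.
#' @param weights `"equal"` or `"wetlands"`.
#' @param n optional number of pooled posterior draws to use.
#' @return data.frame `year`, `mean`, `q2.5`, `q50`, `q97.5`.
#' @export
regional_occupancy <- function(fit, weights = c("equal", "wetlands"),
                               n = NULL) {
  weights <- match.arg(weights)
  psi <- psi_draws(fit, n)
  design <- fit$meta$design
  w <- if (weights == "equal") rep(1, nrow(design$areas)) else
    design$areas$n_wetlands
  w <- w / sum(w)
  reg <- apply(psi, c(1, 3), function(v) sum(v * w))
  qs <- apply(reg, 2, quantile, probs = c(0.025, 0.5, 0.975))
  data.frame(year = design$years, mean = colMeans(reg),
             q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
             row.names = NULL)
}

#' Mean colonization and persistence probabilities
#'
#' Posterior summary of the probability-scale transition parameters averaged
#' over areas and years (the model's "typical" colonization and persistence
#' for the region).
#'
#' @param fit a dynamic `occ_fit`.
#' @param n optional number of pooled posterior draws to use.
#' @return data.frame with rows `colonization` and `persistence`: posterior
#'   mean, SD and 95% interval of the across-area-and-year average.
#' @export
mean_transition_summary <- function(fit, n = NULL) {
  td <- transition_draws(fit, n)
  mg <- apply(td$gamma, 1, mean)
  mp <- apply(td$phi, 1, mean)
  summ <- function(v) c(mean = mean(v), sd = sd(v),
                        q2.5 = unname(quantile(v, 0.025)),
                        q97.5 = unname(quantile(v, 0.975)))
  out <- as.data.frame(rbind(colonization = summ(mg), persistence = summ(mp)))
  out$parameter <- rownames(out)
  rownames(out) <- NULL
  out[, c("parameter", "mean", "sd", "q2.5", "q97.5")]
}
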