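## Parameter containers for the two models.
##
## *_gen_params hold the hyper-level quantities a simulation draws from;
## static_params / dynamic_params hold a *complete* parameter vector
## (including realized random effects) at which the likelihood can be
## evaluated.

#' Generator parameters for the static trend model
#'
#' Defaults are the package's reference simulation conditions: flat mean
#' trend, modest among-area trend spread, a small positive latitude-on-trend
#' effect, mid-study occupancy 0.5, per-visit detection near 0.7 with a weak
#' negative date effect and area-year detection noise.
#'
#' @param alpha_area logit-scale occupancy intercept(s); scalar recycled over
#'   areas or a named vector.
#' @param mu_trend mean trend mu (logit units / year).
#' @param sigma_trend among-area trend SD sigma (>= 0).
#' @param beta_latitude effect of centered latitude on trend.
#' @param det_alpha detection intercept (logit).
#' @param det_beta_date effect of centered date (logit units / day).
#' @param sigma_p SD of the area-year detection random effect (>= 0).
#' @return list of class `static_gen_params`.
#' @export
static_gen_params <- function(alpha_area = 0, mu_trend = 0, sigma_trend = 0.15,
                              beta_latitude = 0.05, det_alpha = qlogis(0.7),
                              det_beta_date = -0.02, sigma_p = 0.5) {
  stopifnot(sigma_trend >= 0, sigma_p >= 0)
  structure(list(alpha_area = alpha_area, mu_trend = mu_trend,
                 sigma_trend = sigma_trend, beta_latitude = beta_latitude,
                 det_alpha = det_alpha, det_beta_date = det_beta_date,
                 sigma_p = sigma_p),
            class = "static_gen_params")
}

#' Generator parameters for the dynamic model
#'
#' Default colonization and persistence means (0.119 and 0.896 on the
#' probability scale) are wood-frog-like values for vernal-pool systems:
#' occupied pools usually stay occupied, empty pools are colonized rarely,
#' giving a long-run occupancy near 0.53.
#'
#' @param psi_init initial occupancy probability; scalar or named per-area
#'   vector, in (0,1).
#' @param col_alpha,per_alpha mean colonization / persistence (logit scale).
#' @param col_sigma_area,per_sigma_area among-area SDs (sigma_delta).
#' @param col_sigma_year,per_sigma_year among-year SDs (sigma_theta).
#' @inheritParams static_gen_params
#' @return list of class `dynamic_gen_params`.
#' @export
dynamic_gen_params <- function(psi_init = 0.5,
                               col_alpha = qlogis(0.119),
                               col_sigma_area = 0.3, col_sigma_year = 0.3,
                               per_alpha = qlogis(0.896),
                               per_sigma_area = 0.3, per_sigma_year = 0.3,
                               det_alpha = qlogis(0.7), det_beta_date = -0.02,
                               sigma_p = 0.5) {
  stopifnot(all(psi_init > 0), all(psi_init < 1),
            col_sigma_area >= 0, col_sigma_year >= 0,
            per_sigma_area >= 0, per_sigma_year >= 0, sigma_p >= 0)
  structure(list(psi_init = psi_init, col_alpha = col_alpha,
                 col_sigma_area = col_sigma_area, col_sigma_year = col_sigma_year,
                 per_alpha = per_alpha, per_sigma_area = per_sigma_area,
                 per_sigma_year = per_sigma_year, det_alpha = det_alpha,
                 det_beta_date = det_beta_date, sigma_p = sigma_p),
            class = "dynamic_gen_params")
}

#' Full parameter vector of the static trend model
#'
#' Houses every quantity the static likelihood and prior need, including
#' realized random effects.  `delta_det` is defined only for sampled
#' area-years (it has no likelihood contribution elsewhere).
#'
#' @param alpha_area named logit-scale intercepts, one per area.
#' @param beta_latitude latitude-on-trend effect.
#' @param mu_trend hyper-mean of the area trends (in the non-nested variant,
#'   the single shared trend slope).
#' @param sigma_trend among-area trend SD (nested variant only).
#' @param delta_trend named area trend effects delta_i (nested variant only).
#' @param det_alpha,det_beta_date detection intercept and date slope.
#' @param sigma_p SD of the area-year detection effect.
#' @param delta_det data.frame `area`, `year`, `value` of area-year detection
#'   effects, or NULL for all-zero.
#' @param nested logical: is the among-area random trend present?
#' @return list of class `static_params`.
#' @export
static_params <- function(alpha_area, beta_latitude = 0, mu_trend = 0,
                          sigma_trend = NULL, delta_trend = NULL,
                          det_alpha = 0, det_beta_date = 0,
                          sigma_p = NULL, delta_det = NULL, nested = TRUE) {
  if (nested && is.null(delta_trend)) stop("nested model needs delta_trend")
  ## non-positive SDs are representable (the prior assigns them -Inf) so that
  ## support violations surface as density zero, not construction errors
  structure(list(alpha_area = alpha_area, beta_latitude = beta_latitude,
                 mu_trend = mu_trend, sigma_trend = sigma_trend,
                 delta_trend = delta_trend, det_alpha = det_alpha,
                 det_beta_date = det_beta_date, sigma_p = sigma_p,
                 delta_det = delta_det, nested = nested),
            class = "static_params")
}

#' Drop the among-area random trend from a static parameter set
#'
#' Returns the non-nested variant: the area trend effects and their
#' hyperparameters are removed, leaving `mu_trend` as a single shared slope
#' plus the latitude regression as the only trend structure.  The detection
#' random effect is retained; only the trend nesting is dropped.
#'
#' @param params a `static_params`.
#' @return a `static_params` with `nested = FALSE`.
#' @export
nonnested_variant <- function(params) {
  stopifnot(inherits(params, "static_params"))
  params$delta_trend <- NULL
  params$sigma_trend <- NULL
  params$nested <- FALSE
  params
}

#' Full parameter vector of the dynamic model
#'
#' @param psi_init named per-area initial occupancy probabilities, in (0,1).
#' @param col_alpha,per_alpha colonization / persistence mean logits.
#' @param col_delta,per_delta named area effects delta_i (or NULL for zero).
#' @param col_theta,per_theta named year effects theta_j indexed by the
#'   *origin* year of each transition (global years except the last), or NULL.
#' @param col_sigma_area,col_sigma_year,per_sigma_area,per_sigma_year
#'   random-effect SDs (may be NULL when effects are absent).
#' @inheritParams static_params
#' @return list of class `dynamic_params`.
#' @export
dynamic_params <- function(psi_init, col_alpha, per_alpha,
                           col_delta = NULL, col_theta = NULL,
                           per_delta = NULL, per_theta = NULL,
                           col_sigma_area = NULL, col_sigma_year = NULL,
                           per_sigma_area = NULL, per_sigma_year = NULL,
                           det_alpha = 0, det_beta_date = 0,
                           sigma_p = NULL, delta_det = NULL) {
  stopifnot(all(psi_init > 0), all(psi_init < 1))
  for (s in list(col_sigma_area, col_sigma_year, per_sigma_area,
                 per_sigma_year, sigma_p))
    if (!is.null(s) && s <= 0) stop("random-effect SDs must be > 0 when active")
  structure(list(psi_init = psi_init, col_alpha = col_alpha,
                 col_delta = col_delta, col_theta = col_theta,
                 col_sigma_area = col_sigma_area, col_sigma_year = col_sigma_year,
                 per_alpha = per_alpha, per_delta = per_delta,
                 per_theta = per_theta, per_sigma_area = per_sigma_area,
                 per_sigma_year = per_sigma_year, det_alpha = det_alpha,
                 det_beta_date = det_beta_date, sigma_p = sigma_p,
                 delta_det = delta_det),
            class = "dynamic_params")
}

## named lookup with recycling of a scalar over ids
expand_by <- function(x, ids, what) {
  if (length(x) == 1 && is.null(names(x))) return(setNames(rep(x, length(ids)), ids))
  if (is.null(names(x)) && length(x) == length(ids)) return(setNames(x, ids))
  if (!all(ids %in% names(x))) stop(what, " missing entries for some areas")
  x[ids]
}
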