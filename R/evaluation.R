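## Model comparison: k-fold cross-validation with predictive deviance
## (random- vs fixed-effects dynamic models) and the nested vs non-nested
## trend comparison.

#' Assign wetlands to cross-validation folds
#'
#' The cross-validation unit is the wetland: its entire detection history is
#' held out together (predicting a new wetland from its area's parameters is
#' the model's actual prediction task, and holding out whole histories
#' avoids leakage through a wetland's own past).  Assignment is stratified
#' by area so every area appears in every training set.
#'
#' @param data a [detection_table()].
#' @param k number of folds.
#' @param seed RNG seed; the same seed reproduces the assignment.
#' @return data.frame `area`, `wetland`, `fold`.
#' @export
kfold_split <- function(data, k = 5, seed = 1) {
  stopifnot(k >= 2, nrow(data) > 0)
  set.seed(as.integer(seed %% 2147483647))
  sites <- unique(as.data.frame(data)[, c("area", "wetland")])
  sites <- sites[order(sites$area, sites$wetland), ]
  out <- do.call(rbind, lapply(split(sites, sites$area), function(s) {
    n <- nrow(s)
    if (n < k)
      warning("area ", s$area[1], " has fewer wetlands (", n,
              ") than folds; spreading as evenly as possible")
    s$fold <- ((sample(n) + sample(k, 1)) %% k) + 1L
    s
  }))
  rownames(out) <- NULL
  out
}

logmeanexp_cols <- function(ll) {
  mx <- apply(ll, 2, max)
  fin <- is.finite(mx)
  out <- rep(-Inf, length(mx))
  if (any(fin))
    out[fin] <- mx[fin] +
      log(colMeans(exp(sweep(ll[, fin, drop = FALSE], 2, mx[fin]))))
  out
}

## per-record detection log-probability matrices (draws x records)
det_logp_draws <- function(m, fit, rec_area, rec_year, rec_date) {
  fixed <- !is.null(fit$meta$variant) && fit$meta$variant == "fixed"
  nR <- length(rec_area)
  if (fixed) {
    da <- m[, paste0("det_alpha[", rec_area, "]"), drop = FALSE]
    db <- m[, paste0("det_beta[", rec_area, "]"), drop = FALSE]
    lin <- da + db * matrix(rec_date, nrow(m), nR, byrow = TRUE)
  } else {
    lin <- outer(m[, "det_alpha"], rep(1, nR)) +
      outer(m[, "det_beta"], rec_date)
    if (isTRUE(fit$meta$use_det_re)) {
      cn <- paste0("delta_det[", rec_area, ":", rec_year, "]")
      have <- cn %in% colnames(m)
      if (!all(have)) stop("detection random effect missing for area-year(s): ",
                           paste(unique(cn[!have]), collapse = ", "))
      lin <- lin + m[, cn, drop = FALSE]
    }
  }
  list(logp = plogis(lin, log.p = TRUE), logq = plogis(-lin, log.p = TRUE))
}

#' Predictive deviance of held-out detection histories
#'
#' Computes `-2 * sum(log posterior-predictive probability)` over held-out
#' wetlands, where each wetland's predictive probability is the average over
#' posterior draws of its marginal likelihood (forward algorithm for dynamic
#' fits, zero-inflated Bernoulli for static fits), averaging on the
#' probability scale before taking the log.  Held-out wetlands inherit the
#' area and area-year effects of their (training-set) area.  For a
#' random-effects dynamic fit, an area absent from training is predicted by
#' drawing its effects from the fitted hyperdistribution; under fixed
#' effects such an area is an error.
#'
#' @param fit an `occ_fit`.
#' @param holdout a [detection_table()] of held-out wetlands.
#' @param ndraws number of pooled posterior draws to average over.
#' @param seed seed for hyperdistribution draws (only used for areas absent
#'   from training).
#' @return scalar deviance (0 for an empty holdout).
#' @export
predictive_deviance <- function(fit, holdout, ndraws = 500, seed = 1) {
  stopifnot(inherits(fit, "occ_fit"), inherits(holdout, "detection_table"))
  if (!nrow(holdout)) return(0)
  design <- fit$meta$design
  new_ids <- setdiff(unique(holdout$area), design$areas$area)
  if (length(new_ids)) {
    if (fit$model != "dynamic" || fit$meta$variant != "random")
      stop("cannot predict for area(s) never seen in training: ",
           paste(new_ids, collapse = ", "))
    design <- augment_design(design, holdout, new_ids)
  }
  m <- pool_draws(fit, ndraws)
  if (fit$model == "dynamic") {
    if (length(new_ids)) m <- augment_dynamic_draws(m, fit, design, new_ids, seed)
    dyn_pred_deviance(m, fit, holdout, design)
  } else {
    static_pred_deviance(m, fit, holdout)
  }
}

dyn_pred_deviance <- function(m, fit, holdout, design) {
  cd <- collapse_dynamic(holdout, design)
  ids <- cd$ids; Tn <- cd$T
  fit2 <- fit; fit2$meta$design <- design
  td <- transition_draws(fit2, m = m)
  nd <- nrow(m); nA <- length(ids)
  psi1 <- vapply(ids, function(id) plogis(m[, paste0("psi1[", id, "]")]),
                 numeric(nd))
  dim(psi1) <- c(nd, nA)
  phim <- matrix(0, nd, nA * (Tn - 1))
  gamm <- matrix(0, nd, nA * (Tn - 1))
  for (a in seq_len(nA))
    for (t in seq_len(Tn - 1)) {
      phim[, (a - 1) * (Tn - 1) + t] <- td$phi[, a, t]
      gamm[, (a - 1) * (Tn - 1) + t] <- td$gamma[, a, t]
    }
  ## per-record area/year for the detection linear predictor
  sy_site <- rep(seq_along(cd$site_area), each = Tn)
  sy_year <- rep(cd$years, times = length(cd$site_area))
  rec_area <- ids[cd$site_area[rep(sy_site, cd$sy_len)] + 1L]
  rec_year <- rep(sy_year, cd$sy_len)
  dl <- det_logp_draws(m, fit, rec_area, rec_year, cd$rec_date)
  ll <- .dyn_pred_loglik_cpp(cd, psi1, phim, gamm, dl$logp, dl$logq)
  -2 * sum(cd$site_w * logmeanexp_cols(ll))
}

static_pred_deviance <- function(m, fit, holdout) {
  covs <- fit$meta$covs
  d <- holdout[order(holdout$area, holdout$wetland, holdout$year,
                     holdout$visit), ]
  dl <- det_logp_draws(m, fit, d$area, d$year, d$date_centered)
  nd <- nrow(m)
  ll_rec <- dl$logp * matrix(d$detection, nd, nrow(d), byrow = TRUE) +
    dl$logq * matrix(1 - d$detection, nd, nrow(d), byrow = TRUE)
  sy <- factor(paste(d$area, d$year, d$wetland, sep = "\r"),
               levels = unique(paste(d$area, d$year, d$wetland, sep = "\r")))
  first <- !duplicated(sy)
  Y <- covs$year$Y[match(paste(d$area, d$year)[first],
                         paste(covs$year$area, covs$year$year))]
  L <- covs$latitude$L[match(d$area[first], covs$latitude$area)]
  alpha <- m[, paste0("alpha[", d$area[first], "]"), drop = FALSE]
  trend <- outer(m[, "beta_lat"], L) +
    (if (fit$meta$nested) m[, paste0("delta[", d$area[first], "]"),
                            drop = FALSE]
     else outer(m[, "mu"], rep(1, sum(first))))
  lpsi <- plogis(alpha + trend * matrix(Y, nd, sum(first), byrow = TRUE),
                 log.p = TRUE)
  l1mpsi <- plogis(-(alpha + trend * matrix(Y, nd, sum(first), byrow = TRUE)),
                   log.p = TRUE)
  cond <- t(rowsum(t(ll_rec), as.integer(sy)))     # draws x site-years
  anydet <- as.vector(rowsum(d$detection, as.integer(sy))) > 0
  ll_sy <- lpsi + cond
  az <- which(!anydet)
  for (j in az) {
    a1 <- ll_sy[, j]; b1 <- l1mpsi[, j]
    mx <- pmax(a1, b1)
    ll_sy[, j] <- mx + log(exp(a1 - mx) + exp(b1 - mx))
  }
  ## aggregate site-years into whole wetland histories before averaging
  wet <- factor(paste(d$area, d$wetland, sep = "\r")[first],
                levels = unique(paste(d$area, d$wetland, sep = "\r")[first]))
  ll_wet <- t(rowsum(t(ll_sy), as.integer(wet)))
  -2 * sum(logmeanexp_cols(ll_wet))
}

## extend a design with areas that appear only in the holdout
augment_design <- function(design, holdout, new_ids) {
  add <- do.call(rbind, lapply(new_ids, function(id) {
    h <- holdout[holdout$area == id, ]
    data.frame(area = id, latitude = mean(design$areas$latitude),
               n_wetlands = length(unique(h$wetland)),
               stringsAsFactors = FALSE)
  }))
  areas <- rbind(design$areas, add)
  areas$sampled_years <- c(design$sampled_years,
                           lapply(new_ids, function(id)
                             sort(unique(holdout$year[holdout$area == id]))))
  study_design(areas, years = design$years, visits = 2L)
}

## append hyperdistribution draws of a never-seen area's effects
augment_dynamic_draws <- function(m, fit, design, new_ids, seed) {
  set.seed(as.integer(seed %% 2147483647))
  nd <- nrow(m)
  for (id in new_ids) {
    add <- cbind(qlogis(runif(nd)),                      # psi1 ~ U(0,1) prior
                 rnorm(nd, 0, m[, "col_sigma_area"]),
                 rnorm(nd, 0, m[, "per_sigma_area"]))
    colnames(add) <- c(paste0("psi1[", id, "]"),
                       paste0("col_delta[", id, "]"),
                       paste0("per_delta[", id, "]"))
    if (isTRUE(fit$meta$use_det_re)) {
      yrs <- design$sampled_years[[id]]
      dd <- vapply(yrs, function(y) rnorm(nd, 0, m[, "sigma_p"]), numeric(nd))
      colnames(dd) <- paste0("delta_det[", id, ":", yrs, "]")
      add <- cbind(add, dd)
    }
    m <- cbind(m, add)
  }
  m
}

#' k-fold cross-validation of the dynamic model
#'
#' Fits the requested variants on each training set and scores the held-out
#' wetlands by [predictive_deviance()].  The random-effects variant shares
#' information across areas through hyperdistributions; the fixed-effects
#' variant estimates every parameter independently per area.
#'
#' @param data a [detection_table()].
#' @param design a [study_design()].
#' @param k number of folds.
#' @param seed master seed (fold assignment and chains).
#' @param variants subset of `c("random", "fixed")`.
#' @param chains,iter,burnin MCMC settings per training fit.
#' @param ndraws posterior draws used for prediction.
#' @return object of class `cv_result`: list with the fold `assignment`,
#'   per-fold `deviance` matrix (variant x fold) and per-variant `total`
#'   (the sum over folds).
#' @export
crossval <- function(data, design, k = 5, seed = 1,
                     variants = c("random", "fixed"),
                     chains = 2, iter = 1500, burnin = 500, ndraws = 400) {
  variants <- match.arg(variants, several.ok = TRUE)
  asg <- kfold_split(data, k = k, seed = seed)
  dev <- matrix(NA_real_, length(variants), k,
                dimnames = list(variants, paste0("fold", seq_len(k))))
  for (f in seq_len(k)) {
    hold_key <- paste(asg$area, asg$wetland)[asg$fold == f]
    in_hold <- paste(data$area, data$wetland) %in% hold_key
    train <- detection_table(as.data.frame(data)[!in_hold,
                                                 c("area", "wetland", "year",
                                                   "visit", "detection", "date")])
    hold <- detection_table(as.data.frame(data)[in_hold,
                                                c("area", "wetland", "year",
                                                  "visit", "detection", "date")])
    for (v in variants) {
      fit <- run_mcmc(train, design, model = "dynamic", variant = v,
                      chains = chains, iter = iter, burnin = burnin,
                      seed = chain_seed(seed, f))
      dev[v, f] <- predictive_deviance(fit, hold, ndraws = ndraws,
                                       seed = chain_seed(seed, f, 1L))
    }
  }
  structure(list(k = k, seed = seed, assignment = asg, deviance = dev,
                 total = rowSums(dev)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(x$k, "-fold predictive deviance (lower is better):\n", sep = "")
  print(round(cbind(x$deviance, total = x$total), 2))
  invisible(x)
}

#' Compare the nested and non-nested trend models
#'
#' Fits the static model with and without the among-area random trend on the
#' same data and seed, and compares the posterior of the latitude-on-trend
#' effect.  Ignoring the nesting treats every wetland as independent and
#' typically yields a spuriously narrow interval and overstated evidence for
#' a latitudinal gradient.
#'
#' @param data a [detection_table()].
#' @param design a [study_design()].
#' @param chains,iter,burnin,seed MCMC settings shared by both fits.
#' @param ... further arguments passed to [run_mcmc()].
#' @return object of class `nesting_comparison`: data.frame with one row per
#'   variant (posterior mean, 95% CI and P(beta > 0) for the latitude
#'   effect), with the non-nested / nested CI-width ratio as attribute
#'   `ci_width_ratio`.
#' @export
compare_nesting <- function(data, design, chains = 3, iter = 4000,
                            burnin = 1000, seed = 1, ...) {
  if (nrow(design$areas) < 2)
    warning("with a single area the nested and non-nested latitude effects ",
            "are not identified apart")
  out <- lapply(c(nested = TRUE, nonnested = FALSE), function(nst) {
    fit <- run_mcmc(data, design, model = "static", nested = nst,
                    chains = chains, iter = iter, burnin = burnin,
                    seed = seed, ...)
    s <- suppressWarnings(fit_summary(fit, params = "beta_lat"))
    data.frame(variant = if (nst) "nested" else "nonnested",
               mean = s$mean, q2.5 = s$q2.5, q97.5 = s$q97.5,
               p_gt0 = s$p_gt0, ci_width = s$q97.5 - s$q2.5,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "ci_width_ratio") <- res$ci_width[res$variant == "nonnested"] /
    res$ci_width[res$variant == "nested"]
  class(res) <- c("nesting_comparison", "data.frame")
  res
}
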