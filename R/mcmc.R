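## MCMC driver: builds packed data, initial values and parameter naming,
## runs one compiled chain per seed offset, and assembles an `occ_fit`.

chain_seed <- function(seed, chain, extra = 0L)
  as.integer((as.numeric(seed) + 1009 * chain + 97 * extra) %% 2147483647)

#' Fit an occupancy model by MCMC
#'
#' Samples the posterior of the static trend model or the dynamic
#' colonization/persistence model with an adaptive random-walk Metropolis
#' sampler (one parameter at a time within blocks; proposal scales adapt
#' toward a target acceptance rate during burn-in and are then frozen).
#' Defaults follow the reference protocol: 3 chains of 20,000 retained
#' samples after 5,000 burn-in.  Given the same seed and configuration the
#' draws are bit-identical.
#'
#' @param data a [detection_table()].
#' @param design a [study_design()] covering the data.
#' @param model `"static"` or `"dynamic"`.
#' @param nested static model: include the among-area random trend
#'   (`FALSE` gives the non-nested variant with a single shared slope).
#' @param variant dynamic model: `"random"` (crossed area/year random
#'   effects) or `"fixed"` (every parameter estimated independently per area,
#'   no hyperdistributions; fitted area by area).
#' @param use_det_re include the area-year detection random effect.
#' @param prior_convention `"sd"` places the Gamma(0.1, 0.1) prior on
#'   random-effect SDs as written; `"precision"` places it on precisions.
#' @param chains,iter,burnin chain count, retained samples per chain, and
#'   burn-in (adaptation) length.
#' @param seed master seed; per-chain seeds are derived by fixed offsets.
#' @param target_accept Metropolis target acceptance rate.
#' @param fix named list of parameters to hold fixed (names as in the output
#'   draws; SDs on the natural scale).
#' @return an object of class `occ_fit`: list with `draws` (one matrix per
#'   chain, iterations x parameters, burn-in excluded), `model`, and `meta`
#'   (design, configuration, acceptance rates).
#' @export
run_mcmc <- function(data, design, model = c("static", "dynamic"),
                     nested = TRUE, variant = c("random", "fixed"),
                     use_det_re = TRUE,
                     prior_convention = c("sd", "precision"),
                     chains = 3, iter = 20000, burnin = 5000, seed = 1,
                     target_accept = 0.3, fix = list()) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  prior_convention <- match.arg(prior_convention)
  stopifnot(inherits(data, "detection_table"), inherits(design, "study_design"),
            chains >= 1, iter >= 1, burnin >= 0)
  validate_detections(data, design)
  covs <- suppressWarnings(build_covariates(design))

  if (model == "static") {
    fit <- run_static(data, design, covs, nested, use_det_re,
                      prior_convention, chains, iter, burnin, seed,
                      target_accept, fix)
  } else if (variant == "random") {
    fit <- run_dynamic(data, design, re_area = 1L, re_year = 1L,
                       use_det_re = use_det_re, prior_convention,
                       chains, iter, burnin, seed, target_accept, fix,
                       per_area_names = FALSE)
  } else {
    ## fixed-effects variant: independent fit per area, no random effects,
    ## chains column-bound with area-tagged parameter names
    per_area <- lapply(seq_along(design$areas$area), function(i) {
      id <- design$areas$area[i]
      run_dynamic(data[data$area == id, ], subset_design(design, id),
                  re_area = 0L, re_year = 0L, use_det_re = FALSE,
                  prior_convention, chains, iter, burnin,
                  chain_seed(seed, 0L, i), target_accept, fix,
                  per_area_names = TRUE)
    })
    draws <- lapply(seq_len(chains), function(ch)
      do.call(cbind, lapply(per_area, function(f) f$draws[[ch]])))
    accept <- unlist(lapply(per_area, function(f) f$meta$accept))
    fit <- structure(list(draws = draws, model = "dynamic",
                          meta = list(variant = "fixed", design = design,
                                      covs = covs, use_det_re = FALSE,
                                      prior_convention = prior_convention,
                                      seed = seed, chains = chains,
                                      iter = iter, burnin = burnin,
                                      accept = accept)),
                     class = "occ_fit")
  }
  fit$meta$covs <- covs
  fit
}

fix_into <- function(init, fixed, fix, names, log_scale_names) {
  for (nm in names(fix)) {
    k <- match(nm, names)
    if (is.na(k)) stop("cannot fix unknown parameter ", nm)
    v <- fix[[nm]]
    if (nm %in% log_scale_names)
      v <- if (is.finite(v) && v > 0) log(v) else NaN
    if (!is.finite(v)) stop("non-finite value for fixed parameter ", nm)
    init[k] <- v
    fixed[k] <- 1L
  }
  list(init = init, fixed = fixed)
}

run_static <- function(data, design, covs, nested, use_det_re,
                       prior_convention, chains, iter, burnin, seed,
                       target_accept, fix) {
  cd <- collapse_static(data, design, covs)
  ids <- cd$ids; ay <- cd$ay
  nA <- length(ids); nAY <- nrow(ay)
  pn <- c(paste0("alpha[", ids, "]"), paste0("delta[", ids, "]"),
          "beta_lat", "mu", "sigma", "det_alpha", "det_beta", "sigma_p",
          paste0("delta_det[", ay$area, ":", ay$year, "]"))
  npar <- length(pn)
  init <- numeric(npar)
  init[pn == "sigma"] <- log(0.5)
  init[pn == "sigma_p"] <- log(0.5)
  scales <- rep(0.3, npar)
  scales[pn == "det_beta"] <- 0.05
  scales[pn == "beta_lat"] <- 0.1
  fixed <- integer(npar)
  fx <- fix_into(init, fixed, fix, pn, c("sigma", "sigma_p"))
  cfg <- list(nested = as.integer(nested), use_det_re = as.integer(use_det_re),
              prior_precision = as.integer(prior_convention == "precision"),
              n_burn = as.integer(burnin), n_keep = as.integer(iter),
              target_acc = target_accept, init = fx$init, fixed = fx$fixed,
              scales = scales)
  keep <- rep(TRUE, npar)
  if (!nested) keep[grepl("^delta\\[", pn) | pn == "sigma"] <- FALSE
  if (!use_det_re) keep[grepl("^delta_det\\[", pn) | pn == "sigma_p"] <- FALSE
  draws <- vector("list", chains)
  accept <- NULL
  for (ch in seq_len(chains)) {
    set.seed(chain_seed(seed, ch))
    res <- .static_mcmc_cpp(cd, cfg)
    m <- res$samples
    colnames(m) <- pn
    draws[[ch]] <- m[, keep, drop = FALSE]
    accept <- setNames(res$accept, pn)
  }
  structure(list(draws = draws, model = "static",
                 meta = list(nested = nested, design = design, covs = covs,
                             use_det_re = use_det_re,
                             prior_convention = prior_convention, seed = seed,
                             chains = chains, iter = iter, burnin = burnin,
                             accept = accept[keep])),
            class = "occ_fit")
}

run_dynamic <- function(data, design, re_area, re_year, use_det_re,
                        prior_convention, chains, iter, burnin, seed,
                        target_accept, fix, per_area_names = FALSE) {
  cd <- collapse_dynamic(data, design)
  ids <- cd$ids; ay <- cd$ay; years <- cd$years
  nA <- length(ids); Tn <- cd$T; nAY <- nrow(ay)
  org <- years[-Tn]
  tag <- function(base) if (per_area_names) paste0(base, "[", ids, "]") else base
  pn <- c(paste0("psi1[", ids, "]"),
          tag("col_alpha"), paste0("col_delta[", ids, "]"),
          paste0("col_theta[", org, "]"), "col_sigma_area", "col_sigma_year",
          tag("per_alpha"), paste0("per_delta[", ids, "]"),
          paste0("per_theta[", org, "]"), "per_sigma_area", "per_sigma_year",
          tag("det_alpha"), tag("det_beta"), "sigma_p",
          paste0("delta_det[", ay$area, ":", ay$year, "]"))
  ## per-area naming only makes sense for single-area (fixed-variant) fits
  if (per_area_names && nA != 1) stop("per_area_names requires one area")
  npar <- length(pn)
  init <- numeric(npar)
  sig_names <- c("col_sigma_area", "col_sigma_year", "per_sigma_area",
                 "per_sigma_year", "sigma_p")
  init[pn %in% sig_names] <- log(0.5)
  scales <- rep(0.3, npar)
  scales[grepl("det_beta", pn)] <- 0.05
  fixed <- integer(npar)
  fx <- fix_into(init, fixed, fix, pn, sig_names)
  cfg <- list(re_area = as.integer(re_area), re_year = as.integer(re_year),
              re_det = as.integer(use_det_re),
              prior_precision = as.integer(prior_convention == "precision"),
              n_burn = as.integer(burnin), n_keep = as.integer(iter),
              target_acc = target_accept, init = fx$init, fixed = fx$fixed,
              scales = scales)
  keep <- rep(TRUE, npar)
  if (!re_area)
    keep[grepl("^(col|per)_delta\\[", pn) |
           pn %in% c("col_sigma_area", "per_sigma_area")] <- FALSE
  if (!re_year)
    keep[grepl("^(col|per)_theta\\[", pn) |
           pn %in% c("col_sigma_year", "per_sigma_year")] <- FALSE
  if (!use_det_re) keep[grepl("^delta_det\\[", pn) | pn == "sigma_p"] <- FALSE
  draws <- vector("list", chains)
  accept <- NULL
  for (ch in seq_len(chains)) {
    set.seed(chain_seed(seed, ch))
    res <- .dynamic_mcmc_cpp(cd, cfg)
    m <- res$samples
    colnames(m) <- pn
    draws[[ch]] <- m[, keep, drop = FALSE]
    accept <- setNames(res$accept, pn)
  }
  structure(list(draws = draws, model = "dynamic",
                 meta = list(variant = if (re_area || re_year) "random" else "fixed",
                             design = design, use_det_re = use_det_re,
                             prior_convention = prior_convention, seed = seed,
                             chains = chains, iter = iter, burnin = burnin,
                             accept = accept[keep])),
            class = "occ_fit")
}

#' @export
print.occ_fit <- function(x, ...) {
  cat("occ_fit:", x$model,
      if (x$model == "static") paste0("(nested=", x$meta$nested, ")")
      else paste0("(variant=", x$meta$variant, ")"),
      "-", length(x$draws), "chains x", nrow(x$draws[[1]]), "draws,",
      ncol(x$draws[[1]]), "parameters\n")
  invisible(x)
}

## pooled draws across chains, optionally thinned to about n rows
pool_draws <- function(fit, n = NULL) {
  m <- do.call(rbind, fit$draws)
  if (!is.null(n) && nrow(m) > n) {
    idx <- unique(round(seq(1, nrow(m), length.out = n)))
    m <- m[idx, , drop = FALSE]
  }
  m
}
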