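test_that("fold assignment partitions wetlands, stratified by area", {
  d <- make_design(n_areas = 1, n_wetlands = 10, years = 2004:2005)
  sim <- simulate_static(d, static_gen_params(), seed = 1)
  asg <- kfold_split(sim$detections, k = 5, seed = 3)
  expect_equal(sort(table(asg$fold)), sort(c(2L, 2L, 2L, 2L, 2L)),
               ignore_attr = TRUE)
  expect_equal(sort(asg$wetland), sort(unique(sim$detections$wetland)))
  expect_identical(asg, kfold_split(sim$detections, k = 5, seed = 3))
  expect_false(identical(asg$fold, kfold_split(sim$detections, 5, 4)$fold))
  ## too-few wetlands: spread as evenly as possible, with a warning
  d2 <- make_design(n_areas = 2, n_wetlands = c(3, 10), years = 2004:2005)
  sim2 <- simulate_static(d2, static_gen_params(), seed = 2)
  expect_warning(asg2 <- kfold_split(sim2$detections, k = 5, seed = 1),
                 "fewer wetlands")
  expect_true(all(table(asg2$fold[asg2$area == "A1"]) <= 1))
})

test_that("predictive deviance matches the closed form for one history", {
  ## single held-out all-zero history in one year with K visits:
  ## deviance = -2 log(psi (1-p)^K + 1 - psi) at fixed parameters
  d <- make_design(n_areas = 1, n_wetlands = 5, years = 2004L, visits = 3,
                   sampled = list(2004L))
  cols <- c("psi1[A1]", "col_alpha", "col_delta[A1]", "col_sigma_area",
            "col_sigma_year", "per_alpha", "per_delta[A1]", "per_sigma_area",
            "per_sigma_year", "det_alpha", "det_beta", "sigma_p")
  m <- matrix(0, 30, length(cols), dimnames = list(NULL, cols))
  psi <- 0.6; p <- 0.55
  m[, "psi1[A1]"] <- qlogis(psi); m[, "det_alpha"] <- qlogis(p)
  fit <- manual_dyn_fit(d, m)
  hold <- detection_table(data.frame(area = "A1", wetland = "h1",
                                     year = 2004L, visit = 1:3,
                                     detection = 0, date = 100))
  expect_equal(predictive_deviance(fit, hold),
               -2 * log(psi * (1 - p)^3 + 1 - psi), tolerance = 1e-10)
  ## all-detections history: only the occupied path contributes
  hold1 <- detection_table(data.frame(area = "A1", wetland = "h1",
                                      year = 2004L, visit = 1:3,
                                      detection = 1, date = 100))
  expect_equal(predictive_deviance(fit, hold1), -2 * log(psi * p^3),
               tolerance = 1e-10)
  ## with constant draws, deviance is additive over held-out wetlands
  both <- detection_table(rbind(as.data.frame(hold)[, 1:6],
                                within(as.data.frame(hold1)[, 1:6],
                                       wetland <- "h2")))
  expect_equal(predictive_deviance(fit, both),
               predictive_deviance(fit, hold) +
                 predictive_deviance(fit, hold1), tolerance = 1e-10)
})

test_that("a perfect deterministic model has zero deviance, empty holdout too", {
  d <- make_design(n_areas = 1, n_wetlands = 2, years = 2004L, visits = 2,
                   sampled = list(2004L))
  cols <- c("psi1[A1]", "col_alpha", "col_delta[A1]", "col_sigma_area",
            "col_sigma_year", "per_alpha", "per_delta[A1]", "per_sigma_area",
            "per_sigma_year", "det_alpha", "det_beta", "sigma_p")
  m <- matrix(0, 10, length(cols), dimnames = list(NULL, cols))
  m[, "psi1[A1]"] <- 40; m[, "det_alpha"] <- 40   # psi = p = 1
  fit <- manual_dyn_fit(d, m)
  hold <- detection_table(data.frame(area = "A1", wetland = "h1",
                                     year = 2004L, visit = 1:2,
                                     detection = 1, date = 100))
  expect_equal(predictive_deviance(fit, hold), 0, tolerance = 1e-8)
  expect_equal(predictive_deviance(fit, empty_detections()), 0)
})

test_that("static holdout scoring matches a direct posterior average", {
  d <- make_design(n_areas = 2, n_wetlands = 8, years = 2004:2006)
  sim <- simulate_static(d, static_gen_params(), seed = 13)
  dat <- as.data.frame(sim$detections)
  in_hold <- dat$wetland %in% c("w001", "w002")
  train <- detection_table(dat[!in_hold, 1:6])
  hold <- detection_table(dat[in_hold, 1:6])
  fit <- run_mcmc(train, d, model = "static", chains = 2, iter = 400,
                  burnin = 200, seed = 5)
  dev <- predictive_deviance(fit, hold, ndraws = 200)
  expect_true(is.finite(dev) && dev > 0)
  ## reference: per-draw static likelihood of each held-out wetland history
  m <- nestocc:::pool_draws(fit, 200)
  covs <- fit$meta$covs
  ids <- d$areas$area
  hold_w <- unique(paste(hold$area, hold$wetland))
  ref <- 0
  for (k in hold_w) {
    hw <- hold[paste(hold$area, hold$wetland) == k, ]
    lls <- vapply(seq_len(nrow(m)), function(i) {
      dr <- m[i, ]
      pars <- static_params(
        alpha_area = setNames(dr[paste0("alpha[", ids, "]")], ids),
        beta_latitude = dr[["beta_lat"]], mu_trend = dr[["mu"]],
        sigma_trend = dr[["sigma"]],
        delta_trend = setNames(dr[paste0("delta[", ids, "]")], ids),
        det_alpha = dr[["det_alpha"]], det_beta_date = dr[["det_beta"]],
        sigma_p = dr[["sigma_p"]],
        delta_det = data.frame(area = rep(ids, each = 3),
                               year = rep(2004:2006, 2),
                               value = dr[paste0("delta_det[",
                                                 rep(ids, each = 3), ":",
                                                 rep(2004:2006, 2), "]")]))
      static_loglik(hw, pars, covs)
    }, 0)
    mx <- max(lls)
    ref <- ref + (mx + log(mean(exp(lls - mx))))
  }
  expect_equal(dev, -2 * ref, tolerance = 1e-8)
})

test_that("cross-validation totals are the sum of finite per-fold deviances", {
  d <- make_design(n_areas = 3, n_wetlands = 8, years = 2004:2007)
  sim <- simulate_dynamic(d, dynamic_gen_params(), seed = 7)
  cv <- crossval(sim$detections, d, k = 4, seed = 2, chains = 2, iter = 300,
                 burnin = 150, ndraws = 100)
  expect_equal(dim(cv$deviance), c(2L, 4L))
  expect_true(all(is.finite(cv$deviance)))
  expect_equal(cv$total, rowSums(cv$deviance))
  expect_true(all(cv$deviance > 0))
  expect_output(print(cv), "predictive deviance")
})

test_that("nesting comparison returns coherent intervals and flags one-area data", {
  d <- make_design(n_areas = 4, n_wetlands = 10, years = 2004:2008)
  sim <- simulate_static(d, static_gen_params(), seed = 3)
  nc <- compare_nesting(sim$detections, d, chains = 2, iter = 400,
                        burnin = 200, seed = 1)
  expect_setequal(nc$variant, c("nested", "nonnested"))
  expect_true(all(nc$q2.5 <= nc$mean & nc$mean <= nc$q97.5))
  expect_equal(attr(nc, "ci_width_ratio"),
               nc$ci_width[2] / nc$ci_width[1])
  d1 <- make_design(n_areas = 1, n_wetlands = 10, years = 2004:2008)
  sim1 <- simulate_static(d1, static_gen_params(), seed = 3)
  expect_warning(compare_nesting(sim1$detections, d1, chains = 2, iter = 200,
                                 burnin = 100, seed = 1),
                 "not identified apart")
})
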