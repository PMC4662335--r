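test_that("detection and occupancy probabilities follow the logit forms", {
  expect_equal(detection_prob(0, 0, 17, 0), 0.5)
  expect_equal(detection_prob(0, 0.1, 10, 0), plogis(1))
  expect_equal(detection_prob(-1, 0, 0, 1), 0.5)
  expect_error(detection_prob(0, 0, Inf, 0))
  expect_equal(occupancy_prob(0.7, 0.1, 2, -0.2, 0), plogis(0.7))
  expect_equal(occupancy_prob(0, 0.1, 2, -0.2, 5), 0.5)
  expect_equal(occupancy_prob(1, 0, 3, 0, c(-2, 0, 2)), rep(plogis(1), 3))
})

test_that("site-year marginal likelihood matches closed forms", {
  expect_equal(site_year_loglik(c(0, 0), 0.5, c(0.5, 0.5)), log(0.625))
  expect_equal(site_year_loglik(c(1, 0), 0.5, c(0.5, 0.5)), log(0.125))
  expect_equal(site_year_loglik(c(1, 1), 0, c(0.9, 0.9)), -Inf)
  expect_error(site_year_loglik(c(0, 2), 0.5, c(0.5, 0.5)), "0 or 1")
  expect_error(site_year_loglik(numeric(0), 0.5, numeric(0)), "length")
})

test_that("site-year likelihood is monotone in psi as expected", {
  psis <- seq(0.05, 0.95, by = 0.1)
  with_det <- vapply(psis, function(ps)
    site_year_loglik(c(1, 0), ps, c(0.6, 0.6)), 0)
  expect_true(all(diff(with_det) > 0))
  all_zero_certain <- vapply(psis, function(ps)
    site_year_loglik(c(0, 0), ps, c(1 - 1e-12, 1 - 1e-12)), 0)
  expect_true(all(diff(all_zero_certain) < 0))
})

test_that("full static likelihood reduces, adds, and matches enumeration", {
  d <- make_design(n_areas = 1, n_wetlands = 1, years = 2004L, visits = 2,
                   sampled = list(2004L))
  cv <- suppressWarnings(build_covariates(d))
  one <- detection_table(data.frame(area = "A1", wetland = "w1", year = 2004,
                                    visit = 1:2, detection = 0, date = 100))
  p <- static_params(alpha_area = c(A1 = 0), delta_trend = c(A1 = 0),
                     det_alpha = 0)
  expect_equal(static_loglik(one, p, cv), log(0.625))
  two <- detection_table(data.frame(area = "A1", wetland = c("w1", "w1", "w2", "w2"),
                                    year = 2004, visit = c(1, 2, 1, 2),
                                    detection = 0, date = 100))
  expect_equal(static_loglik(two, p, cv), 2 * log(0.625))
  expect_equal(static_loglik(empty_detections(), p, cv), 0)
})

test_that("marginalized likelihood equals exhaustive latent-state enumeration", {
  ## 2 areas x 2 wetlands x 2 years x 2 visits = 8 latent states; R surface,
  ## compiled sampler likelihood and brute-force enumeration must agree
  for (rep in 1:6) {
    set.seed(100 + rep)
    d <- make_design(n_areas = 2, n_wetlands = 2, years = 2004:2005)
    cv <- build_covariates(d)
    sim <- simulate_static(d, static_gen_params(sigma_trend = 0.4), seed = rep)
    dat <- sim$detections
    ids <- d$areas$area
    pars <- static_params(
      alpha_area = setNames(rnorm(2, 0, 0.8), ids),
      beta_latitude = rnorm(1, 0, 0.1), mu_trend = rnorm(1, 0, 0.2),
      sigma_trend = runif(1, 0.1, 0.6),
      delta_trend = setNames(rnorm(2, 0, 0.3), ids),
      det_alpha = rnorm(1, 0.5, 0.5), det_beta_date = rnorm(1, 0, 0.03),
      sigma_p = runif(1, 0.2, 0.8),
      delta_det = data.frame(area = rep(ids, each = 2),
                             year = rep(2004:2005, 2),
                             value = rnorm(4, 0, 0.4)))
    ## brute force over the joint latent configuration
    tm <- nestocc:::static_site_terms(dat, pars, cv)
    rec <- as.data.frame(dat)
    sy <- paste(rec$area, rec$year, rec$wetland)
    usy <- unique(sy)
    hist_list <- lapply(usy, function(k) rec$detection[sy == k])
    p_list <- lapply(usy, function(k) {
      rr <- rec[sy == k, ]
      ddv <- pars$delta_det$value[match(paste(rr$area[1], rr$year[1]),
                                        paste(pars$delta_det$area,
                                              pars$delta_det$year))]
      detection_prob(pars$det_alpha, pars$det_beta_date, rr$date_centered, ddv)
    })
    oracle <- oracle_static_loglik(tm$psi, hist_list, p_list)
    expect_equal(static_loglik(dat, pars, cv), oracle, tolerance = 1e-12)
    cd <- nestocc:::collapse_static(dat, d, cv)
    expect_equal(nestocc:::.static_loglik_cpp(cd, theta_static(d, pars), 1L, 1L),
                 oracle, tolerance = 1e-12)
  }
})

test_that("a missing detection random-effect entry is an error", {
  d <- make_design(n_areas = 1, n_wetlands = 1, years = 2004:2005, visits = 1)
  cv <- build_covariates(d)
  dat <- detection_table(data.frame(area = "A1", wetland = "w1",
                                    year = 2004:2005, visit = 1,
                                    detection = c(0, 1), date = 100))
  p <- static_params(alpha_area = c(A1 = 0), delta_trend = c(A1 = 0),
                     sigma_p = 0.5,
                     delta_det = data.frame(area = "A1", year = 2004,
                                            value = 0.2))
  expect_error(static_loglik(dat, p, cv), "delta_det entry missing")
})

test_that("priors follow the stated forms and support", {
  p <- static_params(alpha_area = c(A1 = 0.3), delta_trend = c(A1 = 0.1),
                     mu_trend = 0, sigma_trend = 0.5, beta_latitude = 0,
                     det_alpha = 0, sigma_p = 0.5)
  lp <- static_log_prior(p)
  ## beta and mu at 0 each contribute the Normal(0, 100) mode density;
  ## intercepts contribute the logistic (uniform-on-probability) density
  manual <- dlogis(0.3, log = TRUE) + dlogis(0, log = TRUE) +
    3 * dnorm(0, 0, 100, log = TRUE) +   # beta, mu and the date slope
    dgamma(c(0.5, 0.5), 0.1, 0.1, log = TRUE)[1] * 2 +
    dnorm(0.1, 0, 0.5, log = TRUE)
  expect_equal(lp, manual)
  p$sigma_trend <- -1
  expect_equal(static_log_prior(p), -Inf)
  ## precision convention changes the SD prior but not the rest
  p$sigma_trend <- 0.5
  expect_false(static_log_prior(p) ==
                 static_log_prior(p, prior_convention = "precision"))
})

test_that("with one visit and perfect detection the MAP matches logistic regression", {
  d <- make_design(n_areas = 1, n_wetlands = 150, years = 2004:2013,
                   visits = 1)
  cv <- build_covariates(d)
  sim <- simulate_static(d, static_gen_params(alpha_area = 0.3,
                                              mu_trend = 0.15,
                                              sigma_trend = 0,
                                              beta_latitude = 0,
                                              det_alpha = 40, sigma_p = 0),
                         seed = 21)
  dat <- sim$detections
  nll <- function(par) {
    p <- static_params(alpha_area = c(A1 = par[1]), mu_trend = par[2],
                       nested = FALSE, det_alpha = 40)
    -static_loglik(dat, p, cv)
  }
  map <- optim(c(0, 0), nll)$par
  Y <- cv$year$Y[match(dat$year, cv$year$year)]
  ref <- glm(dat$detection ~ Y, family = binomial())
  expect_equal(map, unname(coef(ref)), tolerance = 1e-3)
})

test_that("the non-nested variant strips the area trend structure", {
  p <- static_params(alpha_area = c(A1 = 0, A2 = 1), mu_trend = 0.1,
                     sigma_trend = 0.3, delta_trend = c(A1 = 0.2, A2 = -0.2))
  q <- nonnested_variant(p)
  expect_false(q$nested)
  expect_null(q$delta_trend)
  expect_null(q$sigma_trend)
  expect_equal(q$mu_trend, 0.1)
})
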