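dp_small <- function(ids = c("A1", "A2"), years = 2004:2006) {
  Tn <- length(years)
  dynamic_params(
    psi_init = setNames(rep(0.5, length(ids)), ids),
    col_alpha = qlogis(0.2), per_alpha = qlogis(0.8),
    col_delta = setNames(rnorm(length(ids), 0, 0.3), ids),
    col_theta = setNames(rnorm(Tn - 1, 0, 0.2), years[-Tn]),
    per_delta = setNames(rnorm(length(ids), 0, 0.3), ids),
    per_theta = setNames(rnorm(Tn - 1, 0, 0.2), years[-Tn]),
    col_sigma_area = 0.3, col_sigma_year = 0.2,
    per_sigma_area = 0.3, per_sigma_year = 0.2,
    det_alpha = 0.6, det_beta_date = -0.02, sigma_p = 0.4,
    delta_det = data.frame(area = rep(ids, each = length(years)),
                           year = rep(years, length(ids)),
                           value = rnorm(length(ids) * length(years), 0, 0.3)))
}

test_that("transition probabilities combine the crossed effects additively", {
  p <- dynamic_params(psi_init = c(A1 = 0.5), col_alpha = qlogis(0.2),
                      per_alpha = qlogis(0.9))
  expect_equal(unname(transition_probs(p, "A1", 2004)["phi"]), 0.9)
  p2 <- dynamic_params(psi_init = c(A1 = 0.5), col_alpha = 0,
                       per_alpha = qlogis(0.9),
                       per_delta = c(A1 = -qlogis(0.9)),
                       per_sigma_area = 0.5)
  expect_equal(unname(transition_probs(p2, "A1", 2004)["phi"]), 0.5)
  ## a year effect shifts every area by the same logit amount
  p3 <- dynamic_params(psi_init = c(A1 = 0.5, A2 = 0.5), col_alpha = 0,
                       per_alpha = 1, per_delta = c(A1 = 0.3, A2 = -0.6),
                       per_theta = c("2004" = 0.5), per_sigma_area = 1,
                       per_sigma_year = 1)
  p0 <- p3; p0$per_theta <- c("2004" = 0)
  for (a in c("A1", "A2"))
    expect_equal(
      qlogis(transition_probs(p3, a, 2004)["phi"]) -
        qlogis(transition_probs(p0, a, 2004)["phi"]),
      c(phi = 0.5))
})

test_that("a single-year history reduces to the static likelihood", {
  h <- list(c(1, 0, 1))
  p <- list(c(0.7, 0.5, 0.6))
  expect_equal(site_loglik_forward(h, p, psi1 = 0.4, phi = numeric(0),
                                   gamma = numeric(0)),
               site_year_loglik(c(1, 0, 1), 0.4, c(0.7, 0.5, 0.6)))
})

test_that("a certain event has log-probability zero", {
  h <- list(1, 1, 1)
  p <- list(1, 1, 1)
  expect_equal(site_loglik_forward(h, p, psi1 = 1, phi = c(1, 1),
                                   gamma = c(0, 0)), 0)
})

test_that("the forward algorithm matches exhaustive path enumeration", {
  set.seed(42)
  for (rep in 1:8) {
    Tn <- sample(2:10, 1)
    phi <- runif(Tn - 1, 0.5, 0.95)
    gam <- runif(Tn - 1, 0.05, 0.5)
    psi1 <- runif(1, 0.2, 0.8)
    hist_list <- lapply(seq_len(Tn), function(t) {
      if (runif(1) < 0.25) NULL else rbinom(sample(1:3, 1), 1, 0.4)
    })
    p_list <- lapply(hist_list, function(h)
      if (is.null(h)) NULL else runif(length(h), 0.3, 0.9))
    expect_equal(site_loglik_forward(hist_list, p_list, psi1, phi, gam),
                 oracle_dynamic_loglik(psi1, phi, gam, hist_list, p_list),
                 tolerance = 1e-12)
  }
})

test_that("the spec's two-year worked example matches the four-path sum", {
  h <- list(1, 0)
  p <- list(0.6, 0.6)
  expect_equal(site_loglik_forward(h, p, 0.5, phi = 0.8, gamma = 0.2),
               oracle_dynamic_loglik(0.5, 0.8, 0.2, h, p))
  ## hand sum: y1=1 requires z1=1 (prob 0.5 * 0.6); then either persists
  ## and is missed (0.8 * 0.4) or goes extinct (0.2 * 1)
  expect_equal(site_loglik_forward(h, p, 0.5, phi = 0.8, gamma = 0.2),
               log(0.5 * 0.6 * (0.8 * 0.4 + 0.2 * 1)))
})

test_that("an unobserved year acts exactly as the two-step transition product", {
  psi1 <- 0.4
  phi <- c(0.8, 0.7); gam <- c(0.15, 0.25)
  h3 <- list(c(1, 0), NULL, c(0, 1))
  p3 <- list(c(0.6, 0.7), NULL, c(0.5, 0.8))
  ## Chapman-Kolmogorov: compose the two transition matrices
  M1 <- rbind(c(1 - gam[1], gam[1]), c(1 - phi[1], phi[1]))
  M2 <- rbind(c(1 - gam[2], gam[2]), c(1 - phi[2], phi[2]))
  M <- M1 %*% M2
  h2 <- list(c(1, 0), c(0, 1))
  p2 <- list(c(0.6, 0.7), c(0.5, 0.8))
  expect_equal(site_loglik_forward(h3, p3, psi1, phi, gam),
               site_loglik_forward(h2, p2, psi1, phi = M[2, 2],
                                   gamma = M[1, 2]),
               tolerance = 1e-12)
})

test_that("partial-data probabilities are non-increasing as visits accrue", {
  psi1 <- 0.5
  phi <- rep(0.8, 3); gam <- rep(0.2, 3)
  full_h <- list(c(1, 0), 0, c(0, 0), 1)
  full_p <- list(c(0.6, 0.6), 0.7, c(0.5, 0.5), 0.6)
  ll <- vapply(seq_along(full_h), function(k) {
    h <- full_h; p <- full_p
    if (k < length(full_h)) for (j in (k + 1):length(full_h)) {
      h[j] <- list(NULL); p[j] <- list(NULL)
    }
    site_loglik_forward(h, p, psi1, phi, gam)
  }, 0)
  expect_true(all(diff(ll) <= 1e-12))
})

test_that("full-table dynamic likelihood agrees between R and compiled code", {
  set.seed(5)
  d <- make_design(n_areas = 2, n_wetlands = 4, years = 2004:2006,
                   sampled = list(2004:2006, c(2004L, 2006L)))
  sim <- simulate_dynamic(d, dynamic_gen_params(), seed = 5)
  pars <- dp_small(years = 2004:2006)
  llR <- dynamic_loglik(sim$detections, pars, d)
  cd <- nestocc:::collapse_dynamic(sim$detections, d)
  llC <- nestocc:::.dynamic_loglik_cpp(cd, theta_dynamic(d, pars), 1L, 1L, 1L)
  expect_equal(llR, llC, tolerance = 1e-12)
  expect_error(
    dynamic_loglik(detection_table(data.frame(area = "A1", wetland = "w1",
                                              year = 2015, visit = 1,
                                              detection = 0, date = 90)),
                   pars, d), "outside the global span")
})

test_that("derived occupancy follows the recursion and its fixed points", {
  years <- 2004:2023   # 20 years: convergence rate is (phi - gamma) per step
  mk <- function(phi, gam, psi1) {
    dynamic_params(psi_init = c(A1 = psi1), col_alpha = qlogis(gam),
                   per_alpha = qlogis(phi))
  }
  ## absorbing chain: constant at the initial value
  expect_equal(unname(derived_occupancy(mk(1 - 1e-15, 1e-15, 0.37), "A1", years)),
               rep(0.37, 20))
  ## convergence toward the stationary value from the reference transitions
  psi <- derived_occupancy(mk(0.896, 0.119, 0.95), "A1", years)
  stat <- 0.119 / (0.119 + 1 - 0.896)
  expect_true(abs(psi[[20]] - stat) < 0.01)
  expect_true(all(diff(unname(psi)) < 0))  # monotone approach from above
  ## the stationary value is an exact fixed point
  psi2 <- derived_occupancy(mk(0.896, 0.119, stat), "A1", years)
  expect_equal(unname(psi2), rep(stat, 20), tolerance = 1e-12)
})

test_that("regional occupancy averages areas as requested", {
  d <- make_design(n_areas = 2, n_wetlands = c(10, 30), years = 2004:2005)
  ## constant draws: area occupancies 0.2 and 0.8, no dynamics
  cols <- c("psi1[A1]", "psi1[A2]", "col_alpha", "col_delta[A1]",
            "col_delta[A2]", "col_theta[2004]", "col_sigma_area",
            "col_sigma_year", "per_alpha", "per_delta[A1]", "per_delta[A2]",
            "per_theta[2004]", "per_sigma_area", "per_sigma_year",
            "det_alpha", "det_beta", "sigma_p")
  m <- matrix(0, 50, length(cols), dimnames = list(NULL, cols))
  m[, "psi1[A1]"] <- qlogis(0.2); m[, "psi1[A2]"] <- qlogis(0.8)
  m[, "per_alpha"] <- 40; m[, "col_alpha"] <- -40  # absorbing
  fit <- manual_dyn_fit(d, m)
  reg <- regional_occupancy(fit)
  expect_equal(reg$mean, rep(0.5, 2), tolerance = 1e-8)
  regw <- regional_occupancy(fit, weights = "wetlands")
  expect_equal(regw$mean, rep(0.25 * 0.2 + 0.75 * 0.8, 2), tolerance = 1e-8)
  ob <- occupancy_by_area_year(fit)
  expect_true(all(reg$mean >= min(ob$mean) & reg$mean <= max(ob$mean)))
})

test_that("small areas shrink toward the cross-area mean under random effects", {
  d <- make_design(n_areas = 5, n_wetlands = c(4, 40, 40, 40, 40),
                   years = 2004:2009, visits = 3)
  gp <- dynamic_gen_params(per_sigma_area = 0.6, col_sigma_area = 0.6)
  sim <- simulate_dynamic(d, gp, seed = 77)
  fr <- run_mcmc(sim$detections, d, model = "dynamic", variant = "random",
                 chains = 2, iter = 1500, burnin = 500, seed = 1)
  ff <- run_mcmc(sim$detections, d, model = "dynamic", variant = "fixed",
                 chains = 2, iter = 1500, burnin = 500, seed = 1)
  phir <- apply(nestocc:::transition_draws(fr)$phi, 2, mean)
  phif <- apply(nestocc:::transition_draws(ff)$phi, 2, mean)
  cm <- mean(phir)
  ## the 4-wetland area's persistence is pulled toward the cross-area mean
  expect_lt(abs(phir[1] - cm), abs(phif[1] - cm))
  ## and shrinkage is much weaker for a 40-wetland area
  expect_lt(abs(phir[2] - phif[2]), abs(phir[1] - phif[1]))
})

test_that("mean transition summary degenerates to the intercepts without effects", {
  d <- make_design(n_areas = 2, n_wetlands = 5, years = 2004:2006)
  cols <- c("psi1[A1]", "psi1[A2]", "col_alpha", "col_delta[A1]",
            "col_delta[A2]", "col_theta[2004]", "col_theta[2005]",
            "col_sigma_area", "col_sigma_year", "per_alpha", "per_delta[A1]",
            "per_delta[A2]", "per_theta[2004]", "per_theta[2005]",
            "per_sigma_area", "per_sigma_year", "det_alpha", "det_beta",
            "sigma_p")
  m <- matrix(0, 20, length(cols), dimnames = list(NULL, cols))
  m[, "col_alpha"] <- qlogis(0.119); m[, "per_alpha"] <- qlogis(0.896)
  fit <- manual_dyn_fit(d, m)
  mt <- mean_transition_summary(fit)
  expect_equal(mt$mean[mt$parameter == "colonization"], 0.119)
  expect_equal(mt$mean[mt$parameter == "persistence"], 0.896)
  expect_true(all(mt$mean > 0 & mt$mean < 1))
})
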