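test_that("synthetic curves honour their construction and invert cleanly", {
  crv <- make_synthetic_curve(cal_range = c(2000, 100), wiggle_amp = 0,
                              slope = 1, sigma_curve = 0)
  expect_equal(crv$c14_mean, crv$cal_bp)

  expect_error(make_synthetic_curve(wiggle_amp = 500, wiggle_period = 500),
               "monotone")

  crv2 <- make_synthetic_curve(cal_range = c(16000, 8000))
  t0 <- 12345
  c14 <- approx(crv2$cal_bp, crv2$c14_mean, xout = t0)$y
  inv <- crv2$cal_bp[which.min(abs(crv2$c14_mean - c14))]
  expect_lt(abs(inv - t0), 5 + 1)  # within knot resolution
})

test_that("simulated truths follow the stated count process", {
  w <- time_grid(5999, 5000)
  set.seed(51)
  tr <- simulate_truth(c(beta0 = log(2)), window = w, phi = Inf)
  expect_lt(abs(length(tr$event_years) - 2000), 3 * sqrt(2000))
  expect_true(all(tr$event_years <= 5999 & tr$event_years >= 5000))

  tr0 <- simulate_truth(c(beta0 = -30), window = w, phi = Inf)
  expect_length(tr0$event_years, 0)

  # fixed-total conditional sampling is exact
  trn <- simulate_truth(c(beta0 = 0), window = w, phi = 10, n_events = 432)
  expect_length(trn$event_years, 432)
})

test_that("a GLM oracle on uncorrupted counts recovers the generating slope", {
  w <- time_grid(9299, 6000)
  yrs <- grid_years(w)
  z <- as.numeric(scale(sin(2 * pi * yrs / 1500)))
  set.seed(52)
  tr <- simulate_truth(c(beta0 = -1, climate = 0.1),
                       covariates = list(climate = z), window = w, phi = Inf)
  fit <- glm(tr$counts ~ z, family = poisson())
  est <- coef(fit)["z"]
  se <- sqrt(diag(vcov(fit)))["z"]
  expect_lt(abs(est - 0.1), 2 * se)
})

test_that("measurement simulation inverts through calibration", {
  crv <- identity_curve(3000, 20000, sigma = 0)
  yrs <- c(12000, 13000, 14000)
  set.seed(53)
  # zero error terms: conventional age equals the true year exactly
  tab0 <- simulate_measurements(yrs, crv, c14_error = 1e-12)
  expect_equal(tab0$c14_age, yrs, tolerance = 1e-6)
  expect_equal(nrow(tab0), 3)

  # round trip: density means sit near truth at the stated error scale
  set.seed(54)
  n <- 60
  true_yrs <- round(runif(n, 11000, 15000))
  tab <- simulate_measurements(true_yrs, crv, c14_error = 80)
  dens <- calibrate_dates(tab, crv)
  est <- vapply(dens, function(d) sum(d$grid * d$mass), numeric(1))
  mae <- mean(abs(est - true_yrs))
  expect_lt(mae, 2 * 80 * sqrt(2 / pi))  # within 2x the predicted |N(0,80)| mean
})

test_that("scenarios record their generating coefficients and reproduce", {
  sc0 <- make_scenario("null_null", n_events = 60, n_human_events = 80,
                       seed = 55)
  expect_equal(unname(sc0$truth$beta[c("climate", "humans")]), c(0, 0))
  sc1 <- make_scenario("climate_driven_humans_null", n_events = 60,
                       n_human_events = 80, seed = 55)
  expect_equal(unname(sc1$truth$beta["climate"]), 0.1)
  expect_equal(unname(sc1$truth$beta["humans"]), 0)
  sc2 <- make_scenario("humans_driven", n_events = 60, n_human_events = 80,
                       seed = 55)
  expect_lt(sc2$truth$beta["humans"], 0)
  expect_error(make_scenario("overkill_vs_climate"), "arg")

  a <- make_scenario("null_null", n_events = 60, seed = 77)
  b <- make_scenario("null_null", n_events = 60, seed = 77)
  expect_identical(a$megafauna, b$megafauna)
  expect_identical(a$truth$megafauna$counts, b$truth$megafauna$counts)
})

test_that("full-scale scenario emulation hits its exact record counts", {
  sc <- make_scenario("climate_driven_humans_null", n_events = 432,
                      n_human_events = 938, n_duplicates = 89, n_canada = 14,
                      exact_n = TRUE, seed = 56)
  expect_equal(nrow(sc$megafauna), 521)
  expect_equal(sum(sc$megafauna$cleaned_flag), 432)
  expect_equal(sum(sc$megafauna$region == "Canada"), 14)
  expect_equal(nrow(sc$humans), 938)
})
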