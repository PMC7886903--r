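test_that("running mean matches a brute-force windowed mean everywhere", {
  age <- 1000:1200
  rec_const <- climate_record(age, rep(-40, 201))
  expect_equal(smooth_running_mean(rec_const, 50)$d18o, rep(-40, 201))

  rec_lin <- climate_record(age, 0.5 * age)
  sm <- smooth_running_mean(rec_lin, 50)
  interior <- 30:170
  expect_equal(sm$d18o[interior], 0.5 * age[interior], tolerance = 1e-9)

  set.seed(31)
  y <- rnorm(201)
  rec <- climate_record(age, y)
  sm <- smooth_running_mean(rec, 50)
  brute <- vapply(seq_along(age), function(i) {
    mean(y[abs(age - age[i]) <= 25])
  }, numeric(1))
  expect_equal(sm$d18o, brute)

  expect_error(smooth_running_mean(climate_record(1:10, rnorm(10)), 50),
               "width")
})

test_that("b2k ages convert to cal BP by the 50-year datum offset", {
  rec <- climate_record(c(12050, 12060), c(-40, -41), unit = "b2k")
  out <- to_cal_bp(rec)
  expect_equal(out$age, c(12000, 12010))
  expect_equal(attr(out, "unit"), "calBP")
  # cal BP input is identity; round trip via manual re-flag
  expect_identical(to_cal_bp(out), out)
  back <- out; back$age <- back$age + 50; attr(back, "unit") <- "b2k"
  expect_equal(to_cal_bp(back)$age, out$age)
})

test_that("covariate alignment interpolates linearly and standardises", {
  g <- time_grid(1200, 1101)
  rec <- climate_record(1000:1300, 2 + 0.01 * (1000:1300))
  v <- align_covariate(rec, g, standardize = FALSE)
  expect_equal(v, 2 + 0.01 * grid_years(g))
  # off-knot years of a line interpolate onto the same line
  rec2 <- climate_record(seq(1000, 1300, by = 7), 2 + 0.01 * seq(1000, 1300, by = 7))
  expect_equal(align_covariate(rec2, g, standardize = FALSE), v,
               tolerance = 1e-9)
  z <- align_covariate(rec, g)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_error(align_covariate(rec, time_grid(5000, 4000)), "span")
})

test_that("degenerate uncertainty collapses the re-projection envelope", {
  rec <- climate_record(1:200, sin(1:200 / 20), sigma_meas = 0, age_sigma = 0)
  ens <- reproject_uncertainty(rec, M = 10)
  for (m in 1:10) expect_equal(ens$members[m, ], rec$d18o, tolerance = 1e-12)
  expect_equal(ens$lower95, rec$d18o, tolerance = 1e-12)
  expect_equal(ens$upper95, rec$d18o, tolerance = 1e-12)
  expect_error(reproject_uncertainty(rec, M = 1), "members")
})

test_that("envelope quantiles are ordered pointwise", {
  set.seed(32)
  rec <- climate_record(1:300, rnorm(300), sigma_meas = 0.2,
                        age_sigma = seq(0, 10, length.out = 300))
  ens <- reproject_uncertainty(rec, M = 50)
  expect_true(all(ens$lower95 <= ens$median + 1e-12))
  expect_true(all(ens$median <= ens$upper95 + 1e-12))
  expect_true(all(is.finite(ens$members)))
})

test_that("taphonomic ensembles honour zero-uncertainty ages and pair by M", {
  g <- time_grid(13000, 12000)
  teph <- data.frame(event_id = c("a", "b"), age_mean = c(12500, 12500),
                     age_sigma = c(0, 0))
  r <- build_taphonomic_rece(teph, M = 6, g)
  expect_equal(nrow(r), 6)
  expect_true(all(r[, "12500"] == 2L))
  expect_equal(sum(r), 12L)
})

test_that("mean taphonomic counts converge to the truncated-normal mass", {
  g <- time_grid(12700, 12300)
  teph <- data.frame(event_id = "a", age_mean = 12500, age_sigma = 40)
  set.seed(33)
  r <- build_taphonomic_rece(teph, M = 4000, g)
  yrs <- grid_years(g)
  z <- qnorm(0.99)
  p <- pnorm(yrs + 0.5, 12500, 40) - pnorm(yrs - 0.5, 12500, 40)
  p[abs(yrs - 12500) > z * 40 + 0.5] <- 0
  p <- p / sum(p)
  emp <- colMeans(r)
  mc_sd <- sqrt(p * (1 - p) / 4000)
  inside <- p > 1e-4 & abs(yrs - 12500) < z * 40 - 1  # clear of the cut bins
  expect_true(mean(abs(emp - p)[inside] <= 3 * mc_sd[inside] + 1e-9) > 0.99)
})
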