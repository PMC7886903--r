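test_that("curve files read back verbatim, with comments tolerated", {
  f <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("100,90,5", "200,210,5", "300,310,5"), f)
  crv <- read_cal_curve(f)
  expect_equal(crv$cal_bp, c(100, 200, 300))
  expect_equal(crv$c14_mean, c(90, 210, 310))
  expect_equal(crv$c14_sigma, c(5, 5, 5))

  f2 <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# IntCal-style header", "# another comment",
               "100,90,5", "200,210,5", "300,310,5"), f2)
  expect_equal(read_cal_curve(f2), crv)

  # whitespace-separated dialect
  f3 <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("100 90 5", "200\t210\t5", "300 310 5"), f3)
  expect_equal(read_cal_curve(f3), crv)
})

test_that("curve reader rejects malformed and duplicate rows loudly", {
  f <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# hdr", "100,90,5", "200,oops,5"), f)
  expect_error(read_cal_curve(f), "line 3")

  f2 <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("100,90,5", "100,95,5", "200,210,5"), f2)
  expect_error(read_cal_curve(f2), "duplicate")
})

test_that("calibration against the identity curve is a discretised normal", {
  crv <- identity_curve(4800, 5200)
  d <- calibrate(5000, 10, crv, grid = seq(5100, 4900, by = -1))
  expect_equal(sum(d$mass), 1, tolerance = 1e-12)
  expect_equal(d$grid[which.max(d$mass)], 5000)
  # symmetry about the mode
  expect_equal(d$mass, rev(d$mass), tolerance = 1e-12)
  # brute-force normalisation oracle: unnormalised grid sum
  raw <- dnorm(5000, mean = d$grid, sd = 10)
  expect_equal(d$mass, raw / sum(raw), tolerance = 1e-9)
})

test_that("a flat curve plateau yields an approximately uniform density", {
  crv <- cal_curve(cal_bp = c(1000, 1100, 1200, 1300),
                   c14_mean = c(900, 1000, 1000, 1100),
                   c14_sigma = rep(0, 4))
  d <- calibrate(1000, 5, crv, grid = seq(1300, 1000, by = -1))
  plateau <- d$grid <= 1195 & d$grid >= 1105
  m <- d$mass[plateau]
  expect_lt(diff(range(m)) / mean(m), 1e-6)
  # the plateau carries the bulk of the mass (tails leak onto the ramps)
  expect_gt(sum(d$mass[d$grid <= 1200 & d$grid >= 1100]), 0.75)
})

test_that("calibrated densities always normalise to 1", {
  crv <- make_synthetic_curve(cal_range = c(20000, 5000))
  set.seed(4)
  for (age in runif(10, 6000, 19000)) {
    d <- calibrate(age, runif(1, 20, 150), crv)
    expect_equal(sum(d$mass), 1, tolerance = 1e-9)
  }
})

test_that("calibration errors are raised for out-of-support grids", {
  crv <- identity_curve(4800, 5200)
  expect_error(calibrate(5000, 10, crv, grid = seq(6000, 4000, by = -1)),
               "outside the calibration curve support")
  expect_error(calibrate(5000, -1, crv), "c14_error")
})

test_that("HDR masks match the independent accumulate-to-level oracle", {
  expect_equal(hdr(c(0, 1, 0)), c(FALSE, TRUE, FALSE))
  # symmetric unimodal: contiguous central run containing the mode
  m <- dnorm(seq(-3, 3, length.out = 61)); m <- m / sum(m)
  mask <- hdr(m, 0.9)
  expect_true(mask[31])
  expect_equal(sum(diff(mask) != 0), 2)  # one contiguous run
  set.seed(11)
  for (i in 1:120) {
    mass <- rexp(sample(5:50, 1)); mass <- mass / sum(mass)
    lvl <- sample(c(0.5, 0.9, 0.98), 1)
    mask <- hdr(mass, lvl)
    expect_identical(mask, hdr_oracle(mass, lvl))
    expect_gte(sum(mass[mask]), lvl - 1e-12)
  }
  expect_error(hdr(c(0.4, 0.4)), "normalised")
})

test_that("density mode inverts a monotone curve as errors shrink", {
  crv <- make_synthetic_curve(cal_range = c(16000, 8000), sigma_curve = 0)
  true_year <- 12345
  c14 <- approx(crv$cal_bp, crv$c14_mean, xout = true_year)$y
  d <- calibrate(c14, 1, crv)
  expect_lt(abs(d$grid[which.max(d$mass)] - true_year), 3)
})
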