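make_test_fit <- function(M = 6, Tn = 120, beta = c(-0.5, 0.3), seed = 41,
                          ...) {
  set.seed(seed)
  g <- time_grid(10000 + (Tn - 1) * 10, 10000, step = 10)
  x <- as.numeric(scale(sin(seq_len(Tn) / 9)))
  counts <- t(vapply(seq_len(M), function(j) {
    rpois(Tn, exp(beta[1] + beta[2] * x))
  }, numeric(Tn)))
  list(response = as_rece(counts, g), x = x, grid = g)
}

test_that("the fit validates its contracts", {
  d <- make_test_fit()
  expect_error(recm(d$response, list(d$x)), "named list")
  bad <- unclass(d$response)
  expect_error(recm(bad, list(clim = d$x)), "rece")
  expect_error(recm(d$response, list(clim = d$x[-1]),
                    iterations = 200, warmup = 50), "does not match")
  expect_error(recm(d$response, list(), iterations = 100, warmup = 200),
               "warmup")
})

test_that("identical seeds give identical posterior draws", {
  d <- make_test_fit()
  f1 <- recm(d$response, list(clim = d$x), iterations = 400, warmup = 200,
             chains = 1, seed = 5)
  f2 <- recm(d$response, list(clim = d$x), iterations = 400, warmup = 200,
             chains = 1, seed = 5)
  expect_identical(f1$hyper_mean, f2$hyper_mean)
  expect_identical(f1$member, f2$member)
  expect_identical(f1$phi, f2$phi)
})

test_that("hyper-posteriors are invariant to joint member permutation", {
  d <- make_test_fit(M = 8, seed = 43)
  g <- d$grid
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  r1 <- d$response
  r2 <- as_rece(unclass(r1)[perm, ], g)
  f1 <- recm(r1, list(clim = d$x), iterations = 2000, warmup = 600,
             chains = 1, seed = 9)
  f2 <- recm(r2, list(clim = d$x), iterations = 2000, warmup = 600,
             chains = 1, seed = 9)
  expect_lt(abs(mean(f1$hyper_mean[, "beta_clim"]) -
                mean(f2$hyper_mean[, "beta_clim"])), 0.05)
  expect_lt(abs(mean(f1$hyper_mean[, "beta0"]) -
                mean(f2$hyper_mean[, "beta0"])), 0.05)
})

test_that("identical members collapse the between-member spread", {
  set.seed(44)
  d <- make_test_fit(M = 1, Tn = 150, seed = 44)
  one <- unclass(d$response)
  rep10 <- as_rece(one[rep(1, 10), ], d$grid)
  f10 <- recm(rep10, list(clim = d$x), iterations = 2000, warmup = 800,
              chains = 1, seed = 3)
  f1 <- recm(d$response, list(clim = d$x), iterations = 2000, warmup = 800,
             chains = 1, seed = 3)
  # hyper-sds concentrate near zero relative to their half-normal(1) prior
  expect_lt(median(f10$hyper_sd[, "sd_beta_clim"]), 0.15)
  # hyper-means match a single-member fit
  expect_lt(abs(mean(f10$hyper_mean[, "beta_clim"]) -
                mean(f1$hyper_mean[, "beta_clim"])), 0.07)
})

test_that("significance decisions follow the credible-interval rule", {
  d <- make_test_fit()
  fit <- recm(d$response, list(clim = d$x), iterations = 300, warmup = 100,
              chains = 1, seed = 2)
  fit$hyper_mean[, "beta_clim"] <- abs(fit$hyper_mean[, "beta_clim"]) + 0.01
  expect_equal(significance(fit, "clim")$decision, "significant_positive")
  fit$hyper_mean[, "beta_clim"] <- -fit$hyper_mean[, "beta_clim"]
  expect_equal(significance(fit, "clim")$decision, "significant_negative")
  s <- sort(rnorm(nrow(fit$hyper_mean)))
  fit$hyper_mean[, "beta_clim"] <- c(s, -s)[seq_len(nrow(fit$hyper_mean))]
  expect_equal(significance(fit, "clim")$decision, "not_significant")
  expect_error(significance(fit, "nope"), "unknown covariate")
})

test_that("methods expose coherent views of the posterior", {
  d <- make_test_fit(M = 4)
  fit <- recm(d$response, list(clim = d$x), iterations = 600, warmup = 200,
              chains = 2, seed = 8)
  expect_named(coef(fit), c("beta0", "beta_clim"))
  ci <- confint(fit)
  expect_true(all(ci[, 1] < ci[, 2]))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.recm")
  expect_true("phi" %in% sm$table$parameter)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(unclass(d$response)))
  expect_true(all(sims[[1]] >= 0))
  mu <- fitted(fit)
  expect_equal(dim(mu), dim(unclass(d$response)))
  r <- residuals(fit)
  expect_equal(dim(r), dim(mu))
  expect_output(print(fit), "Hierarchical NB")
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f, width = 600, height = 250)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("posterior matches an independent MCMC engine on a shared fixture", {
  skip_if_not_installed("rjags")
  set.seed(46)
  M <- 4; Tn <- 80
  g <- time_grid(9000 + (Tn - 1) * 10, 9000, step = 10)
  x <- as.numeric(scale(cos(seq_len(Tn) / 6)))
  counts <- t(vapply(seq_len(M), function(j) {
    rnbinom(Tn, mu = exp(0.4 + 0.5 * x), size = 5)
  }, numeric(Tn)))
  resp <- as_rece(counts, g)
  fit <- recm(resp, list(clim = x), iterations = 6000, warmup = 2000,
              chains = 1, seed = 12, standardize = FALSE)

  model <- "model {
    for (i in 1:N) {
      y[i] ~ dnegbin(p[i], r)
      p[i] <- r / (r + mu[i])
      log(mu[i]) <- b0[g[i]] + b1[g[i]] * x[i]
    }
    for (j in 1:M) {
      b0[j] ~ dnorm(B0, pow(s0, -2))
      b1[j] ~ dnorm(B1, pow(s1, -2))
    }
    B0 ~ dnorm(0, 0.01); B1 ~ dnorm(0, 0.01)
    s0 ~ dnorm(0, 1) T(0.0001,); s1 ~ dnorm(0, 1) T(0.0001,)
    invr ~ dnorm(0, 0.04) T(0.0001,)
    r <- 1 / invr
  }"
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(y = as.integer(t(counts)), x = rep(x, M),
                g = rep(seq_len(M), each = Tn), N = M * Tn, M = M),
    inits = list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = 7),
    n.chains = 1, quiet = TRUE)
  update(jm, 1500)
  s <- rjags::coda.samples(jm, c("B0", "B1", "r"), 4000)[[1]]

  expect_lt(abs(mean(fit$hyper_mean[, "beta_clim"]) - mean(s[, "B1"])), 0.05)
  expect_lt(abs(mean(fit$hyper_mean[, "beta0"]) - mean(s[, "B0"])), 0.05)
  # dispersion agrees on the log scale (its posterior is long-tailed)
  expect_lt(abs(median(log(fit$phi)) - median(log(s[, "r"]))), 0.4)
})
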