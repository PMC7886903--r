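#' Synthetic calibration curve
#'
#' A monotone baseline with optional sinusoidal wiggles and a constant
#' curve error: `c14_mean(t) = slope * t + wiggle_amp * sin(2*pi*t /
#' wiggle_period)`. Used as the test-default curve so every pipeline stage
#' runs without external downloads; real curves are supplied at runtime
#' via [read_cal_curve()].
#'
#' @param cal_range Calendar span of the curve, years cal BP (oldest,
#'   youngest).
#' @param knot_step Knot spacing in years.
#' @param slope Baseline slope (14C yr per cal yr), > 0.
#' @param wiggle_amp Wiggle amplitude, 14C yr.
#' @param wiggle_period Wiggle period, years.
#' @param sigma_curve Constant curve 1-sigma error, 14C yr.
#' @return A [cal_curve]. Errors if the chosen wiggles destroy strict
#'   monotonicity of `c14_mean` (required for unambiguous inversion).
#' @export
make_synthetic_curve <- function(cal_range = c(30000, 1000), knot_step = 5,
                                 slope = 1, wiggle_amp = 15,
                                 wiggle_period = 500, sigma_curve = 10) {
  if (slope <= 0) stop("slope must be > 0")
  t <- seq(cal_range[2L], cal_range[1L], by = knot_step)
  c14 <- slope * t + wiggle_amp * sin(2 * pi * t / wiggle_period)
  if (any(!is.finite(c14))) stop("curve parameters produce non-finite values")
  if (any(diff(c14) <= 0)) {
    stop("wiggles too large for the slope: c14_mean is not strictly monotone ",
         "(need slope > 2*pi*wiggle_amp/wiggle_period)")
  }
  cal_curve(cal_bp = t, c14_mean = c14, c14_sigma = rep(sigma_curve, length(t)))
}

#' Simulate a ground-truth event history
#'
#' The generative counterpart of the analysis model: for every year of the
#' window a count is drawn from a negative-binomial (or Poisson) process
#' whose log mean is linear in the supplied covariate series,
#' `log mu(t) = beta0 + sum_k beta_k x_k(t)`, and counts are expanded into
#' individual event years.
#'
#' @param beta Named coefficient vector on the log-link scale; the first
#'   element is the intercept, the rest must match `names(covariates)`.
#' @param covariates Named list of numeric series, one value per window
#'   year (supply standardized series to interpret `beta` in standardized
#'   units).
#' @param window A [time_grid()] (annual).
#' @param phi Negative-binomial dispersion of the generating process;
#'   `Inf` gives Poisson counts.
#' @param n_events If given, exactly this many events are drawn by
#'   multinomial sampling with probability proportional to `mu(t)`
#'   (the fixed-total conditional of the count process); otherwise the
#'   total is random.
#' @return A `synthetic_truth` list: `beta`, `event_years`, `counts` (per
#'   window year), `covariates`, `window`.
#' @export
simulate_truth <- function(beta, covariates = list(), window,
                           phi = Inf, n_events = NULL) {
  yrs <- grid_years(window)
  Tn <- length(yrs)
  eta <- rep(beta[1L], Tn)
  if (length(covariates)) {
    if (!all(names(covariates) %in% names(beta))) {
      stop("every covariate series needs a matching named beta")
    }
    for (nm in names(covariates)) {
      x <- covariates[[nm]]
      if (length(x) != Tn) stop("covariate '", nm, "' must have one value per window year")
      eta <- eta + beta[nm] * x
    }
  }
  if (any(eta > 50)) stop("log-mean overflow: check beta")
  mu <- exp(eta)
  if (is.null(n_events)) {
    counts <- if (is.infinite(phi)) stats::rpois(Tn, mu)
              else stats::rnbinom(Tn, mu = mu, size = phi)
  } else {
    counts <- as.integer(stats::rmultinom(1L, size = n_events,
                                          prob = mu / sum(mu)))
  }
  structure(
    list(beta = beta, event_years = rep(yrs, counts), counts = counts,
         covariates = covariates, window = window, phi = phi),
    class = "synthetic_truth"
  )
}

#' Simulate radiocarbon measurements of known event years
#'
#' For each true calendar year t the conventional age is drawn from
#' `Normal(c14_mean(t), sqrt(c14_error^2 + c14_sigma(t)^2))` — the exact
#' error model that [calibrate()] later inverts.
#'
#' @param truth A `synthetic_truth` (or a bare vector of event years, cal
#'   BP).
#' @param curve A [cal_curve] covering the event years.
#' @param c14_error Reported 1-sigma measurement error, 14C yr.
#' @param id_prefix Prefix for generated record ids.
#' @return A date-table data frame (one row per event) with the standard
#'   columns; `taxon`, `site`, `region` are left empty and `cleaned_flag`
#'   is `TRUE`.
#' @export
simulate_measurements <- function(truth, curve, c14_error = 80,
                                  id_prefix = "SYN") {
  yrs <- if (inherits(truth, "synthetic_truth")) truth$event_years else truth
  n <- length(yrs)
  cv <- curve_at(curve, yrs)
  sd_tot <- sqrt(c14_error^2 + cv$c14_sigma^2)
  ages <- stats::rnorm(n, mean = cv$c14_mean, sd = sd_tot)
  data.frame(
    record_id = sprintf("%s-%04d", id_prefix, seq_len(n)),
    taxon = "", site = "", region = "",
    c14_age = ages, c14_error = c14_error, cleaned_flag = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Generate a complete synthetic study scenario
#'
#' Produces every input the pipeline consumes — megafauna and human
#' radiocarbon date tables, an annual climate record with measurement and
#' accumulated age uncertainty, a tephra-based taphonomic event table and
#' a calibration curve — from a known generative truth, so full-pipeline
#' parameter recovery can be tested without downloads.
#'
#' Scenarios encode the competing hypotheses: `"climate_driven_humans_null"`
#' sets the climate coefficient to +0.1 (standardized units) and the human
#' coefficient to 0; `"null_null"` sets both to 0; `"humans_driven"` sets
#' the human coefficient to -0.1 and climate to 0. The taphonomic
#' coefficient is 0 in all scenarios. Defaults mirror the real records'
#' order of magnitude at desk scale: ~300 megafauna events, ~600 human
#' events, a 15.0-11.7 ka window, M = 20 and 80 14C yr measurement errors.
#'
#' @param name Scenario name.
#' @param n_events Expected (or exact, see `exact_n`) megafauna event count.
#' @param n_human_events Expected/exact human event count.
#' @param n_duplicates Extra duplicate megafauna rows appended with
#'   `cleaned_flag = FALSE`, emulating non-separable repeat dates of single
#'   individuals (the full table then has `n_events + n_duplicates` rows
#'   and the chronological-cleaning filter recovers `n_events`).
#' @param n_canada Number of megafauna rows assigned the region label
#'   `"Canada"`.
#' @param n_tephra Number of tephra events.
#' @param window Analysis window, a [time_grid()] (annual).
#' @param M Default ensemble size recorded in the truth bundle.
#' @param c14_error 1-sigma radiocarbon measurement error, 14C yr.
#' @param phi Dispersion of the generating count process.
#' @param exact_n Draw exactly `n_events`/`n_human_events` events
#'   (fixed-total multinomial) instead of a random NB total.
#' @param seed Optional seed; the whole bundle is reproducible from it.
#' @return List with elements `megafauna`, `humans`, `climate`, `tephra`,
#'   `curve` and `truth` (the `synthetic_truth` plus scenario bookkeeping).
#' @export
make_scenario <- function(name = c("climate_driven_humans_null", "null_null",
                                   "humans_driven"),
                          n_events = 300, n_human_events = 600,
                          n_duplicates = 0, n_canada = 0, n_tephra = 60,
                          window = time_grid(15000, 11700), M = 20,
                          c14_error = 80, phi = 10, exact_n = FALSE,
                          seed = NULL) {
  name <- match.arg(name)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(window$step == 1L)
  yrs <- grid_years(window)
  pad <- 2000
  curve <- make_synthetic_curve(
    cal_range = c(window$start_bp + pad + 1000, max(window$end_bp - pad, 0)))

  # climate truth: millennial-scale quasi-stadial variability (permil)
  ext_age <- seq(window$end_bp - pad, window$start_bp + pad, by = 1)
  clim_fun <- function(t) {
    -40 + 1.8 * sin(2 * pi * (t - window$end_bp) / 3000) +
      0.6 * sin(2 * pi * t / 1100)
  }
  clim_true <- clim_fun(ext_age)
  climate <- climate_record(
    age = ext_age, d18o = clim_true, sigma_meas = 0.1,
    age_sigma = pmax(0, 0.004 * (ext_age - min(ext_age))),
    unit = "calBP")
  z_climate <- standardize_vec(clim_fun(yrs))

  # human truth: late-glacial population growth ramp (younger = larger)
  hum_int <- exp(1.2 * (window$start_bp - yrs) / (window$start_bp - window$end_bp))
  z_humans <- standardize_vec(hum_int)
  h_beta0 <- log(n_human_events / sum(hum_int))
  hmu <- hum_int / sum(hum_int) * n_human_events
  h_counts <- if (exact_n) {
    as.integer(stats::rmultinom(1L, n_human_events, prob = hmu))
  } else stats::rnbinom(length(yrs), mu = hmu, size = phi)
  humans_truth <- structure(
    list(beta = c(beta0 = h_beta0), event_years = rep(yrs, h_counts),
         counts = h_counts, covariates = list(), window = window, phi = phi),
    class = "synthetic_truth")

  beta <- switch(name,
    climate_driven_humans_null = c(beta0 = 0, climate = 0.1, humans = 0,
                                   taphonomy = 0),
    null_null = c(beta0 = 0, climate = 0, humans = 0, taphonomy = 0),
    humans_driven = c(beta0 = 0, climate = 0, humans = -0.1, taphonomy = 0))
  lin <- beta["climate"] * z_climate + beta["humans"] * z_humans
  beta["beta0"] <- log(n_events / sum(exp(lin)))
  mega_truth <- simulate_truth(
    beta, covariates = list(climate = z_climate, humans = z_humans),
    window = window, phi = phi,
    n_events = if (exact_n) n_events else NULL)

  taxa <- c("Equus sp.", "Mammuthus sp.", "Mammut americanum",
            "Nothrotheriops shastensis", "Smilodon fatalis")
  regions <- c("Great Lakes", "Southwest", "Other")

  megafauna <- simulate_measurements(mega_truth, curve, c14_error,
                                     id_prefix = "MEGA")
  n_m <- nrow(megafauna)
  megafauna$taxon <- sample(taxa, n_m, replace = TRUE,
                            prob = c(0.25, 0.3, 0.2, 0.15, 0.1))
  megafauna$site <- sprintf("site_%03d", sample.int(max(2L, n_m %/% 3L), n_m,
                                                    replace = TRUE))
  megafauna$region <- sample(regions, n_m, replace = TRUE,
                             prob = c(0.35, 0.3, 0.35))
  if (n_canada > 0) {
    megafauna$region[sample.int(n_m, min(n_canada, n_m))] <- "Canada"
  }
  if (n_duplicates > 0) {
    pool <- which(megafauna$region != "Canada")  # keep regional counts exact
    src <- megafauna[sample(pool, n_duplicates,
                            replace = n_duplicates > length(pool)), ]
    src$record_id <- sprintf("MEGA-DUP-%04d", seq_len(n_duplicates))
    src$c14_age <- src$c14_age + stats::rnorm(n_duplicates, 0, src$c14_error / 2)
    src$cleaned_flag <- FALSE
    megafauna <- rbind(megafauna, src)
    megafauna <- megafauna[sample.int(nrow(megafauna)), ]
    rownames(megafauna) <- NULL
  }

  humans <- simulate_measurements(humans_truth, curve, c14_error,
                                  id_prefix = "ARCH")
  humans$taxon <- "Homo sapiens"
  humans$site <- sprintf("asite_%03d", seq_len(nrow(humans)))

  tephra <- data.frame(
    event_id = sprintf("TEPH-%03d", seq_len(n_tephra)),
    age_mean = round(stats::runif(n_tephra, window$end_bp, window$start_bp)),
    age_sigma = round(stats::runif(n_tephra, 30, 80)),
    stringsAsFactors = FALSE
  )

  list(
    megafauna = megafauna, humans = humans, climate = climate,
    tephra = tephra, curve = curve,
    truth = list(
      scenario = name, beta = beta, megafauna = mega_truth,
      humans = humans_truth, z_climate = z_climate, z_humans = z_humans,
      climate_true = clim_true, window = window, M = M,
      c14_error = c14_error, phi = phi, seed = seed)
  )
}
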