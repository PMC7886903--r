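#' Prior settings for the hierarchical event-count regression
#'
#' Weakly informative defaults: Normal(0, `hyper_mean_sd`) on each top-level
#' coefficient mean, half-Normal(`hyper_sd_scale`) on each between-member
#' standard deviation, and half-Normal(`dispersion_inv_scale`) on the
#' reciprocal of the shared negative-binomial dispersion.
#'
#' @param hyper_mean_sd Prior sd of the hyper-means (default 10).
#' @param hyper_sd_scale Half-normal scale of the hyper-sds (default 1).
#' @param dispersion_inv_scale Half-normal scale on 1/phi (default 5).
#' @return List of prior settings.
#' @export
recm_priors <- function(hyper_mean_sd = 10, hyper_sd_scale = 1,
                        dispersion_inv_scale = 5) {
  stopifnot(hyper_mean_sd > 0, hyper_sd_scale > 0, dispersion_inv_scale > 0)
  list(hyper_mean_sd = hyper_mean_sd, hyper_sd_scale = hyper_sd_scale,
       dispersion_inv_scale = dispersion_inv_scale)
}

#' Fit a hierarchical negative-binomial event-count regression
#'
#' The REC regression model: each ensemble member m of the response (one
#' probable annual event-count sequence) is a separate negative-binomial
#' count regression,
#' \deqn{y_{mt} \sim \mathrm{NB}(\mu_{mt}, \phi), \quad
#'       \log \mu_{mt} = \beta_{0m} + \sum_k \beta_{km} x_{kmt},}
#' and the member-level coefficients are pooled under top-level normal
#' hyper-distributions \eqn{\beta_{km} \sim N(B_k, \sigma_k)}. The
#' hyper-means \eqn{B_k} summarise the covariate effects across all
#' probable event histories, so their posteriors carry the chronological
#' uncertainty of the radiocarbon record without conflating it with
#' process variation. Covariate member j is always paired with response
#' member j, so covariate ensembles propagate their own chronological
#' uncertainty into the matching regression.
#'
#' @param response A `rece` (M members x T retained years), typically
#'   thinned with [thin_rece()].
#' @param covariates Named list; each element one of: a `rece` with the
#'   same M and grid (member-paired counts, e.g. a human population or
#'   taphonomic proxy), a `climate_ensemble` (member-paired series; must
#'   have at least M members and is aligned onto the response grid), a
#'   `climate_record`, or a numeric vector with one value per retained
#'   year (shared across members).
#' @param iterations Total MCMC iterations per chain (default 3000).
#' @param warmup Warm-up (adaptation) iterations discarded from each chain
#'   (default 1000).
#' @param chains Number of chains (default 2).
#' @param priors A [recm_priors()] list.
#' @param dispersion `NULL` to estimate the shared dispersion, or a fixed
#'   positive value (large values approach the Poisson limit).
#' @param standardize Z-score every covariate over the window, per member
#'   (default `TRUE`); coefficients then refer to standardized units.
#' @param seed Optional integer seed; chains use `seed`, `seed + 1`, ...
#'   Identical seed and configuration give identical draws.
#' @return An object of class `recm`; see [summary.recm()],
#'   [significance()], [coef.recm()], [plot.recm()].
#' @examples
#' \donttest{
#' sc <- make_scenario("climate_driven_humans_null", n_events = 150,
#'                     M = 8, seed = 1)
#' fit <- fit_scenario(sc, family = "climate_only", iterations = 1500,
#'                     warmup = 500, chains = 1, seed = 1)
#' summary(fit)
#' }
#' @export
recm <- function(response, covariates = list(),
                 iterations = 3000, warmup = 1000, chains = 2,
                 priors = recm_priors(), dispersion = NULL,
                 standardize = TRUE, seed = NULL) {
  if (!inherits(response, "rece")) stop("response must be a rece object")
  if (iterations <= warmup || warmup < 0) stop("need iterations > warmup >= 0")
  if (chains < 1) stop("chains must be >= 1")
  M <- nrow(response)
  Tn <- ncol(response)
  g <- attr(response, "grid")
  if (any(response < 0) || any(response != round(response))) {
    stop("response counts must be non-negative integers")
  }
  cov_names <- names(covariates)
  if (length(covariates) && (is.null(cov_names) || any(cov_names == ""))) {
    stop("covariates must be a named list")
  }

  # per-member T x K covariate slices, member-paired
  cov_members <- lapply(covariates, align_member_covariate, response = response)
  K <- length(cov_members)

  # stacked design, sorted by member
  y <- as.integer(t(response))              # member-major stacking
  memb <- rep(seq_len(M), each = Tn)
  X <- matrix(1.0, nrow = M * Tn, ncol = 1L + K)
  colnames(X) <- c("beta0", if (K) paste0("beta_", cov_names))
  for (k in seq_len(K)) {
    v <- cov_members[[k]]                   # M x T
    # a constant member slice (e.g. an all-zero count covariate) carries no
    # information for that member; centre it to zero rather than fail
    if (standardize) {
      v <- t(apply(v, 1L, function(row) {
        s <- stats::sd(row)
        if (!is.finite(s) || s == 0) rep(0, length(row))
        else (row - mean(row)) / s
      }))
    }
    X[, k + 1L] <- as.numeric(t(v))
  }

  fixed_phi <- if (is.null(dispersion)) NA_real_ else {
    stopifnot(dispersion > 0); as.numeric(dispersion)
  }
  beta_init <- c(log(mean(y) + 0.01), rep(0, K))

  n_save <- iterations - warmup
  chains_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    if (!is.null(seed)) set.seed(seed + ch - 1L)
    chains_out[[ch]] <- .recm_sampler(
      y = y, X = X, member = memb, M = M,
      n_warmup = as.integer(warmup), n_save = as.integer(n_save),
      hyper_mean_sd = priors$hyper_mean_sd,
      hyper_sd_scale = priors$hyper_sd_scale,
      disp_inv_scale = priors$dispersion_inv_scale,
      fixed_phi = fixed_phi,
      beta_init = beta_init, phi_init = 10)
  }

  par_names <- colnames(X)
  hyper_mean <- do.call(rbind, lapply(chains_out, `[[`, "B"))
  hyper_sd <- do.call(rbind, lapply(chains_out, `[[`, "sigma"))
  colnames(hyper_mean) <- par_names
  colnames(hyper_sd) <- paste0("sd_", par_names)
  phi_draws <- unlist(lapply(chains_out, `[[`, "phi"))
  member_draws <- do.call(rbind, lapply(chains_out, `[[`, "beta"))
  colnames(member_draws) <- paste0(rep(par_names, each = M), "[",
                                   rep(seq_len(M), length(par_names)), "]")

  diag_mat <- cbind(hyper_mean, hyper_sd)
  if (is.null(dispersion)) diag_mat <- cbind(diag_mat, phi = phi_draws)
  diagnostics <- mcmc_diagnostics(diag_mat, chains, n_save)

  out <- list(
    hyper_mean = hyper_mean, hyper_sd = hyper_sd, phi = phi_draws,
    member = member_draws, parameters = par_names, covariates = cov_names,
    M = M, grid = g, n_obs = Tn,
    diagnostics = diagnostics,
    config = list(iterations = iterations, warmup = warmup, chains = chains,
                  priors = priors, dispersion = dispersion,
                  standardize = standardize, seed = seed,
                  source_label = attr(response, "source_label")),
    design = list(y = y, X = X, member = memb),
    call = match.call()
  )
  class(out) <- "recm"
  if (!diagnostics$converged) {
    warning("MCMC convergence diagnostics flagged: max split R-hat = ",
            round(diagnostics$rhat_max, 3),
            " (target <= 1.05); inspect $diagnostics", call. = FALSE)
  }
  out
}

# Resolve one covariate spec into an M x T member-paired matrix.
align_member_covariate <- function(cv, response) {
  M <- nrow(response); Tn <- ncol(response)
  g <- attr(response, "grid")
  yrs <- grid_years(g)
  if (inherits(cv, "rece")) {
    if (nrow(cv) != M) {
      stop("covariate ensemble has ", nrow(cv), " members but the response has ",
           M, "; member pairing requires equal M")
    }
    cg <- attr(cv, "grid")
    if (!identical(grid_years(cg), yrs)) {
      stop("covariate RECE grid does not match the response grid; ",
           "build and thin it on the same window")
    }
    return(matrix(as.numeric(cv), nrow = M))
  }
  if (inherits(cv, "climate_ensemble")) {
    if (nrow(cv$members) < M) {
      stop("climate ensemble has fewer members (", nrow(cv$members),
           ") than the response (", M, ")")
    }
    out <- t(vapply(seq_len(M), function(j) {
      align_covariate(cv$members[j, ], grid = g, age = cv$age,
                      standardize = FALSE)
    }, numeric(Tn)))
    return(out)
  }
  if (inherits(cv, "climate_record")) {
    v <- align_covariate(cv, grid = g, standardize = FALSE)
    return(matrix(v, nrow = M, ncol = Tn, byrow = TRUE))
  }
  if (is.numeric(cv) && is.null(dim(cv))) {
    if (length(cv) != Tn) {
      stop("numeric covariate length ", length(cv),
           " does not match the response grid (", Tn, " retained years)")
    }
    return(matrix(cv, nrow = M, ncol = Tn, byrow = TRUE))
  }
  if (is.matrix(cv)) {
    if (!all(dim(cv) == c(M, Tn))) stop("matrix covariate must be M x T")
    return(cv)
  }
  stop("unsupported covariate type: ", paste(class(cv), collapse = "/"))
}

# Split R-hat and effective sample size for a draws matrix (chains stacked).
mcmc_diagnostics <- function(draws, chains, n_save) {
  rhat <- apply(draws, 2L, split_rhat, chains = chains, n_save = n_save)
  ess <- vapply(seq_len(ncol(draws)), function(k) {
    sum(vapply(seq_len(chains), function(ch) {
      rows <- ((ch - 1) * n_save + 1):(ch * n_save)
      as.numeric(coda::effectiveSize(draws[rows, k]))
    }, numeric(1)))
  }, numeric(1))
  names(ess) <- colnames(draws)
  list(rhat = rhat, ess = ess, rhat_max = max(rhat, na.rm = TRUE),
       ess_min = min(ess), converged = max(rhat, na.rm = TRUE) <= 1.05)
}

split_rhat <- function(x, chains, n_save) {
  half <- floor(n_save / 2)
  segs <- lapply(seq_len(chains), function(ch) {
    v <- x[((ch - 1) * n_save + 1):(ch * n_save)]
    list(v[seq_len(half)], v[(n_save - half + 1):n_save])
  })
  segs <- unlist(segs, recursive = FALSE)
  m <- length(segs); n <- half
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
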