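#' Construct an ice-core climate record
#'
#' Holds a d18O series against its age axis, with optional per-sample
#' measurement error and accumulated (layer-counting) age uncertainty.
#'
#' @param age Sample ages, strictly monotone. Unit given by `unit`.
#' @param d18o Oxygen-isotope values, permil.
#' @param sigma_meas Optional 1-sigma measurement error, permil (scalar or
#'   per sample).
#' @param age_sigma Optional accumulated 1-sigma age (counting) uncertainty
#'   per sample, years.
#' @param unit Age datum: `"calBP"` (years before 1950 CE) or `"b2k"`
#'   (years before 2000 CE, the GICC05 datum).
#' @return A `climate_record` data frame with attribute `unit`.
#' @export
climate_record <- function(age, d18o, sigma_meas = NULL, age_sigma = NULL,
                           unit = c("calBP", "b2k")) {
  unit <- match.arg(unit)
  stopifnot(length(age) == length(d18o))
  if (anyNA(age) || anyNA(d18o)) stop("climate record values must be finite")
  if (is.unsorted(age, strictly = TRUE) &&
      is.unsorted(rev(age), strictly = TRUE)) {
    stop("climate record ages must be strictly monotone")
  }
  df <- data.frame(age = age, d18o = d18o)
  if (!is.null(sigma_meas)) df$sigma_meas <- rep_len(sigma_meas, nrow(df))
  if (!is.null(age_sigma)) {
    if (any(age_sigma < 0)) stop("age_sigma must be >= 0")
    df$age_sigma <- rep_len(age_sigma, nrow(df))
  }
  structure(df, unit = unit, class = c("climate_record", "data.frame"))
}

#' Read an NGRIP-style delimited d18O series
#'
#' Two to four columns: age, d18O and optionally measurement sigma and
#' accumulated age sigma. `#` comment lines are skipped.
#'
#' @param path File path (tab-, comma- or whitespace-separated).
#' @param unit Age datum of the file (see [climate_record()]).
#' @return A `climate_record`.
#' @export
read_climate <- function(path, unit = c("calBP", "b2k")) {
  unit <- match.arg(unit)
  m <- utils::read.table(path, header = FALSE, comment.char = "#",
                         sep = "", fill = FALSE)
  if (ncol(m) == 1L) {  # retry comma-separated
    m <- utils::read.table(path, header = FALSE, comment.char = "#", sep = ",")
  }
  if (ncol(m) < 2L) stop("climate file needs >= 2 columns (age, d18O): ", path)
  climate_record(age = m[[1L]], d18o = m[[2L]],
                 sigma_meas = if (ncol(m) >= 3L) m[[3L]],
                 age_sigma = if (ncol(m) >= 4L) m[[4L]],
                 unit = unit)
}

#' Convert a climate record's age axis to cal BP
#'
#' GICC05 ages are reported b2k (before 2000 CE); radiocarbon calendar ages
#' are cal BP (before 1950 CE), so cal BP = b2k - 50. Records already on
#' cal BP are returned unchanged.
#'
#' @param record A `climate_record`.
#' @return The record on the cal BP datum.
#' @export
to_cal_bp <- function(record) {
  unit <- attr(record, "unit")
  if (is.null(unit)) stop("climate record is missing its age-unit flag")
  if (unit == "calBP") return(record)
  record$age <- record$age - 50
  attr(record, "unit") <- "calBP"
  record
}

#' Centred running mean of a climate record
#'
#' Smooths an annual series with a centred moving average of the given
#' width; at the edges the window is truncated (shrinking mean). The
#' 50-year default reproduces the conventional smoothed ice-core product.
#'
#' @param record An annual `climate_record`.
#' @param width Window width in years (default 50; the window spans
#'   `age +/- width/2`).
#' @return A `climate_record` with the smoothed series.
#' @export
smooth_running_mean <- function(record, width = 50) {
  n <- nrow(record)
  if (width >= diff(range(record$age)) + 1) {
    stop("smoothing width exceeds the record span")
  }
  half <- width / 2
  x <- record$d18o
  age <- record$age
  out <- vapply(seq_len(n), function(i) {
    w <- abs(age - age[i]) <= half
    mean(x[w])
  }, numeric(1))
  record$d18o <- out
  record
}

#' Re-project chronological and measurement uncertainty onto the series
#'
#' Produces an ensemble of probable d18O series: each member evaluates the
#' record under one sampled age-model realisation (a monotone perturbation
#' of the ages consistent with the accumulated counting uncertainty,
#' re-interpolated onto the original age grid) and adds independent
#' measurement noise. The pointwise 2.5/50/97.5 percentiles across members
#' form the uncertainty envelope in the measurement domain.
#'
#' Age-model realisations are built as cumulative sums of independent
#' Gaussian increments whose running variance matches the accumulated
#' `age_sigma` profile, then sorted to enforce monotonicity.
#'
#' @param record An annual `climate_record` with `age_sigma` and/or
#'   `sigma_meas` columns (either may be absent; both absent gives a
#'   degenerate ensemble equal to the input).
#' @param M Number of ensemble members (>= 2).
#' @return A `climate_ensemble`: list with `age` (the record's age axis),
#'   `unit`, `members` (M x n matrix, permil), and `lower95`, `median`,
#'   `upper95` envelopes.
#' @export
reproject_uncertainty <- function(record, M = 200L) {
  if (M < 2L) stop("an envelope needs at least 2 ensemble members")
  n <- nrow(record)
  age <- record$age
  asig <- if ("age_sigma" %in% names(record)) record$age_sigma else numeric(n)
  msig <- if ("sigma_meas" %in% names(record)) record$sigma_meas else numeric(n)
  # order by age so the cumulative scheme runs old->young consistently
  ord <- order(age)
  members <- matrix(NA_real_, nrow = M, ncol = n)
  for (m in seq_len(M)) {
    shift <- age_model_realisation(age[ord], asig[ord])
    pa <- age[ord] + shift
    pa <- sort(pa)  # enforce a monotone age model
    # member value at the original ages, under the perturbed age model
    y <- stats::approx(pa, record$d18o[ord], xout = age[ord], rule = 2)$y
    y <- y + stats::rnorm(n, 0, msig[ord])
    members[m, ord] <- y
  }
  q <- apply(members, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
             names = FALSE)
  structure(
    list(age = age, unit = attr(record, "unit"), members = members,
         lower95 = q[1L, ], median = q[2L, ], upper95 = q[3L, ]),
    class = "climate_ensemble"
  )
}

# One monotone-consistent age-model perturbation: Gaussian increments whose
# cumulative variance tracks the accumulated counting uncertainty profile.
age_model_realisation <- function(age_sorted, asig_sorted) {
  n <- length(age_sorted)
  v <- asig_sorted^2
  dv <- pmax(diff(c(0, v)), 0)
  cumsum(stats::rnorm(n, 0, sqrt(dv)))
}

#' @export
print.climate_ensemble <- function(x, ...) {
  cat("Climate ensemble: ", nrow(x$members), " members x ", length(x$age),
      " samples (", min(x$age), "-", max(x$age), " ", x$unit, ")\n", sep = "")
  invisible(x)
}

#' Align a proxy series onto the analysis grid
#'
#' Linearly interpolates the series onto the grid years and (by default)
#' standardises it to zero mean and unit standard deviation over the
#' window, so regression coefficients are comparable across proxies.
#'
#' @param x A `climate_record`, or a plain numeric series with ages in
#'   `age` (both cal BP).
#' @param grid A `time_grid`.
#' @param age Ages of `x` when `x` is a bare numeric vector.
#' @param standardize Z-score over the window (default `TRUE`).
#' @return Numeric covariate vector, one value per grid year.
#' @export
align_covariate <- function(x, grid, age = NULL, standardize = TRUE) {
  if (inherits(x, "climate_record")) {
    if (attr(x, "unit") != "calBP") stop("convert the record with to_cal_bp() first")
    age <- x$age
    x <- x$d18o
  }
  if (is.null(age)) stop("ages are required to align a bare numeric series")
  yrs <- grid_years(grid)
  if (min(yrs) < min(age) || max(yrs) > max(age)) {
    stop("analysis grid (", min(yrs), "-", max(yrs), " cal BP) extends ",
         "outside the series span (", min(age), "-", max(age), ")")
  }
  v <- stats::approx(age, x, xout = yrs)$y
  if (standardize) v <- standardize_vec(v)
  v
}

standardize_vec <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot standardise a constant covariate")
  (v - mean(v)) / s
}
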