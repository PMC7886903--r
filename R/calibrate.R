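#' Calibrate a conventional radiocarbon age
#'
#' Converts a conventional radiocarbon measurement (age +/- 1-sigma error,
#' 14C yr BP) into a probability mass function over annual calendar years,
#' using a normal measurement-error model against the calibration curve:
#' the unnormalised mass at calendar year t is the normal density of the
#' measured age at mean `c14_mean(t)` and standard deviation
#' `sqrt(c14_error^2 + c14_sigma(t)^2)`. The mass is normalised over the
#' grid and the 98% highest-density region is attached.
#'
#' @param c14_age Conventional radiocarbon age, 14C yr BP (RCYBP).
#' @param c14_error 1-sigma measurement error, 14C yr (> 0).
#' @param curve A [cal_curve] object.
#' @param grid Annual calendar grid (integer years cal BP, descending). If
#'   `NULL`, an annual grid spanning the curve support is used and the
#'   stored density is trimmed to the years that carry all but `1e-10` of
#'   the mass.
#' @param hdr_level Coverage level of the attached highest-density region
#'   (default 0.98).
#' @param record_id Optional identifier carried through to the result.
#' @return A `cal_density` object: list with elements `record_id`, `grid`
#'   (years cal BP, descending), `mass` (sums to 1) and `hdr` (logical mask
#'   of the highest-density region).
#' @examples
#' crv <- cal_curve(cal_bp = c(4800, 5200), c14_mean = c(4800, 5200),
#'                  c14_sigma = c(0, 0))
#' d <- calibrate(5000, 10, crv)
#' d$grid[which.max(d$mass)]  # mode at 5000 cal BP
#' @export
calibrate <- function(c14_age, c14_error, curve, grid = NULL,
                      hdr_level = 0.98, record_id = NA_character_) {
  stopifnot(is.finite(c14_age), c14_age > 0)
  if (!is.finite(c14_error) || c14_error <= 0) {
    stop("c14_error must be finite and > 0")
  }
  trim <- is.null(grid)
  if (trim) {
    grid <- seq(floor(max(curve$cal_bp)), ceiling(min(curve$cal_bp)), by = -1)
  }
  if (is.unsorted(rev(grid), strictly = TRUE)) {
    stop("calendar grid must be strictly descending (oldest first)")
  }
  cv <- curve_at(curve, grid)
  sd_tot <- sqrt(c14_error^2 + cv$c14_sigma^2)
  # work in log space to dodge underflow for ages far from the curve
  logm <- stats::dnorm(c14_age, mean = cv$c14_mean, sd = sd_tot, log = TRUE)
  logm <- logm - max(logm)
  m <- exp(logm)
  tot <- sum(m)
  if (!is.finite(tot) || tot < 1e-300) {
    stop("degenerate calibrated density: no calendar year carries mass for ",
         "c14_age = ", c14_age)
  }
  m <- m / tot
  if (trim) {
    keep <- which(cumsum(m) > 5e-11 & rev(cumsum(rev(m))) > 5e-11)
    if (length(keep) >= 1L) {
      grid <- grid[keep]
      m <- m[keep] / sum(m[keep])
    }
  }
  structure(
    list(record_id = record_id, grid = grid, mass = m,
         hdr = hdr(m, level = hdr_level), hdr_level = hdr_level),
    class = "cal_density"
  )
}

#' Highest-density region of a discrete density
#'
#' Returns the smallest set of bins, chosen in descending order of mass,
#' whose total mass reaches `level`. Ties at the cut-off mass are all
#' included.
#'
#' @param mass Normalised probability masses (must sum to 1 within 1e-6).
#' @param level Coverage level, strictly between 0 and 1.
#' @return Logical mask, `TRUE` for bins inside the region.
#' @export
hdr <- function(mass, level = 0.98) {
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  if (abs(sum(mass) - 1) > 1e-6) {
    stop("hdr() expects a normalised density (|sum - 1| <= 1e-6)")
  }
  if (any(mass < 0)) stop("mass must be non-negative")
  if (level == 1) return(mass > 0)
  ord <- order(mass, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  k <- which(cum >= level - 1e-12)[1L]
  if (is.na(k)) k <- length(mass)
  cut <- mass[ord[k]]
  mass >= cut & mass > 0
}

#' @export
print.cal_density <- function(x, ...) {
  mode_yr <- x$grid[which.max(x$mass)]
  inhdr <- range(x$grid[x$hdr])
  cat("Calibrated density", if (!is.na(x$record_id)) paste0(" [", x$record_id, "]"),
      ": mode ", mode_yr, " cal BP; ", round(100 * x$hdr_level), "% HDR within ",
      inhdr[2L], "-", inhdr[1L], " cal BP (", sum(x$hdr), " yr)\n", sep = "")
  invisible(x)
}

#' Calibrate every row of a radiocarbon date table
#'
#' @param dates A date table as returned by [read_dates()] (columns
#'   `record_id`, `c14_age`, `c14_error`, ...).
#' @inheritParams calibrate
#' @return List of `cal_density` objects, one per row.
#' @export
calibrate_dates <- function(dates, curve, grid = NULL, hdr_level = 0.98) {
  lapply(seq_len(nrow(dates)), function(i) {
    calibrate(dates$c14_age[i], dates$c14_error[i], curve, grid = grid,
              hdr_level = hdr_level, record_id = as.character(dates$record_id[i]))
  })
}
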