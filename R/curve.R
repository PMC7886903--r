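#' Read a radiocarbon calibration curve
#'
#' Reads a calibration curve in the tabular `.14c` dialect: one row per
#' calendar-age knot with at least three columns — calendar age (cal BP),
#' curve radiocarbon age (14C yr BP) and the curve's 1-sigma error (14C yr).
#' Columns may be comma- or whitespace-separated; lines starting with `#`
#' are comments; extra columns are ignored.
#'
#' @param path Path to the curve file.
#' @return A `cal_curve` object: a data frame with columns `cal_bp`,
#'   `c14_mean` and `c14_sigma`, sorted by increasing `cal_bp`.
#' @examples
#' f <- tempfile(fileext = ".14c")
#' writeLines(c("# toy curve", "100,90,5", "200,210,5", "300,310,5"), f)
#' crv <- read_cal_curve(f)
#' crv$cal_bp
#' @export
read_cal_curve <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) < 2L) {
    stop("calibration curve file needs at least 2 data rows: ", path)
  }
  parse_row <- function(i) {
    fields <- strsplit(trimws(lines[i]), "[,\t ]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (length(fields) < 3L || anyNA(vals)) {
      stop("malformed calibration-curve row at line ", lineno[i], ": ",
           lines[i])
    }
    vals
  }
  m <- t(vapply(seq_along(lines), parse_row, numeric(3)))
  if (anyDuplicated(m[, 1L])) {
    dup <- m[duplicated(m[, 1L]), 1L]
    stop("duplicate cal BP knots in calibration curve: ",
         paste(unique(dup), collapse = ", "))
  }
  ord <- order(m[, 1L])
  cal_curve(cal_bp = m[ord, 1L], c14_mean = m[ord, 2L], c14_sigma = m[ord, 3L])
}

#' Construct a calibration curve object
#'
#' @param cal_bp Calendar ages of the knots, years cal BP (strictly monotone).
#' @param c14_mean Curve radiocarbon age at each knot, 14C yr BP.
#' @param c14_sigma Curve 1-sigma error at each knot, 14C yr (all >= 0).
#' @return A `cal_curve` data frame sorted by increasing `cal_bp`.
#' @export
cal_curve <- function(cal_bp, c14_mean, c14_sigma) {
  stopifnot(length(cal_bp) == length(c14_mean),
            length(cal_bp) == length(c14_sigma))
  if (length(cal_bp) < 2L) stop("a calibration curve needs >= 2 knots")
  ord <- order(cal_bp)
  cal_bp <- cal_bp[ord]; c14_mean <- c14_mean[ord]; c14_sigma <- c14_sigma[ord]
  if (any(diff(cal_bp) <= 0)) stop("cal_bp knots must be strictly monotone")
  if (any(!is.finite(cal_bp)) || any(!is.finite(c14_mean)) ||
      any(!is.finite(c14_sigma))) {
    stop("calibration curve values must be finite")
  }
  if (any(c14_sigma < 0)) stop("curve c14_sigma must be >= 0")
  structure(
    data.frame(cal_bp = cal_bp, c14_mean = c14_mean, c14_sigma = c14_sigma),
    class = c("cal_curve", "data.frame")
  )
}

#' @export
print.cal_curve <- function(x, ...) {
  cat("Calibration curve: ", nrow(x), " knots, ",
      min(x$cal_bp), "-", max(x$cal_bp), " cal BP\n", sep = "")
  invisible(x)
}

# Interpolate curve mean and sigma onto arbitrary calendar ages (linear).
curve_at <- function(curve, cal_bp) {
  if (min(cal_bp) < min(curve$cal_bp) || max(cal_bp) > max(curve$cal_bp)) {
    stop("requested calendar ages fall outside the calibration curve support (",
         min(curve$cal_bp), "-", max(curve$cal_bp), " cal BP)")
  }
  list(
    c14_mean = stats::approx(curve$cal_bp, curve$c14_mean, xout = cal_bp)$y,
    c14_sigma = stats::approx(curve$cal_bp, curve$c14_sigma, xout = cal_bp)$y
  )
}
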