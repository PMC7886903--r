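#' Analysis time grid
#'
#' The shared calendar convention of the package: integer years cal BP,
#' stored descending (oldest first), annual by default.
#'
#' @param start_bp Window start (oldest year), cal BP.
#' @param end_bp Window end (youngest year), cal BP; must be < `start_bp`.
#' @param step Years per retained observation (1 = annual).
#' @return A `time_grid` object.
#' @examples
#' g <- time_grid(15000, 11700)
#' length(grid_years(g))
#' @export
time_grid <- function(start_bp, end_bp, step = 1L) {
  step <- as.integer(step)
  if (!(start_bp > end_bp)) stop("start_bp must be > end_bp (cal BP, oldest first)")
  if (step < 1L) stop("step must be a positive integer")
  structure(list(start_bp = start_bp, end_bp = end_bp, step = step),
            class = "time_grid")
}

#' @rdname time_grid
#' @param grid A `time_grid`.
#' @export
grid_years <- function(grid) {
  seq(grid$start_bp, grid$end_bp, by = -grid$step)
}

#' @export
print.time_grid <- function(x, ...) {
  cat("Time grid: ", x$start_bp, "-", x$end_bp, " cal BP, step ", x$step,
      " yr (", length(grid_years(x)), " bins)\n", sep = "")
  invisible(x)
}

#' Sample one probable calendar date from a calibrated density
#'
#' Draws a single year from the highest-density region of the density,
#' with probability proportional to the mass renormalised over that region.
#' This is the elementary step of RECE construction: each ensemble member
#' assigns one probable calendar year to each dated event.
#'
#' @param density A `cal_density` (from [calibrate()]).
#' @param n Number of independent draws.
#' @return Integer vector of years (cal BP), all inside the HDR mask.
#' @export
sample_event_date <- function(density, n = 1L) {
  yrs <- density$grid[density$hdr]
  p <- density$mass[density$hdr]
  if (length(yrs) == 0L) stop("calibrated density has an empty HDR mask")
  if (length(yrs) == 1L) return(rep(yrs, n))
  sample(yrs, size = n, replace = TRUE, prob = p)
}

#' Build a Radiocarbon-dated Event Count Ensemble (RECE)
#'
#' Each ensemble member is one probable annual event-count sequence: a
#' single calendar year is sampled independently from each calibrated
#' density (within its 98% highest-density region, in proportion to the
#' density), and the sampled years are counted per annual bin of the
#' analysis window. Years falling outside the window are dropped from that
#' member. Repeating the sampling M times yields the ensemble.
#'
#' @param densities List of `cal_density` objects.
#' @param M Number of ensemble members (>= 1).
#' @param grid A `time_grid`; must be annual (step 1) at this stage —
#'   decadal thinning is a separate, later step ([thin_rece()]).
#' @param source_label Label recording which record set produced the
#'   ensemble (e.g. "megafauna", "humans").
#' @return A `rece` object: integer matrix with M rows and one column per
#'   grid year (columns named by year), with attributes `grid` and
#'   `source_label`.
#' @export
build_rece <- function(densities, M, grid, source_label = "events") {
  if (M < 1L) stop("M must be >= 1")
  if (grid$step != 1L) stop("RECEs are built on an annual grid; thin afterwards")
  yrs <- grid_years(grid)
  counts <- matrix(0L, nrow = M, ncol = length(yrs),
                   dimnames = list(NULL, as.character(yrs)))
  for (d in densities) {
    draws <- sample_event_date(d, n = M)           # one year per member
    inside <- draws <= grid$start_bp & draws >= grid$end_bp
    if (!any(inside)) next
    j <- grid$start_bp - draws[inside] + 1L        # annual: year -> column
    idx <- cbind(which(inside), j)
    counts[idx] <- counts[idx] + 1L
  }
  new_rece(counts, grid, source_label)
}

#' Wrap a count matrix as a RECE
#'
#' For counts produced outside [build_rece()] (imports, simulations):
#' rows are members, columns are the grid years.
#'
#' @param counts Non-negative integer matrix, M x length(grid years).
#' @param grid A [time_grid()].
#' @param source_label Record-set label.
#' @return A `rece` object.
#' @export
as_rece <- function(counts, grid, source_label = "events") {
  counts <- as.matrix(counts)
  if (ncol(counts) != length(grid_years(grid))) {
    stop("counts must have one column per grid year")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  colnames(counts) <- as.character(grid_years(grid))
  new_rece(counts, grid, source_label)
}

new_rece <- function(counts, grid, source_label) {
  structure(counts, grid = grid, source_label = source_label,
            class = c("rece", "matrix", "array"))
}

#' Thin a RECE in time
#'
#' Retains only every `step`-th annual observation, starting from the
#' window start. Counts are selected, not aggregated: the retained values
#' are the original annual counts at the retained years. The default of 10
#' reproduces the decadal sub-sampling used to keep the hierarchical
#' regression tractable.
#'
#' @param rece A `rece` built on an annual grid.
#' @param step Retain every `step`-th year (default 10).
#' @return A `rece` on the thinned grid.
#' @export
thin_rece <- function(rece, step = 10L) {
  step <- as.integer(step)
  if (step < 1L) stop("step must be >= 1")
  if (step == 1L) return(rece)
  g <- attr(rece, "grid")
  keep <- seq(1L, ncol(rece), by = step)
  yrs <- grid_years(g)[keep]
  g2 <- time_grid(g$start_bp, min(yrs), step = step)
  new_rece(rece[, keep, drop = FALSE], g2, attr(rece, "source_label"))
}

#' @export
print.rece <- function(x, ...) {
  g <- attr(x, "grid")
  cat("RECE [", attr(x, "source_label"), "]: ", nrow(x), " members x ",
      ncol(x), " bins (", g$start_bp, "-", g$end_bp, " cal BP, step ",
      g$step, " yr); mean events/member = ",
      round(mean(rowSums(x)), 2), "\n", sep = "")
  invisible(x)
}

#' Summed probability density function (SPDF)
#'
#' The pointwise sum of the (untruncated) calibrated densities over the
#' grid — the conventional palaeodemographic proxy that the event-count
#' ensemble approach is designed to replace. Provided as a comparison
#' baseline; over an all-covering grid the SPDF integrates to the number
#' of records.
#'
#' @param densities List of `cal_density` objects.
#' @param grid A `time_grid` (annual).
#' @return An `spdf` object: data frame with columns `year` (cal BP) and
#'   `density`.
#' @export
build_spdf <- function(densities, grid) {
  if (grid$step != 1L) stop("SPDFs are built on an annual grid")
  yrs <- grid_years(grid)
  dens <- numeric(length(yrs))
  for (d in densities) {
    inside <- d$grid <= grid$start_bp & d$grid >= grid$end_bp
    if (!any(inside)) next
    j <- grid$start_bp - d$grid[inside] + 1L
    dens[j] <- dens[j] + d$mass[inside]
  }
  structure(data.frame(year = yrs, density = dens),
            class = c("spdf", "data.frame"))
}

#' Export / import a RECE as CSV
#'
#' Rows are ensemble members, columns are grid years (header row of years).
#'
#' @param rece A `rece` object.
#' @param path Output file.
#' @export
write_rece_csv <- function(rece, path) {
  utils::write.csv(as.data.frame(unclass(rece), check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_rece_csv
#' @param source_label Label for the imported ensemble.
#' @export
read_rece_csv <- function(path, source_label = "events") {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  yrs <- as.numeric(colnames(m))
  if (anyNA(yrs)) stop("RECE CSV must have a header row of grid years")
  step <- if (length(yrs) > 1L) as.integer(yrs[1L] - yrs[2L]) else 1L
  g <- time_grid(yrs[1L], yrs[length(yrs)], step = step)
  storage.mode(m) <- "integer"
  new_rece(m, g, source_label)
}
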