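#' Member-agreement heat map of a RECE
#'
#' The ensemble's figure idiom: x is calendar time (ka BP, reversed), y is
#' the per-year event count, and cell intensity is the number of ensemble
#' members showing that count in that year ("agreement"), stretched as
#' `log(1 + agreement)` to enhance contrast, in a magma-style colour map.
#' Summing agreement over counts recovers M in every year. An optional
#' climate ensemble is drawn as a panel above, with its pointwise 95%
#' envelope.
#'
#' @param rece A `rece` object.
#' @param climate Optional `climate_ensemble` for the upper panel.
#' @param max_count Upper y limit (default: observed maximum).
#' @param main Title.
#' @return Invisibly, the agreement matrix (count level x year).
#' @export
plot_rece_heatmap <- function(rece, climate = NULL, max_count = NULL,
                              main = attr(rece, "source_label")) {
  g <- attr(rece, "grid")
  yrs <- grid_years(g)
  M <- nrow(rece)
  cmax <- if (is.null(max_count)) max(rece) else max_count
  agree <- vapply(seq_len(ncol(rece)), function(j) {
    tabulate(rece[, j] + 1L, nbins = cmax + 1L)
  }, integer(cmax + 1L))
  rownames(agree) <- 0:cmax
  colnames(agree) <- yrs

  two <- !is.null(climate)
  if (two) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(0.5, 4, 2, 1))
    on.exit(graphics::par(op))
    ka <- climate$age / 1000
    graphics::plot(ka, climate$median, type = "n", xlim = rev(range(ka)),
                   xaxt = "n", ylab = expression(delta^18 * O ~ "(‰)"),
                   main = main)
    graphics::polygon(c(ka, rev(ka)), c(climate$lower95, rev(climate$upper95)),
                      col = grDevices::adjustcolor("lightblue", 0.6),
                      border = NA)
    graphics::lines(ka, climate$median, col = "white", lwd = 2)
    graphics::lines(ka, climate$median, col = "grey30", lwd = 0.8)
    graphics::par(mar = c(4, 4, 0.5, 1))
    main <- NULL
  }
  z <- log1p(t(agree))                      # years x counts
  graphics::image(x = rev(yrs) / 1000, y = 0:cmax, z = z[rev(seq_len(nrow(z))), ,
                  drop = FALSE],
                  xlim = rev(range(yrs / 1000)),
                  col = grDevices::hcl.colors(64, "Inferno"),
                  xlab = "ka cal BP", ylab = "events per year",
                  main = if (two) NULL else main)
  invisible(agree)
}

#' Plot an SPDF
#'
#' @param x An `spdf` from [build_spdf()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spdf <- function(x, ...) {
  graphics::plot(x$year / 1000, x$density, type = "l",
                 xlim = rev(range(x$year / 1000)),
                 xlab = "ka cal BP", ylab = "summed probability", ...)
  invisible(x)
}
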