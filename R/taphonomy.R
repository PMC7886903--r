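#' Read a tephra-based taphonomic proxy table
#'
#' CSV with header `event_id,age_mean,age_sigma`: dated tephra events whose
#' through-time frequency proxies the taphonomic loss of datable material.
#'
#' @param path CSV file path.
#' @return Data frame with the three required columns.
#' @export
read_tephra <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "age_mean", "age_sigma")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("tephra table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$age_sigma < 0)) stop("tephra age_sigma must be >= 0")
  df
}

#' Build the taphonomic-proxy event count ensemble
#'
#' Tephra event ages carry symmetric Gaussian uncertainty, so each ensemble
#' member samples every event's age from a Normal(age_mean, age_sigma)
#' truncated to its central 98% region (identical to the highest-density
#' region for a symmetric unimodal density), and counts sampled ages per
#' annual bin. The result pairs member-for-member with the response RECE.
#'
#' @param tephra Data frame with columns `age_mean`, `age_sigma` (years BP).
#' @param M Number of members; must match the response ensemble's M at fit
#'   time.
#' @param grid Annual [time_grid()].
#' @param level Central coverage of the truncation region (default 0.98).
#' @return A `rece` object labelled `"taphonomy"`.
#' @export
build_taphonomic_rece <- function(tephra, M, grid, level = 0.98) {
  if (grid$step != 1L) stop("taphonomic RECEs are built on an annual grid")
  yrs <- grid_years(grid)
  counts <- matrix(0L, nrow = M, ncol = length(yrs),
                   dimnames = list(NULL, as.character(yrs)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  for (i in seq_len(nrow(tephra))) {
    mu <- tephra$age_mean[i]; s <- tephra$age_sigma[i]
    if (s == 0) {
      draws <- rep(round(mu), M)
    } else {
      lo <- stats::pnorm(-z); hi <- stats::pnorm(z)
      draws <- round(mu + s * stats::qnorm(stats::runif(M, lo, hi)))
    }
    inside <- draws <= grid$start_bp & draws >= grid$end_bp
    if (!any(inside)) next
    idx <- cbind(which(inside), grid$start_bp - draws[inside] + 1L)
    counts[idx] <- counts[idx] + 1L
  }
  new_rece(counts, grid, "taphonomy")
}
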