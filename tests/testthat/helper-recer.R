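# Shared fixtures, all built in code.

# Identity calibration curve: c14_mean(t) = t, constant curve error.
identity_curve <- function(from = 3000, to = 30000, sigma = 0) {
  cal_curve(cal_bp = c(from, to), c14_mean = c(from, to),
            c14_sigma = c(sigma, sigma))
}

# A point-mass calibrated density at one calendar year.
point_density <- function(year, id = "pt") {
  structure(
    list(record_id = id, grid = year, mass = 1, hdr = TRUE, hdr_level = 0.98),
    class = "cal_density"
  )
}

# Random normalised density on an annual grid (descending years).
random_density <- function(n_bins = 50, start = 10000, id = "rnd") {
  m <- stats::rexp(n_bins)
  m <- m / sum(m)
  structure(
    list(record_id = id, grid = seq(start, by = -1, length.out = n_bins),
         mass = m, hdr = hdr(m, 0.98), hdr_level = 0.98),
    class = "cal_density"
  )
}

# Independent HDR oracle: grow the region one bin at a time in descending
# mass order until the level is reached, then pull in ties at the cut.
hdr_oracle <- function(mass, level) {
  sel <- logical(length(mass))
  remaining <- which(mass > 0)
  tot <- 0
  while (tot < level - 1e-12 && length(remaining)) {
    i <- remaining[which.max(mass[remaining])]
    sel[i] <- TRUE
    tot <- tot + mass[i]
    remaining <- remaining[remaining != i]
  }
  cut <- min(mass[sel])
  sel | (mass == cut & mass > 0)
}

# Tiny date table for IO tests.
toy_dates <- function(n = 6, c14_age = 12000, c14_error = 50) {
  data.frame(
    record_id = sprintf("T-%02d", seq_len(n)),
    taxon = rep(c("Equus sp.", "Mammuthus sp.", "Smilodon fatalis"),
                length.out = n),
    site = "toy", region = rep(c("Great Lakes", "Southwest"), length.out = n),
    c14_age = c14_age, c14_error = c14_error, cleaned_flag = TRUE,
    stringsAsFactors = FALSE
  )
}
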