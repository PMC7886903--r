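#' Read a radiocarbon date table
#'
#' Reads a CSV with header
#' `record_id,taxon,site,region,c14_age,c14_error,cleaned_flag`, validates
#' rows, and optionally applies the chronological-cleaning filter (keeping
#' only rows whose `cleaned_flag` is true — the records that survive the
#' duplicate-date adjudication). Rows with non-positive or missing
#' `c14_error`/`c14_age` are excluded and reported, never silently coerced.
#'
#' @param path CSV file path.
#' @param apply_cleaned_filter If `TRUE`, retain only `cleaned_flag == TRUE`
#'   rows.
#' @param quiet Suppress the retained/dropped message.
#' @return A `date_table` data frame; attributes `provenance` (source file),
#'   `n_input`, `n_excluded` record the read-back accounting.
#' @export
read_dates <- function(path, apply_cleaned_filter = FALSE, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "taxon", "site", "region", "c14_age", "c14_error",
            "cleaned_flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("date table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  n_input <- nrow(df)
  df$cleaned_flag <- as.logical(df$cleaned_flag)
  bad <- !is.finite(df$c14_age) | df$c14_age <= 0 |
    !is.finite(df$c14_error) | df$c14_error <= 0 | is.na(df$cleaned_flag)
  if (any(bad) && !quiet) {
    message(sum(bad), " malformed row(s) excluded from ", basename(path))
  }
  df <- df[!bad, , drop = FALSE]
  if (apply_cleaned_filter) {
    kept <- df$cleaned_flag
    if (!quiet) {
      message("cleaned filter: ", sum(kept), " retained, ", sum(!kept),
              " dropped")
    }
    df <- df[kept, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, provenance = path, n_input = n_input,
            n_excluded = sum(bad),
            class = c("date_table", "data.frame"))
}

# Controlled vocabulary: genus-level, case-insensitive matching.
taxon_vocab <- c(all = "all", equus = "Equus", mammuthus = "Mammuthus",
                 mammut = "Mammut", nothrotheriops = "Nothrotheriops",
                 smilodon = "Smilodon")

#' Subset a date table by taxon and/or region
#'
#' Taxon matching is case-insensitive at genus level (`"Equus"` matches
#' `"Equus sp."`). Region matching is case-insensitive on the full label.
#' The five supported taxa are horse (Equus), mammoth (Mammuthus), mastodon
#' (Mammut), Shasta's ground sloth (Nothrotheriops) and saber-tooth cat
#' (Smilodon); `"all"` disables the respective filter.
#'
#' @param dates A `date_table` from [read_dates()].
#' @param taxon Taxon label or `"all"`.
#' @param region Region label or `"all"`.
#' @return Filtered `date_table`.
#' @export
subset_dates <- function(dates, taxon = "all", region = "all") {
  key <- tolower(taxon)
  if (!key %in% names(taxon_vocab)) {
    stop("unknown taxon '", taxon, "'; valid labels: ",
         paste(unname(taxon_vocab), collapse = ", "))
  }
  out <- dates
  if (key != "all") {
    genus <- vapply(strsplit(tolower(out$taxon), "[ _]"), `[`, "", 1L)
    out <- out[genus == key, , drop = FALSE]
  }
  if (tolower(region) != "all") {
    out <- out[tolower(out$region) == tolower(region), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a radiocarbon date table
#'
#' @param dates Data frame with the date-table columns.
#' @param path Output CSV path.
#' @export
write_dates <- function(dates, path) {
  utils::write.csv(as.data.frame(dates), path, row.names = FALSE)
  invisible(path)
}

#' Write a calibration curve in the tabular .14c dialect
#'
#' @param curve A [cal_curve].
#' @param path Output path.
#' @export
write_cal_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cal BP, 14C age BP, sigma", con)
  writeLines(sprintf("%s,%s,%s", curve$cal_bp, curve$c14_mean,
                     curve$c14_sigma), con)
  invisible(path)
}
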