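#' Fit one model family to a synthetic scenario
#'
#' Convenience wrapper running the full pipeline on a [make_scenario()]
#' bundle: calibrate the dates, build and thin the response and covariate
#' ensembles, smooth the climate record, and fit the hierarchical
#' regression. The taphonomic proxy is included as a control covariate in
#' every family.
#'
#' @param sc A scenario bundle from [make_scenario()].
#' @param family `"humans_only"`, `"climate_only"` or `"mixed"`.
#' @param M Ensemble size (default: the scenario's).
#' @param thin_step Temporal thinning step in years (default 10).
#' @param use_climate_ensemble Propagate climate chronological/measurement
#'   uncertainty by feeding a member-paired [reproject_uncertainty()]
#'   ensemble instead of the smoothed record (the extended-analysis mode).
#' @param smooth_width Running-mean width for the climate covariate, years.
#' @param ... Passed to [recm()] (iterations, warmup, chains, priors,
#'   seed, ...).
#' @return A fitted [recm()] object.
#' @export
fit_scenario <- function(sc, family = c("mixed", "humans_only", "climate_only"),
                         M = sc$truth$M, thin_step = 10,
                         use_climate_ensemble = FALSE, smooth_width = 50,
                         ...) {
  family <- match.arg(family)
  window <- sc$truth$window
  dens <- calibrate_dates(sc$megafauna[sc$megafauna$cleaned_flag, ], sc$curve)
  response <- thin_rece(build_rece(dens, M, window, "megafauna"), thin_step)
  covs <- list()
  if (family %in% c("humans_only", "mixed")) {
    hdens <- calibrate_dates(sc$humans, sc$curve)
    covs$humans <- thin_rece(build_rece(hdens, M, window, "humans"), thin_step)
  }
  if (family %in% c("climate_only", "mixed")) {
    covs$climate <- if (use_climate_ensemble) {
      reproject_uncertainty(sc$climate, M = M)
    } else {
      smooth_running_mean(sc$climate, smooth_width)
    }
  }
  covs$taphonomy <- thin_rece(
    build_taphonomic_rece(sc$tephra, M, window), thin_step)
  recm(response, covs, ...)
}

#' Run the full multi-model analysis suite
#'
#' For every requested (taxon, region) subset of the megafauna date table,
#' fits the requested model families — `humans_only` (human event-count
#' proxy), `climate_only` (ice-core proxy) and `mixed` (both) — always
#' controlling for the taphonomic proxy when a tephra table is supplied,
#' and collects the top-level posterior summaries and credible-region
#' decisions into one results table.
#'
#' @param megafauna A `date_table` ([read_dates()]): the response records.
#' @param humans Optional `date_table` of anthropogenic dates.
#' @param climate Optional `climate_record` (cal BP) or `climate_ensemble`.
#' @param tephra Optional tephra table ([read_tephra()]).
#' @param curve A [cal_curve].
#' @param taxa,regions Character vectors of subset labels (`"all"` for no
#'   filter); every taxon x region combination is analysed.
#' @param families Model families to fit per subset.
#' @param window Analysis window ([time_grid()], annual).
#' @param M Ensemble size (50 reproduces the study configuration).
#' @param thin_step Temporal thinning, years (10 = decadal).
#' @param smooth_width Climate running-mean width, years (ignored for
#'   ensembles).
#' @param min_records Subsets with fewer records are flagged `skipped`
#'   rather than fitted.
#' @param ... Passed to [recm()].
#' @return Data frame with one row per (subset, family, covariate):
#'   `taxon`, `region`, `model_family`, `covariate`, `hyper_mean`,
#'   `ci_low`, `ci_high`, `decision`, `rhat_max`, `ess_min`, `n_records`.
#' @export
run_analysis_suite <- function(megafauna, humans = NULL, climate = NULL,
                               tephra = NULL, curve,
                               taxa = "all", regions = "all",
                               families = c("humans_only", "climate_only",
                                            "mixed"),
                               window = time_grid(15000, 11700),
                               M = 50, thin_step = 10, smooth_width = 50,
                               min_records = 5, ...) {
  families <- match.arg(families, c("humans_only", "climate_only", "mixed"),
                        several.ok = TRUE)
  need_humans <- any(families %in% c("humans_only", "mixed"))
  need_climate <- any(families %in% c("climate_only", "mixed"))
  if (need_humans && is.null(humans)) stop("these families need a human date table")
  if (need_climate && is.null(climate)) stop("these families need a climate record")

  shared <- list()
  if (need_humans) {
    hdens <- calibrate_dates(humans, curve)
    shared$humans <- thin_rece(build_rece(hdens, M, window, "humans"),
                               thin_step)
  }
  if (need_climate) {
    shared$climate <- if (inherits(climate, "climate_ensemble")) climate
                      else smooth_running_mean(to_cal_bp(climate), smooth_width)
  }
  if (!is.null(tephra)) {
    shared$taphonomy <- thin_rece(build_taphonomic_rece(tephra, M, window),
                                  thin_step)
  }

  rows <- list()
  for (tx in taxa) for (rg in regions) {
    sub <- subset_dates(megafauna, taxon = tx, region = rg)
    label <- list(taxon = tx, region = rg)
    if (nrow(sub) < min_records) {
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, region = rg, model_family = families, covariate = NA,
        hyper_mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        decision = "skipped", rhat_max = NA_real_, ess_min = NA_real_,
        n_records = nrow(sub))
      next
    }
    dens <- calibrate_dates(sub, curve)
    response <- thin_rece(build_rece(dens, M, window, "megafauna"), thin_step)
    for (fam in families) {
      covs <- switch(fam,
        humans_only = shared[intersect(c("humans", "taphonomy"), names(shared))],
        climate_only = shared[intersect(c("climate", "taphonomy"), names(shared))],
        mixed = shared)
      fit <- recm(response, covs, ...)
      for (cv in fit$covariates) {
        s <- significance(fit, cv)
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = tx, region = rg, model_family = fam, covariate = cv,
          hyper_mean = s$mean, ci_low = s$interval[1L],
          ci_high = s$interval[2L], decision = s$decision,
          rhat_max = fit$diagnostics$rhat_max,
          ess_min = fit$diagnostics$ess_min, n_records = nrow(sub))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
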