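#' @export
print.recm <- function(x, ...) {
  cat("Hierarchical NB event-count regression (", x$M, " ensemble members, ",
      x$n_obs, " retained years)\n", sep = "")
  cat("Covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(intercept only)", "\n")
  cat("Top-level coefficient means (posterior mean [95% CrI]):\n")
  ci <- stats::confint(x)
  pm <- colMeans(x$hyper_mean)
  for (k in seq_along(pm)) {
    cat(sprintf("  %-16s %8.4f [%8.4f, %8.4f]\n", names(pm)[k], pm[k],
                ci[k, 1L], ci[k, 2L]))
  }
  if (!is.null(x$config$dispersion)) {
    cat("Dispersion phi fixed at", x$config$dispersion, "\n")
  } else {
    cat(sprintf("Dispersion phi: %.3f\n", mean(x$phi)))
  }
  d <- x$diagnostics
  cat(sprintf("Max split R-hat %.3f; min ESS %.0f%s\n", d$rhat_max, d$ess_min,
              if (d$converged) "" else "  ** convergence flagged **"))
  invisible(x)
}

#' Summarise a fitted event-count regression
#'
#' @param object A fitted [recm()] object.
#' @param level Credible level for the equal-tailed intervals.
#' @param ... Unused.
#' @return A `summary.recm` object: a data frame with posterior mean, sd,
#'   interval, split R-hat and ESS per top-level parameter, plus the
#'   significance decision for every covariate hyper-mean (the intercept
#'   carries no substantive interpretation and is never tested).
#' @export
summary.recm <- function(object, level = 0.95, ...) {
  draws <- cbind(object$hyper_mean, object$hyper_sd)
  if (is.null(object$config$dispersion)) draws <- cbind(draws, phi = object$phi)
  a <- (1 - level) / 2
  tab <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2L, stats::sd),
    ci_low = apply(draws, 2L, stats::quantile, probs = a, names = FALSE),
    ci_high = apply(draws, 2L, stats::quantile, probs = 1 - a, names = FALSE),
    rhat = object$diagnostics$rhat[colnames(draws)],
    ess = object$diagnostics$ess[colnames(draws)],
    row.names = NULL
  )
  decision <- rep(NA_character_, nrow(tab))
  for (cv in object$covariates) {
    i <- match(paste0("beta_", cv), tab$parameter)
    decision[i] <- significance(object, cv, level = level)$decision
  }
  tab$decision <- decision
  structure(list(table = tab, level = level, M = object$M,
                 covariates = object$covariates),
            class = "summary.recm")
}

#' @export
print.summary.recm <- function(x, ...) {
  cat("Top-level posterior summary (", x$M, " members, ",
      round(100 * x$level), "% equal-tailed intervals):\n", sep = "")
  tab <- x$table
  tab$mean <- round(tab$mean, 4); tab$sd <- round(tab$sd, 4)
  tab$ci_low <- round(tab$ci_low, 4); tab$ci_high <- round(tab$ci_high, 4)
  tab$rhat <- round(tab$rhat, 3); tab$ess <- round(tab$ess)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.recm <- function(object, ...) {
  colMeans(object$hyper_mean)
}

#' @export
confint.recm <- function(object, parm, level = 0.95, ...) {
  a <- (1 - level) / 2
  ci <- t(apply(object$hyper_mean, 2L, stats::quantile, probs = c(a, 1 - a),
                names = FALSE))
  colnames(ci) <- paste0(100 * c(a, 1 - a), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Credible-region significance decision for a covariate
#'
#' A covariate is deemed important when the equal-tailed 95% credible
#' interval of its top-level hyper-mean excludes zero; the decision sign
#' follows the interval.
#'
#' @param fit A fitted [recm()] object.
#' @param covariate Covariate name (as given in the fit's covariate list).
#' @param level Credible level (default 0.95).
#' @return List with `decision` (`"significant_positive"`,
#'   `"significant_negative"` or `"not_significant"`), `interval` and
#'   `mean`.
#' @export
significance <- function(fit, covariate, level = 0.95) {
  stopifnot(inherits(fit, "recm"))
  par <- paste0("beta_", covariate)
  if (!par %in% colnames(fit$hyper_mean)) {
    stop("unknown covariate '", covariate, "'; fitted covariates: ",
         paste(fit$covariates, collapse = ", "))
  }
  draws <- fit$hyper_mean[, par]
  a <- (1 - level) / 2
  ci <- stats::quantile(draws, probs = c(a, 1 - a), names = FALSE)
  decision <- if (ci[1L] > 0) "significant_positive"
              else if (ci[2L] < 0) "significant_negative"
              else "not_significant"
  list(decision = decision, interval = ci, mean = mean(draws), level = level)
}

#' Posterior-predictive simulation of count sequences
#'
#' Draws new member count sequences from the fitted model: for each
#' simulation one posterior draw is selected and counts are generated from
#' the negative-binomial observation model for every member and retained
#' year using that draw's member-level coefficients and dispersion.
#'
#' @param object A fitted [recm()] object.
#' @param nsim Number of posterior-predictive replicates.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` integer matrices (M x retained years).
#' @export
simulate.recm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(object$hyper_mean)
  M <- object$M; Tn <- object$n_obs
  X <- object$design$X; memb <- object$design$member
  P <- length(object$parameters)
  lapply(seq_len(nsim), function(s) {
    i <- sample.int(S, 1L)
    bmat <- matrix(object$member[i, ], nrow = M)       # M x P
    eta <- rowSums(X * bmat[memb, , drop = FALSE])
    phi <- if (is.null(object$config$dispersion)) object$phi[i]
           else object$config$dispersion
    matrix(stats::rnbinom(length(eta), mu = exp(eta), size = phi),
           nrow = M, byrow = TRUE)
  })
}

#' @export
fitted.recm <- function(object, ...) {
  M <- object$M
  bmat <- matrix(colMeans(object$member), nrow = M)
  eta <- rowSums(object$design$X * bmat[object$design$member, , drop = FALSE])
  matrix(exp(eta), nrow = M, byrow = TRUE)
}

#' @export
residuals.recm <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  yy <- matrix(object$design$y, nrow = object$M, byrow = TRUE)
  r <- yy - mu
  if (type == "pearson") {
    phi <- if (is.null(object$config$dispersion)) mean(object$phi)
           else object$config$dispersion
    r <- r / sqrt(mu + mu^2 / phi)
  }
  r
}

#' Plot posterior densities of the top-level coefficients
#'
#' One panel per top-level hyper-mean (the figure idiom of the study:
#' posterior density with a vertical reference line at zero, which a
#' covariate must exclude at the 95% level to be deemed important).
#'
#' @param x A fitted [recm()] object.
#' @param parameters Which hyper-means to show (default: all).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.recm <- function(x, parameters = x$parameters, ...) {
  op <- graphics::par(mfrow = c(1, length(parameters)),
                      mar = c(4, 3, 3, 1))
  on.exit(graphics::par(op))
  for (p in parameters) {
    d <- stats::density(x$hyper_mean[, p])
    graphics::plot(d, main = p, xlab = "coefficient (standardized units)",
                   ylab = "", ...)
    graphics::abline(v = 0, col = "grey40", lwd = 2)
    graphics::polygon(d, col = grDevices::adjustcolor("steelblue", 0.4),
                      border = "steelblue")
  }
  invisible(x)
}
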