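sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) return(0)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}

qq_frame <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  data.frame(theoretical = stats::qnorm(stats::ppoints(n)), sample = x)
}

#' Assumption diagnostics for a fitted agreement model
#'
#' Extracts the empirical best linear unbiased predictors (BLUPs) of every
#' random effect and the residuals from a REML fit, and assembles the data
#' behind the standard assumption checks: normal Q-Q data per random-effect
#' vector and for the residuals, residual-vs-fitted and standardized
#' residual-vs-fitted pairs, and a coarse skewness flag (|sample skewness|
#' > 1) per vector.  These support the usual checks for mixed-model
#' agreement analyses: normality of random effects and errors, constant
#' variability and fixed bias across the measurement range.
#'
#' @param fit a `full_model_fit`, `diff_model_fit` (its differences model is
#'   used) or `reml_fit` with an lme4 backend.
#' @return Object of class `diagnostics_bundle`: `qq` (named list of Q-Q
#'   data.frames), `residual_vs_fitted`, `std_residual_vs_fitted`,
#'   `skew` (named skewness values), `flags` (named logicals).
#' @export
model_diagnostics <- function(fit) {
  rf <- if (inherits(fit, "full_model_fit")) {
    fit$reml
  } else if (inherits(fit, "diff_model_fit")) {
    fit$reml$diff_model
  } else if (inherits(fit, "reml_fit")) {
    fit
  } else {
    ag_argument_error("unsupported fit object")
  }
  if (is.null(rf$fit)) {
    ag_argument_error(
      "diagnostics need a data-backed lme4 fit (not a constructed one)")
  }
  m <- rf$fit
  res <- stats::residuals(m)
  fitted_ <- stats::fitted(m)
  sdr <- stats::sd(res)
  std <- if (sdr > 0) (res - mean(res)) / sdr else res * 0
  re <- lme4::ranef(m)
  qq <- c(lapply(re, function(df) qq_frame(df[[1L]])),
          list(residuals = qq_frame(res)))
  vecs <- c(lapply(re, function(df) df[[1L]]), list(residuals = res))
  skew <- vapply(vecs, sample_skewness, numeric(1))
  structure(list(
    qq = qq,
    residual_vs_fitted = data.frame(fitted = fitted_, residual = res),
    std_residual_vs_fitted = data.frame(fitted = fitted_, residual = std),
    skew = skew,
    flags = abs(skew) > 1
  ), class = "diagnostics_bundle")
}

#' @export
print.diagnostics_bundle <- function(x, ...) {
  cat("Model diagnostics\n  skewness by component:\n")
  print(round(x$skew, 3))
  if (any(x$flags)) {
    cat("  flagged (|skew| > 1):", paste(names(x$flags)[x$flags],
                                         collapse = ", "), "\n")
  } else {
    cat("  no skewness flags\n")
  }
  invisible(x)
}

#' Bland-Altman plot specification
#'
#' Assembles the data behind a Bland-Altman plot -- paired differences
#' against pair averages, with the mean-bias line, limits-of-agreement
#' lines, optional bootstrap CI lines, and optional clinically-acceptable-
#' difference lines at \eqn{\pm\delta}.  The specification is a plain,
#' JSON-serializable object; rendering (see [plot.bland_altman_spec()]) is
#' best-effort and optional, so headless pipelines can still produce and
#' test the numbers.
#'
#' @param pairs a [pair_differences()] table.
#' @param report optional `agreement_report` supplying the bias/LoA lines
#'   (its primary LoA is used); if NULL the naive mean and SD limits are
#'   drawn from the pairs themselves.
#' @param settings optional [agreement_settings()] for the CAD lines.
#' @param ci optional list with elements `bias`, `lower`, `upper`, each a
#'   length-2 numeric CI, drawn as extra dotted lines.
#' @return Object of class `bland_altman_spec`.
#' @export
bland_altman <- function(pairs, report = NULL, settings = NULL, ci = NULL) {
  stopifnot(inherits(pairs, "paired_differences"))
  if (nrow(pairs) == 0L) ag_data_error("no pairs to plot")
  if (!is.null(report)) {
    loa <- report$indices$loa
    bias <- loa$bias; lower <- loa$lower; upper <- loa$upper
    source <- loa$source
    if (is.null(settings)) settings <- report$settings
  } else {
    m <- 1.96
    bias <- mean(pairs$diff)
    s <- stats::sd(pairs$diff)
    if (is.na(s)) s <- 0
    lower <- bias - m * s; upper <- bias + m * s
    source <- "naive"
  }
  structure(list(
    points = data.frame(avg = pairs$avg, diff = pairs$diff),
    bias = bias, loa_lower = lower, loa_upper = upper, loa_source = source,
    cad = if (!is.null(settings)) settings$cad_delta else NULL,
    ci = ci
  ), class = "bland_altman_spec")
}

#' Serialize a Bland-Altman specification to JSON
#' @param spec a `bland_altman_spec`.
#' @export
ba_to_json <- function(spec) {
  stopifnot(inherits(spec, "bland_altman_spec"))
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, digits = NA,
                   null = "null", dataframe = "columns")
}

#' Render a Bland-Altman plot
#'
#' @param x a `bland_altman_spec`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman_spec <- function(x, ...) {
  ylim <- range(c(x$points$diff, x$loa_lower, x$loa_upper,
                  if (!is.null(x$cad)) c(-x$cad, x$cad)), na.rm = TRUE)
  graphics::plot(x$points$avg, x$points$diff, xlab = "Average of pair",
                 ylab = "Difference (test - reference)", ylim = ylim, ...)
  graphics::abline(h = x$bias, col = "red", lty = 2)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), col = "blue", lty = 2)
  if (!is.null(x$cad)) {
    graphics::abline(h = c(-x$cad, x$cad), col = "darkgreen", lty = 1)
  }
  if (!is.null(x$ci)) {
    for (ln in x$ci) graphics::abline(h = ln, col = "grey40", lty = 3)
  }
  invisible(x)
}
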