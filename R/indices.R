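#' Agreement analysis settings
#'
#' Bundles the decision parameters of an agreement analysis.
#'
#' @param cad_delta clinically acceptable difference half-width
#'   \eqn{\delta > 0}, in measurement units.  Differences within
#'   \eqn{\pm\delta} are considered practically negligible.
#' @param tdi_p containment probability for the TDI, default 0.95.
#' @param cp_threshold coverage-probability threshold for the "agree"
#'   verdict, default 0.95.
#' @param cia_threshold CIA threshold for "acceptable" agreement,
#'   default 0.8.
#' @param loa_multiplier multiplier for the limits of agreement, default
#'   1.96 (95% limits).
#' @param ccc_threshold optional CCC threshold; the CCC is reported without
#'   verdict unless one is supplied (what value constitutes agreement must be
#'   agreed beforehand by the investigators).
#' @export
agreement_settings <- function(cad_delta, tdi_p = 0.95, cp_threshold = 0.95,
                               cia_threshold = 0.8, loa_multiplier = 1.96,
                               ccc_threshold = NULL) {
  if (!is.numeric(cad_delta) || cad_delta <= 0) {
    ag_argument_error("cad_delta must be a positive number")
  }
  if (tdi_p <= 0 || tdi_p >= 1) ag_argument_error("tdi_p must be in (0,1)")
  if (cp_threshold <= 0 || cp_threshold > 1) {
    ag_argument_error("cp_threshold must be in (0,1]")
  }
  if (cia_threshold <= 0 || cia_threshold > 1) {
    ag_argument_error("cia_threshold must be in (0,1]")
  }
  structure(list(cad_delta = cad_delta, tdi_p = tdi_p,
                 cp_threshold = cp_threshold, cia_threshold = cia_threshold,
                 loa_multiplier = loa_multiplier,
                 ccc_threshold = ccc_threshold),
            class = "agreement_settings")
}

# phi_beta^2 = sum_j beta_j^2; under sum-to-zero coding this is diff^2/2.
phi_beta_sq <- function(fit) fit$device_diff^2 / 2

#' Concordance correlation coefficient for repeated measures
#'
#' Under the full crossed model with a fixed device effect, the CCC for
#' repeated measurements coincides with an intraclass correlation:
#' \deqn{\rho_{CCC} = \frac{\sigma_\alpha^2 + \sigma_\gamma^2 +
#'   \sigma_{\alpha\gamma}^2}{\sigma_\alpha^2 + \phi_\beta^2 +
#'   \sigma_\gamma^2 + \sigma_{\alpha\gamma}^2 + \sigma_{\alpha\beta}^2 +
#'   \sigma_{\beta\gamma}^2 + \sigma_\epsilon^2}}
#' where \eqn{\phi_\beta^2 = \sum_j \beta_j^2} is the variance attributable
#' to the fixed device effect.
#'
#' @param fit a `full_model_fit`.
#' @return scalar in \[0, 1\].
#' @export
ccc_repeated <- function(fit) {
  stopifnot(inherits(fit, "full_model_fit"))
  if (!fit$converged) warning("fit did not converge; CCC may be unreliable")
  num <- fit$var_subject + fit$var_activity + fit$var_subject_activity
  den <- num + phi_beta_sq(fit) + fit$var_subject_device +
    fit$var_device_activity + fit$var_resid
  if (den <= 0) {
    ag_argument_error(
      "total variance is zero: CCC undefined (no variability in the data)")
  }
  num / den
}

#' Mean squared deviation between devices
#'
#' Expected squared difference between time-matched readings by the two
#' devices on the same subject under the same activity:
#' \deqn{MSD = (\beta_1 - \beta_2)^2 + 2(\sigma_{\alpha\beta}^2 +
#'   \sigma_{\beta\gamma}^2 + \sigma_\epsilon^2)}
#'
#' @param fit a `full_model_fit`.
#' @return non-negative scalar in squared measurement units.
#' @export
msd <- function(fit) {
  stopifnot(inherits(fit, "full_model_fit"))
  fit$device_diff^2 +
    2 * (fit$var_subject_device + fit$var_device_activity + fit$var_resid)
}

#' Coverage probability of the clinically acceptable difference
#'
#' Probability that a between-device difference falls within \eqn{\pm\delta},
#' under normality of the differences:
#' \deqn{CP(\delta) = 1 - 2\{1 - \Phi(\delta/\sqrt{MSD})\}}
#'
#' @param msd_value mean squared deviation (>= 0), or a `full_model_fit`
#'   from which it is computed.
#' @param delta clinically acceptable difference half-width (> 0).
#' @return probability in \[0, 1\]; an MSD of zero gives 1.
#' @export
coverage_probability <- function(msd_value, delta) {
  if (inherits(msd_value, "full_model_fit")) msd_value <- msd(msd_value)
  if (!is.numeric(msd_value) || msd_value < 0) {
    ag_argument_error("msd_value must be a non-negative number")
  }
  if (!is.numeric(delta) || delta <= 0) {
    ag_argument_error("delta must be a positive number")
  }
  if (msd_value == 0) return(1)
  1 - 2 * (1 - stats::pnorm(delta / sqrt(msd_value)))
}

#' Total deviation index
#'
#' The half-width within which a proportion `p` of between-device differences
#' is expected to fall:
#' \deqn{TDI(p) = \Phi^{-1}((1+p)/2)\,\sqrt{MSD}}
#' TDI and CP are inverses of one another:
#' `coverage_probability(msd, tdi(msd, p)) == p`.
#'
#' @param msd_value mean squared deviation (>= 0), or a `full_model_fit`.
#' @param p containment probability in (0, 1), default 0.95.
#' @return non-negative scalar in measurement units.
#' @export
tdi <- function(msd_value, p = 0.95) {
  if (inherits(msd_value, "full_model_fit")) msd_value <- msd(msd_value)
  if (!is.numeric(msd_value) || msd_value < 0) {
    ag_argument_error("msd_value must be a non-negative number")
  }
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    ag_argument_error("p must be in (0, 1)")
  }
  stats::qnorm((1 + p) / 2) * sqrt(msd_value)
}

#' Coefficient of individual agreement
#'
#' Ratio of the within-device replication disagreement to the between-device
#' disagreement, both measured as mean squared deviations:
#' \deqn{CIA = \frac{2\sigma_\epsilon^2}{(\beta_1-\beta_2)^2 +
#'   2(\sigma_{\alpha\beta}^2 + \sigma_{\beta\gamma}^2 + \sigma_\epsilon^2)}}
#' A CIA of 1 means switching device adds no variability beyond replication
#' error.  Requires \eqn{\sigma_\epsilon^2 > 0}: with no replication error
#' the within-device benchmark is degenerate and the CIA is undefined.
#'
#' @param fit a `full_model_fit`.
#' @return scalar in (0, 1\].
#' @export
cia <- function(fit) {
  stopifnot(inherits(fit, "full_model_fit"))
  if (fit$var_resid <= 0) {
    ag_argument_error(paste0(
      "residual variance is zero: the within-device replication benchmark ",
      "is degenerate, so the CIA is undefined"))
  }
  2 * fit$var_resid / msd(fit)
}

#' Repeatability coefficient
#'
#' \eqn{1.96\sqrt{2\sigma_\epsilon^2}}: the half-width within which two
#' replicate readings by the same device on the same subject under the same
#' conditions are expected to fall about 95% of the time.  Used as a sanity
#' check that the replication-error benchmark underlying the CIA is
#' acceptable.
#'
#' @param fit a `full_model_fit`.
#' @param multiplier normal quantile multiplier, default 1.96.
#' @return non-negative scalar in measurement units.
#' @export
repeatability_coefficient <- function(fit, multiplier = 1.96) {
  stopifnot(inherits(fit, "full_model_fit"))
  multiplier * sqrt(2 * fit$var_resid)
}

loa_triplet <- function(bias, sd, multiplier, source) {
  structure(list(bias = bias, lower = bias - multiplier * sd,
                 upper = bias + multiplier * sd, sd = sd,
                 multiplier = multiplier, source = source),
            class = "loa")
}

#' @export
print.loa <- function(x, ...) {
  cat(sprintf("Limits of agreement [%s]: bias %.3f (%.0f%% LoA %.3f to %.3f)\n",
              x$source, x$bias, 100 * 2 * (stats::pnorm(x$multiplier) - 0.5),
              x$lower, x$upper))
  invisible(x)
}

#' Mixed-effects limits of agreement from the differences model
#'
#' \deqn{\mu_0^* \pm m\sqrt{\sigma_{\alpha^*}^2 + \sigma_{\gamma^*}^2 +
#'   \sigma_{\epsilon^*}^2}}
#' The bias is the intercept of the bias-only model (weighted mean bias); the
#' spread comes from the variance components of the differences model.  This
#' is the primary LoA estimate: normality is more plausible for differences
#' than for raw readings.
#'
#' @param diff_fit a `diff_model_fit`.
#' @param multiplier LoA multiplier, default 1.96.
#' @return list with `bias`, `lower`, `upper` (class `loa`).
#' @export
loa_from_diff_model <- function(diff_fit, multiplier = 1.96) {
  stopifnot(inherits(diff_fit, "diff_model_fit"))
  sd <- sqrt(diff_fit$var_subject_star + diff_fit$var_activity_star +
               diff_fit$var_resid_star)
  loa_triplet(diff_fit$mu0_star, sd, multiplier, "diff_model")
}

#' Mixed-effects limits of agreement from the full model
#'
#' The paired difference implied by the full model has mean
#' \eqn{\beta_2 - \beta_1} and variance
#' \eqn{2\sigma_{\alpha\beta}^2 + 2\sigma_{\beta\gamma}^2 +
#'   2\sigma_\epsilon^2}, giving
#' \deqn{\beta_2 - \beta_1 \pm m\sqrt{2\sigma_{\alpha\beta}^2 +
#'   2\sigma_{\beta\gamma}^2 + 2\sigma_\epsilon^2}}
#'
#' @param fit a `full_model_fit`.
#' @param multiplier LoA multiplier, default 1.96.
#' @return list with `bias`, `lower`, `upper` (class `loa`).
#' @export
loa_from_full_model <- function(fit, multiplier = 1.96) {
  stopifnot(inherits(fit, "full_model_fit"))
  sd <- sqrt(2 * (fit$var_subject_device + fit$var_device_activity +
                    fit$var_resid))
  loa_triplet(fit$device_diff, sd, multiplier, "full_model")
}

#' Naive (clustering-ignorant) agreement indices
#'
#' Quick summaries that treat every time-matched pair as independent:
#' Pearson's correlation of the paired readings, Lin's concordance
#' correlation coefficient
#' \eqn{2 s_{12} / (s_1^2 + s_2^2 + (\bar y_1 - \bar y_2)^2)}
#' (1/n moment estimators, as in Lin's original proposal), and simple limits
#' of agreement `mean(diff) +/- m * sd(diff)`.  With clustered repeated
#' measures these indices are biased -- the simple LoA in particular are too
#' narrow -- and are reported only for comparison with the mixed-model
#' versions.
#'
#' @param pairs a [pair_differences()] table.
#' @param multiplier LoA multiplier, default 1.96.
#' @return list with `pearson`, `lin_ccc` and `simple_loa` (class `loa`).
#' @export
naive_indices <- function(pairs, multiplier = 1.96) {
  stopifnot(inherits(pairs, "paired_differences"))
  if (nrow(pairs) < 3L) ag_data_error("need at least 3 pairs")
  # reconstruct the paired readings from diff and avg
  y_test <- pairs$avg + pairs$diff / 2
  y_ref <- pairs$avg - pairs$diff / 2
  if (any(is.na(pairs$avg))) {
    ag_data_error("pair averages unavailable: cannot compute naive indices")
  }
  if (stats::sd(y_test) == 0 || stats::sd(y_ref) == 0) {
    ag_data_error("zero variance in one device's readings: correlation undefined")
  }
  n <- nrow(pairs)
  s12 <- mean((y_ref - mean(y_ref)) * (y_test - mean(y_test)))
  s1 <- mean((y_ref - mean(y_ref))^2)
  s2 <- mean((y_test - mean(y_test))^2)
  lin <- 2 * s12 / (s1 + s2 + (mean(y_ref) - mean(y_test))^2)
  list(
    pearson = stats::cor(y_ref, y_test),
    lin_ccc = lin,
    simple_loa = loa_triplet(mean(pairs$diff), stats::sd(pairs$diff),
                             multiplier, "naive")
  )
}

#' Fixed-effects (ANOVA) limits of agreement for repeated differences
#'
#' The one-way ANOVA-on-differences extension of the limits of agreement to
#' repeated measures: the total variance of a single paired difference is
#' decomposed as between-subject plus within-subject,
#' \eqn{\hat\sigma_b^2 + \hat\sigma_w^2}, with
#' \eqn{\hat\sigma_w^2 = MSW} (within-subject mean square) and
#' \eqn{\hat\sigma_b^2 = (MSB - MSW)/n_0} truncated at zero, where for k
#' subjects with \eqn{m_i} differences each
#' \eqn{n_0 = [\sum m_i - \sum m_i^2/\sum m_i]/(k-1)} corrects for
#' unbalance.
#'
#' @param pairs a [pair_differences()] table.
#' @param multiplier LoA multiplier, default 1.96.
#' @return list with `bias`, `lower`, `upper` (class `loa`).
#' @export
anova_loa <- function(pairs, multiplier = 1.96) {
  stopifnot(inherits(pairs, "paired_differences"))
  d <- pairs$diff
  subj <- pairs$subject
  k <- length(unique(subj))
  if (k < 2L) ag_data_error("need >= 2 subjects")
  m_i <- tapply(d, subj, length)
  if (all(m_i < 2L)) {
    ag_data_error(paste0(
      "every subject has a single difference: the within-subject mean ",
      "square is inestimable; use the mixed-model limits of agreement"))
  }
  means <- tapply(d, subj, mean)
  grand <- mean(d)
  ssw <- sum((d - means[as.character(subj)])^2)
  msw <- ssw / (sum(m_i) - k)
  ssb <- sum(m_i * (means - grand)^2)
  msb <- ssb / (k - 1)
  n0 <- (sum(m_i) - sum(m_i^2) / sum(m_i)) / (k - 1)
  sb2 <- max((msb - msw) / n0, 0)
  loa_triplet(grand, sqrt(sb2 + msw), multiplier, "anova")
}

verdict <- function(agree) if (isTRUE(agree)) "agree" else "do not agree"

#' Build a combined agreement report
#'
#' Computes every index available from the supplied fits and compares the
#' CAD-dependent ones against the thresholds in `settings`:
#' LoA "agree" when both limits lie within \eqn{\pm\delta}; CP "agree" when
#' \eqn{CP(\delta) \ge} `cp_threshold`; TDI "agree" when
#' \eqn{TDI(p) \le \delta}; CIA "agree" when CIA \eqn{\ge} `cia_threshold`.
#' The CCC gets a verdict only if `ccc_threshold` was supplied.  When the
#' estimated MSD is exactly zero (perfect agreement in the fitted model) the
#' degenerate limits CP = 1, TDI = 0 and CIA = 1 are reported with a flag.
#'
#' @param full_fit a `full_model_fit`, or NULL.
#' @param diff_fit a `diff_model_fit`, or NULL.
#' @param pairs optional [pair_differences()] table (enables naive and ANOVA
#'   indices).
#' @param settings an [agreement_settings()].
#' @return Object of class `agreement_report`: named index estimates,
#'   verdicts, and the provenance (which fit produced each number).
#' @export
build_report <- function(full_fit = NULL, diff_fit = NULL, pairs = NULL,
                         settings) {
  stopifnot(inherits(settings, "agreement_settings"))
  if (is.null(full_fit) && is.null(diff_fit)) {
    ag_argument_error("need at least one fitted model")
  }
  idx <- list()
  prov <- list()
  degenerate_msd <- FALSE
  m <- settings$loa_multiplier
  if (!is.null(full_fit)) {
    msd_hat <- msd(full_fit)
    degenerate_msd <- msd_hat == 0
    idx$ccc <- tryCatch(ccc_repeated(full_fit),
                        agreemix_error = function(e) NA_real_)
    idx$msd <- msd_hat
    idx$cp <- coverage_probability(msd_hat, settings$cad_delta)
    idx$tdi <- tdi(msd_hat, settings$tdi_p)
    idx$cia <- if (degenerate_msd) 1 else if (full_fit$var_resid > 0) {
      cia(full_fit)
    } else NA_real_
    idx$repeatability <- repeatability_coefficient(full_fit, m)
    idx$loa_full <- loa_from_full_model(full_fit, m)
    prov[names(idx)] <- "full_model"
  }
  if (!is.null(diff_fit)) {
    idx$loa <- loa_from_diff_model(diff_fit, m)
    prov$loa <- "diff_model"
  } else if (!is.null(full_fit)) {
    idx$loa <- idx$loa_full
    prov$loa <- "full_model"
  }
  if (!is.null(pairs)) {
    idx$naive <- tryCatch(naive_indices(pairs, m), agreemix_error = function(e) NULL)
    idx$anova_loa <- tryCatch(anova_loa(pairs, m),
                              agreemix_error = function(e) NULL)
    prov$naive <- prov$anova_loa <- "pairs"
  }

  d <- settings$cad_delta
  verdicts <- list(
    loa = verdict(idx$loa$lower >= -d && idx$loa$upper <= d)
  )
  if (!is.null(full_fit)) {
    verdicts$cp <- verdict(idx$cp >= settings$cp_threshold)
    verdicts$tdi <- verdict(idx$tdi <= d)
    verdicts$cia <- if (is.na(idx$cia)) NA_character_ else {
      verdict(idx$cia >= settings$cia_threshold)
    }
    verdicts$ccc <- if (is.null(settings$ccc_threshold) || is.na(idx$ccc)) {
      NA_character_
    } else {
      verdict(idx$ccc >= settings$ccc_threshold)
    }
  }
  structure(list(indices = idx, verdicts = verdicts, settings = settings,
                 provenance = prov, degenerate_msd = degenerate_msd,
                 boundary = if (!is.null(full_fit)) full_fit$boundary else NULL),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report (CAD delta = ", x$settings$cad_delta, ")\n", sep = "")
  fmt <- function(v) formatC(v, digits = 3, format = "fg")
  i <- x$indices
  v <- x$verdicts
  if (!is.null(i$ccc)) {
    cat("  CCC          ", fmt(i$ccc),
        if (!is.na(v$ccc %||% NA)) paste0("  [", v$ccc, "]") else "", "\n")
  }
  if (!is.null(i$loa)) {
    cat("  LoA (", i$loa$source, ")  bias ", fmt(i$loa$bias), " (",
        fmt(i$loa$lower), " to ", fmt(i$loa$upper), ")  [", v$loa, "]\n",
        sep = "")
  }
  if (!is.null(i$msd)) cat("  MSD          ", fmt(i$msd), "\n")
  if (!is.null(i$cp)) cat("  CP           ", fmt(i$cp), "  [", v$cp, "]\n")
  if (!is.null(i$tdi)) {
    cat("  TDI(", x$settings$tdi_p, ")    ", fmt(i$tdi), "  [", v$tdi, "]\n",
        sep = "")
  }
  if (!is.null(i$cia) && !is.na(i$cia)) {
    cat("  CIA          ", fmt(i$cia), "  [", v$cia, "]\n")
  }
  if (!is.null(i$repeatability)) {
    cat("  Repeatability", fmt(i$repeatability), "\n")
  }
  if (x$degenerate_msd) cat("  (degenerate: estimated MSD is zero)\n")
  invisible(x)
}

#' Serialize an agreement report to JSON
#'
#' @param report an `agreement_report`.
#' @return JSON string.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "agreement_report"))
  x <- unclass(report)
  x$settings <- unclass(x$settings)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   force = TRUE)
}
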