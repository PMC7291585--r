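#' Fit the full crossed agreement model to raw readings
#'
#' Fits, by REML, the linear mixed model for a reading on subject i by
#' device j under activity l at replicate t:
#' \deqn{y_{ijlt} = \mu + \alpha_i + \beta_j + \gamma_l + (\alpha\beta)_{ij}
#'   + (\alpha\gamma)_{il} + (\beta\gamma)_{jl} + \epsilon_{ijlt}}
#' with a fixed sum-to-zero device effect and independent Gaussian random
#' intercepts for subject, activity and the three two-way interactions.
#' All available readings are used, including readings that have no
#' time-matched counterpart on the other device (mixed models tolerate
#' unbalance).  With a single activity the activity terms are dropped with a
#' warning.
#'
#' @param table a [measurement_table()].
#' @param method REML backend, see [reml_fit()].
#' @return Object of class `full_model_fit` with elements `mu`, `beta`
#'   (named device effects summing to zero, reference first), `device_diff`
#'   (\eqn{\beta_{test} - \beta_{ref}}), the six variances `var_subject`,
#'   `var_activity`, `var_subject_device`, `var_subject_activity`,
#'   `var_device_activity`, `var_resid`, plus `reml_loglik`, `converged`,
#'   `boundary`, `n_obs`, `n_subjects` and the underlying `reml` fit.
#' @export
fit_full_model <- function(table, method = c("lme4", "dense")) {
  stopifnot(inherits(table, "measurement_table"))
  method <- match.arg(method)
  ref <- attr(table, "reference_device")
  tst <- attr(table, "test_device")
  df <- as.data.frame(table)
  device <- factor(df$device, levels = c(ref, tst))
  groups <- list(
    subject = df$subject,
    activity = df$activity,
    subject_device = paste(df$subject, df$device, sep = ":"),
    subject_activity = paste(df$subject, df$activity, sep = ":"),
    device_activity = paste(df$device, df$activity, sep = ":")
  )
  if (length(unique(df$activity)) < 2L) {
    warning("single activity: dropping activity, subject:activity and ",
            "device:activity terms", call. = FALSE)
    groups <- groups[c("subject", "subject_device")]
  }
  fit <- reml_fit(df$value, groups, device = device, method = method)
  vc <- function(nm) unname(fit$varcomp[nm]) %||% NA_real_
  comp <- c(
    var_subject = if ("subject" %in% names(fit$varcomp)) vc("subject") else 0,
    var_activity = if ("activity" %in% names(fit$varcomp)) vc("activity") else 0,
    var_subject_device = if ("subject_device" %in% names(fit$varcomp)) vc("subject_device") else 0,
    var_subject_activity = if ("subject_activity" %in% names(fit$varcomp)) vc("subject_activity") else 0,
    var_device_activity = if ("device_activity" %in% names(fit$varcomp)) vc("device_activity") else 0
  )
  comp[is.na(comp)] <- 0
  beta <- fit$device_effects
  structure(c(
    list(mu = fit$mu, beta = beta,
         device_diff = unname(beta[tst] - beta[ref])),
    as.list(comp),
    list(var_resid = fit$var_resid,
         reml_loglik = fit$reml_loglik, converged = fit$converged,
         boundary = fit$boundary, n_obs = fit$n_obs,
         n_subjects = length(unique(df$subject)),
         reference_device = ref, test_device = tst, reml = fit)
  ), class = "full_model_fit")
}

#' Construct a full-model fit from known components
#'
#' Builds a `full_model_fit` directly from variance components and a mean
#' device difference, e.g. values published in a report, so that the
#' agreement indices can be recomputed without access to the raw data.
#'
#' @param var_subject,var_activity,var_subject_device,var_subject_activity,var_device_activity,var_resid
#'   non-negative variances (squared measurement units).
#' @param device_diff mean device difference \eqn{\beta_{test} - \beta_{ref}}.
#' @param mu overall mean (optional, only used for reporting).
#' @export
full_model_fit <- function(var_subject, var_activity, var_subject_device,
                           var_subject_activity, var_device_activity,
                           var_resid, device_diff = 0, mu = NA_real_) {
  comp <- c(var_subject = var_subject, var_activity = var_activity,
            var_subject_device = var_subject_device,
            var_subject_activity = var_subject_activity,
            var_device_activity = var_device_activity,
            var_resid = var_resid)
  if (any(comp < 0)) ag_argument_error("variance components must be >= 0")
  beta <- c(reference = -device_diff / 2, test = device_diff / 2)
  structure(c(
    list(mu = mu, beta = beta, device_diff = device_diff),
    as.list(comp),
    list(reml_loglik = NA_real_, converged = TRUE,
         boundary = comp == 0, n_obs = NA_integer_,
         n_subjects = NA_integer_, reference_device = "reference",
         test_device = "test", reml = NULL)
  ), class = "full_model_fit")
}

#' @export
print.full_model_fit <- function(x, ...) {
  cat("Full agreement model (REML)\n")
  cat("  device difference (test - reference):", format(x$device_diff), "\n")
  vc <- unlist(x[c("var_subject", "var_activity", "var_subject_device",
                   "var_subject_activity", "var_device_activity",
                   "var_resid")])
  print(round(vc, 4))
  if (!x$converged) cat("  ** fit did not converge cleanly **\n")
  invisible(x)
}

#' Fit the paired-differences agreement models
#'
#' Fits two REML models to the time-matched paired differences
#' \eqn{D_{ilt}}: the differences model
#' \eqn{D_{ilt} = \mu^* + \alpha_i^* + \gamma_l^* + \epsilon^*_{ilt}}
#' (random subject and activity intercepts), from which the limits-of-
#' agreement variance is taken, and a bias-only model
#' \eqn{D_{ilt} = \mu_0^* + \alpha_{0i}^* + \epsilon^*_{0ilt}}
#' whose intercept \eqn{\mu_0^*} is the appropriately weighted mean bias.
#'
#' @param pairs a [pair_differences()] table.
#' @param method REML backend, see [reml_fit()].
#' @return Object of class `diff_model_fit`: `mu_star`, `var_subject_star`,
#'   `var_activity_star`, `var_resid_star` (differences model), `mu0_star`,
#'   `var_subject0`, `var_resid0` (bias model), log-likelihoods and
#'   convergence flags.
#' @export
fit_diff_model <- function(pairs, method = c("lme4", "dense")) {
  stopifnot(inherits(pairs, "paired_differences"))
  method <- match.arg(method)
  if (length(unique(pairs$subject)) < 2L) {
    ag_data_error("need >= 2 subjects with differences")
  }
  m3 <- reml_fit(pairs$diff,
                 list(subject = pairs$subject, activity = pairs$activity),
                 method = method)
  m0 <- reml_fit(pairs$diff, list(subject = pairs$subject), method = method)
  va <- if ("activity" %in% names(m3$varcomp)) {
    unname(m3$varcomp["activity"])
  } else 0
  structure(list(
    mu_star = m3$mu,
    var_subject_star = unname(m3$varcomp["subject"]),
    var_activity_star = va,
    var_resid_star = m3$var_resid,
    mu0_star = m0$mu,
    var_subject0 = unname(m0$varcomp["subject"]),
    var_resid0 = m0$var_resid,
    reml_loglik = c(diff_model = m3$reml_loglik, bias_model = m0$reml_loglik),
    converged = c(diff_model = m3$converged, bias_model = m0$converged),
    n_obs = m3$n_obs, n_subjects = length(unique(pairs$subject)),
    reml = list(diff_model = m3, bias_model = m0)
  ), class = "diff_model_fit")
}

#' Construct a differences-model fit from known components
#'
#' @param mu0_star mean bias (bias-only model intercept).
#' @param var_subject_star,var_activity_star,var_resid_star variances of the
#'   differences model.
#' @param mu_star optional differences-model intercept (defaults to
#'   `mu0_star`).
#' @export
diff_model_fit <- function(mu0_star, var_subject_star, var_activity_star,
                           var_resid_star, mu_star = mu0_star) {
  comp <- c(var_subject_star, var_activity_star, var_resid_star)
  if (any(comp < 0)) ag_argument_error("variance components must be >= 0")
  structure(list(
    mu_star = mu_star, var_subject_star = var_subject_star,
    var_activity_star = var_activity_star, var_resid_star = var_resid_star,
    mu0_star = mu0_star, var_subject0 = NA_real_, var_resid0 = NA_real_,
    reml_loglik = c(diff_model = NA_real_, bias_model = NA_real_),
    converged = c(diff_model = TRUE, bias_model = TRUE),
    n_obs = NA_integer_, n_subjects = NA_integer_, reml = NULL
  ), class = "diff_model_fit")
}

#' @export
print.diff_model_fit <- function(x, ...) {
  cat("Paired-differences agreement models (REML)\n")
  cat("  mean bias mu0* =", format(x$mu0_star), "\n")
  cat("  differences-model variances: subject =",
      format(x$var_subject_star, digits = 4), ", activity =",
      format(x$var_activity_star, digits = 4), ", residual =",
      format(x$var_resid_star, digits = 4), "\n")
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param fit a `full_model_fit`, `diff_model_fit` or `reml_fit`.
#' @return a JSON string (class `json`).
#' @export
fit_to_json <- function(fit) {
  drop_heavy <- function(x) {
    x$reml <- NULL
    x$fit <- NULL
    x
  }
  x <- drop_heavy(unclass(fit))
  x <- lapply(x, function(el) if (inherits(el, "reml_fit")) drop_heavy(unclass(el)) else el)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   force = TRUE)
}
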