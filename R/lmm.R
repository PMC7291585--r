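#' Dense-matrix REML log-likelihood (reference evaluator)
#'
#' Evaluates the restricted log-likelihood of a Gaussian linear mixed model
#' by explicit assembly of the marginal covariance
#' \eqn{V = \sum_k \sigma_k^2 Z_k Z_k' + \sigma_\epsilon^2 I}:
#' \deqn{\ell_R = -\tfrac12\left[(n-p)\log 2\pi + \log|V| +
#'   \log|X'V^{-1}X| + (y-X\hat\beta)'V^{-1}(y-X\hat\beta)\right]}
#' with \eqn{\hat\beta} the GLS estimate.  This is deliberately independent
#' of the production fitting path (sparse, profiled) and serves as the
#' oracle for cross-checking fitted criteria on small instances; it is
#' O(n^3) and intended for n up to a few hundred.
#'
#' @param y numeric response vector.
#' @param X fixed-effects design matrix (n x p, full column rank).
#' @param Z list of random-effects indicator matrices (each n x q_k).
#' @param varcomp numeric vector of variances, one per element of `Z`.
#' @param var_resid residual variance (> 0).
#' @return scalar restricted log-likelihood.
#' @export
dense_reml_loglik <- function(y, X, Z, varcomp, var_resid) {
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  if (length(Z) != length(varcomp)) {
    ag_argument_error("varcomp must have one entry per Z matrix")
  }
  if (var_resid <= 0) return(-Inf)
  V <- diag(var_resid, n)
  for (k in seq_along(Z)) {
    if (varcomp[k] < 0) return(-Inf)
    if (varcomp[k] > 0) V <- V + varcomp[k] * tcrossprod(as.matrix(Z[[k]]))
  }
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdetV <- 2 * sum(log(diag(R)))
  Viy <- backsolve(R, forwardsolve(t(R), y))
  ViX <- backsolve(R, forwardsolve(t(R), X))
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(ViX, y))
  r <- y - X %*% beta
  Vir <- backsolve(R, forwardsolve(t(R), r))
  quad <- sum(r * Vir)
  ld2 <- determinant(XtViX, logarithm = TRUE)$modulus
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + logdetV + ld2 + quad))
}

# Build the design pieces (X, Z list) shared by the dense path and the oracle.
build_designs <- function(n, groups, device = NULL) {
  if (!is.null(device)) {
    # sum-to-zero device coding: column is +1 for the first level (reference)
    # and -1 for the second (test), so beta_ref = coef, beta_test = -coef.
    dv <- ifelse(device == levels(device)[1L], 1, -1)
    X <- cbind(`(Intercept)` = rep(1, n), device = dv)
  } else {
    X <- cbind(`(Intercept)` = rep(1, n))
  }
  Z <- lapply(groups, function(g) {
    g <- droplevels(as.factor(g))
    stats::model.matrix(~ 0 + g)
  })
  list(X = X, Z = Z)
}

moment_starts <- function(y, k) {
  v <- stats::var(y)
  if (!is.finite(v) || v <= 0) v <- 1
  # deterministic multi-start grid over how much variance sits in the residual
  lapply(c(0.5, 0.9, 0.2), function(fr) {
    c(rep(sqrt(v * (1 - fr) / max(k, 1)), k), sqrt(v * fr))
  })
}

reml_fit_dense <- function(y, groups, device, tol = 1e-8) {
  n <- length(y)
  des <- build_designs(n, groups, device)
  k <- length(groups)
  obj <- function(theta) {
    -dense_reml_loglik(y, des$X, des$Z, theta[seq_len(k)]^2, theta[k + 1L]^2)
  }
  best <- NULL
  for (st in moment_starts(y, k)) {
    op <- tryCatch(
      stats::nlminb(st, obj, control = list(rel.tol = tol, iter.max = 500)),
      error = function(e) NULL
    )
    if (!is.null(op) && (is.null(best) || op$objective < best$objective)) {
      best <- op
    }
  }
  if (is.null(best)) ag_stop("dense REML optimization failed", "agreemix_fit_error")
  vc <- best$par[seq_len(k)]^2
  ve <- best$par[k + 1L]^2
  tot <- sum(vc) + ve
  vc[vc < 1e-8 * tot] <- 0          # snap boundary estimates to exact zero
  ll <- dense_reml_loglik(y, des$X, des$Z, vc, ve)
  # GLS fixed effects at the optimum
  V <- diag(ve, n)
  for (j in seq_len(k)) if (vc[j] > 0) V <- V + vc[j] * tcrossprod(des$Z[[j]])
  Vi <- chol2inv(chol(V))
  beta <- solve(crossprod(des$X, Vi %*% des$X), crossprod(des$X, Vi %*% y))
  list(fixef = drop(beta), varcomp = stats::setNames(vc, names(groups)),
       var_resid = ve, loglik = ll,
       converged = best$convergence == 0)
}

reml_fit_lme4 <- function(y, groups, device) {
  dat <- data.frame(.y = y)
  for (nm in names(groups)) dat[[nm]] <- droplevels(as.factor(groups[[nm]]))
  rand <- paste(sprintf("(1 | %s)", names(groups)), collapse = " + ")
  if (!is.null(device)) {
    dat$.device <- device
    form <- stats::as.formula(paste(".y ~ .device +", rand))
    contr <- list(.device = "contr.sum")
  } else {
    form <- stats::as.formula(paste(".y ~ 1 +", rand))
    contr <- NULL
  }
  warns <- character(0)
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(
      form, data = dat, REML = TRUE, contrasts = contr,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")
    )),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  ve <- vc$vcov[vc$grp == "Residual"]
  comp <- stats::setNames(vc$vcov[match(names(groups), vc$grp)], names(groups))
  fx <- lme4::fixef(fit)
  opt_ok <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  list(fixef = fx, varcomp = comp, var_resid = ve,
       loglik = as.numeric(stats::logLik(fit)),
       converged = opt_ok && length(warns) == 0,
       warnings = warns, fit = fit)
}

#' REML fit of a crossed random-intercept mixed model
#'
#' Fits `response ~ fixed + sum of random intercepts` by REML.  The fixed part
#' is an intercept plus, optionally, a two-level device effect coded
#' sum-to-zero (\eqn{\beta_1 + \beta_2 = 0}).  The production backend is
#' lme4's profiled sparse REML; `method = "dense"` uses a self-contained
#' optimizer over the explicit marginal covariance (the same criterion as
#' [dense_reml_loglik()]), useful for verification and tiny data.
#'
#' Random terms whose grouping factor has fewer than 2 levels are dropped with
#' a warning.  Variance estimates on the boundary (zero) are legitimate and
#' flagged rather than treated as failures.
#'
#' @param response numeric vector.
#' @param groups named list of grouping vectors, one per random intercept.
#' @param device optional factor with exactly two levels; its first level is
#'   taken as the reference device.
#' @param method `"lme4"` (default) or `"dense"`.
#' @return Object of class `reml_fit`: list with `mu`, `device_effects`
#'   (named length-2 vector or NULL), `varcomp` (named variances), `var_resid`,
#'   `reml_loglik`, `converged`, `boundary` (named flags), `n_obs`,
#'   `n_levels`, `dropped_terms`, `method` and (lme4 path) the backend `fit`.
#' @export
reml_fit <- function(response, groups, device = NULL,
                     method = c("lme4", "dense")) {
  method <- match.arg(method)
  y <- as.numeric(response)
  n <- length(y)
  if (any(!is.finite(y))) ag_data_error("non-finite response values")
  if (!is.null(device)) {
    device <- as.factor(device)
    if (nlevels(droplevels(device)) != 2L) {
      ag_argument_error("device factor must have exactly 2 levels")
    }
    device <- droplevels(device)
  }
  p <- 1L + !is.null(device)
  if (n <= p) ag_data_error("more fixed-effect parameters than observations")

  keep <- vapply(groups, function(g) length(unique(g)) >= 2L, logical(1))
  dropped <- names(groups)[!keep]
  if (length(dropped) > 0) {
    warning("dropping random term(s) with < 2 levels: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    groups <- groups[keep]
  }

  # degenerate data: response constant within each fixed-effect cell
  cell <- if (is.null(device)) rep(1L, n) else as.integer(device)
  resid_spread <- max(tapply(y, cell, function(v) {
    if (length(v) > 1) stats::var(v) else 0
  }))
  if (resid_spread == 0) {
    means <- tapply(y, cell, mean)
    if (is.null(device)) {
      mu <- unname(means[1L]); dev_eff <- NULL
    } else {
      mu <- mean(means)
      dev_eff <- stats::setNames(as.numeric(means - mu), levels(device))
    }
    vc <- stats::setNames(rep(0, length(groups)), names(groups))
    return(structure(list(
      mu = mu, device_effects = dev_eff, varcomp = vc, var_resid = 0,
      reml_loglik = NA_real_, converged = TRUE,
      boundary = stats::setNames(rep(TRUE, length(vc) + 1L),
                                 c(names(vc), "resid")),
      n_obs = n,
      n_levels = vapply(groups, function(g) length(unique(g)), integer(1)),
      dropped_terms = dropped, method = "degenerate", fit = NULL
    ), class = "reml_fit"))
  }

  if (length(groups) == 0L) {
    # pure fixed-effects model: REML residual variance
    X <- build_designs(n, groups, device)$X
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) ag_stop("singular fixed-effect design",
                                    "agreemix_fit_error")
    beta <- qr.coef(qrX, y)
    r <- y - X %*% beta
    ve <- sum(r^2) / (n - ncol(X))
    res <- list(fixef = beta, varcomp = stats::setNames(numeric(0), character(0)),
                var_resid = ve,
                loglik = dense_reml_loglik(y, X, list(), numeric(0), ve),
                converged = TRUE)
  } else if (method == "dense") {
    res <- reml_fit_dense(y, groups, device)
  } else {
    res <- reml_fit_lme4(y, groups, device)
  }

  if (is.null(device)) {
    mu <- unname(res$fixef[1L]); dev_eff <- NULL
  } else {
    mu <- unname(res$fixef[1L])
    b <- unname(res$fixef[2L])   # sum-to-zero: beta_ref = b, beta_test = -b
    dev_eff <- stats::setNames(c(b, -b), levels(device))
  }
  tot <- sum(res$varcomp) + res$var_resid
  boundary <- c(res$varcomp <= 1e-8 * tot, resid = res$var_resid <= 1e-8 * tot)
  structure(list(
    mu = mu, device_effects = dev_eff, varcomp = res$varcomp,
    var_resid = res$var_resid, reml_loglik = res$loglik,
    converged = isTRUE(res$converged), boundary = boundary, n_obs = n,
    n_levels = vapply(groups, function(g) length(unique(g)), integer(1)),
    dropped_terms = dropped, method = method, fit = res$fit %||% NULL,
    warnings = res$warnings %||% character(0)
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit (", x$method, "), n = ", x$n_obs,
      ", logLik = ", format(x$reml_loglik), ", converged: ", x$converged,
      "\n", sep = "")
  cat("  mu =", format(x$mu), "\n")
  if (!is.null(x$device_effects)) {
    cat("  device effects:",
        paste(names(x$device_effects), "=",
              format(x$device_effects, digits = 4), collapse = ", "), "\n")
  }
  vc <- c(x$varcomp, resid = x$var_resid)
  cat("  variance components:\n")
  print(round(vc, 4))
  invisible(x)
}
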