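#' Nonparametric total deviation index
#'
#' Empirical TDI: the p-quantile of the ordered absolute paired differences.
#' The default convention is nearest-rank -- element \eqn{\lceil p n \rceil}
#' of the ascending sort of |diff| -- which is exactly reproducible by
#' enumeration; `type = "interpolate"` uses the usual interpolating sample
#' quantile (R type 7) instead.  No distributional assumption is made, which
#' makes this estimator the recommended check when the paired differences
#' look skewed or heavy-tailed.
#'
#' @param pairs a [pair_differences()] table (or anything with a `diff`
#'   column).
#' @param p containment probability in (0, 1), default 0.95.
#' @param type `"nearest_rank"` (default) or `"interpolate"`.
#' @return non-negative scalar in measurement units.
#' @export
np_tdi <- function(pairs, p = 0.95, type = c("nearest_rank", "interpolate")) {
  type <- match.arg(type)
  d <- abs(pairs$diff)
  if (length(d) == 0L) ag_data_error("no differences supplied")
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    ag_argument_error("p must be in (0, 1)")
  }
  if (type == "nearest_rank") {
    sort(d)[ceiling(p * length(d))]
  } else {
    unname(stats::quantile(d, p, type = 7))
  }
}

#' Bootstrap upper bound for the nonparametric TDI
#'
#' The `conf`-quantile of [np_tdi()] over subject-level (patient-level)
#' bootstrap resamples: a one-sided upper confidence bound for the TDI.
#'
#' @inheritParams np_tdi
#' @param B number of resamples, default 1000.
#' @param conf one-sided confidence level, default 0.95.
#' @param seed integer seed.
#' @return scalar upper bound; the full replicate set is attached as
#'   attribute `bootstrap`.
#' @export
np_tdi_upper <- function(pairs, p = 0.95, B = 1000, conf = 0.95, seed = 1L,
                         type = c("nearest_rank", "interpolate")) {
  type <- match.arg(type)
  bt <- cluster_bootstrap(pairs, function(d) np_tdi(d, p = p, type = type),
                          B = B, conf = conf, seed = seed,
                          index_name = "np_tdi")
  ub <- unname(stats::quantile(bt$estimates, conf, names = FALSE))
  attr(ub, "bootstrap") <- bt
  ub
}
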