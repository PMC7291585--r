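resample_subjects <- function(x, ids) {
  # ids: subject labels drawn with replacement; resampled copies are
  # relabeled uniquely so a subject drawn twice contributes two clusters
  pieces <- lapply(seq_along(ids), function(b) {
    rows <- x[x$subject == ids[b], , drop = FALSE]
    rows$subject <- sprintf("b%03d", b)
    rows
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attributes(out)[setdiff(names(attributes(x)),
                          c("names", "row.names", "class"))] <-
    attributes(x)[setdiff(names(attributes(x)),
                          c("names", "row.names", "class"))]
  class(out) <- class(x)
  out
}

#' Subject-level (cluster) bootstrap confidence interval for an index
#'
#' Resamples whole subjects with replacement (the same number of subjects as
#' observed, each resampled copy relabeled as a distinct cluster), re-runs
#' the full index pipeline on every resample, and returns a percentile
#' confidence interval.  Resampling at the subject level respects the
#' within-subject dependence of clustered repeated measures; activities are
#' carried along inside each subject, never resampled independently.
#'
#' Replicates where the pipeline fails (e.g. a non-converged refit) are
#' skipped and counted; if more than 20% fail the result is flagged
#' unreliable.
#'
#' @param data a [measurement_table()] or [pair_differences()] table (any
#'   data.frame with a `subject` column whose attributes survive row
#'   subsetting).
#' @param index_fn function taking a resampled `data` and returning a single
#'   numeric index value.
#' @param B number of bootstrap resamples, default 1000.
#' @param conf confidence level, default 0.95.
#' @param seed integer seed; the result is reproducible given
#'   (data, B, seed).
#' @param index_name label stored in the result.
#' @return Object of class `bootstrap_result`: `index_name`, `estimates`
#'   (successful replicate values), `n_failed`, `ci` (percentile bounds),
#'   `conf`, `B`, `seed`, `unreliable`.
#' @export
cluster_bootstrap <- function(data, index_fn, B = 1000, conf = 0.95,
                              seed = 1L,
                              index_name = deparse(substitute(index_fn))) {
  stopifnot(is.function(index_fn), B >= 1)
  subjects <- unique(data$subject)
  if (length(subjects) < 2L) ag_data_error("need >= 2 subjects to bootstrap")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  draws <- matrix(sample(subjects, length(subjects) * B, replace = TRUE),
                  nrow = B)
  est <- numeric(0)
  n_failed <- 0L
  for (b in seq_len(B)) {
    val <- tryCatch(
      suppressWarnings(index_fn(resample_subjects(data, draws[b, ]))),
      error = function(e) NA_real_
    )
    if (is.numeric(val) && length(val) == 1L && is.finite(val)) {
      est <- c(est, val)
    } else {
      n_failed <- n_failed + 1L
    }
  }
  if (length(est) == 0L) ag_data_error("all bootstrap replicates failed")
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(est, c(alpha, 1 - alpha), names = FALSE))
  structure(list(
    index_name = index_name, estimates = est, n_failed = n_failed,
    ci = c(lower = ci[1L], upper = ci[2L]), conf = conf, B = as.integer(B),
    seed = as.integer(seed), unreliable = n_failed > 0.2 * B
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Cluster bootstrap of %s: %d/%d replicates, %.0f%% CI (%.4g, %.4g)%s\n",
    x$index_name, length(x$estimates), x$B, 100 * x$conf,
    x$ci["lower"], x$ci["upper"],
    if (x$unreliable) "  ** >20% failed refits: unreliable **" else ""))
  invisible(x)
}
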