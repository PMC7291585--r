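#' Specify one activity of a synthetic design
#'
#' @param label activity name.
#' @param reps vector of possible paired-reading counts per subject for this
#'   activity (e.g. `c(6, 7)`).
#' @param rep_prob probabilities for `reps` (uniform if NULL).
#' @param participation probability in (0, 1\] that a given subject performs
#'   this activity at all (emulates subjects skipping strenuous tasks).
#' @export
activity_spec <- function(label, reps = 1L, rep_prob = NULL,
                          participation = 1) {
  if (any(reps < 1L)) ag_argument_error("replicate counts must be >= 1")
  if (participation <= 0 || participation > 1) {
    ag_argument_error("participation must be in (0, 1]")
  }
  if (!is.null(rep_prob) && length(rep_prob) != length(reps)) {
    ag_argument_error("rep_prob must match reps in length")
  }
  list(label = as.character(label), reps = as.integer(reps),
       rep_prob = rep_prob, participation = participation)
}

#' Specify a synthetic two-device agreement design
#'
#' Describes the generative model for synthetic readings: the full crossed
#' mixed model with all effects drawn independent normal,
#' \eqn{y_{ijlt} = \mu + \alpha_i + \beta_j + \gamma_l + (\alpha\beta)_{ij} +
#' (\alpha\gamma)_{il} + (\beta\gamma)_{jl} + \epsilon_{ijlt}}, on an
#' (optionally unbalanced) schedule of subjects x activities x replicates.
#' Both devices are observed at every generated (subject, activity,
#' replicate), i.e. pairs are time-matched by construction.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param activities list of [activity_spec()]s.
#' @param mu overall mean.
#' @param device_diff fixed mean device difference
#'   \eqn{\beta_{test} - \beta_{ref}} (sum-to-zero coding).
#' @param var_subject,var_activity,var_subject_device,var_subject_activity,var_device_activity,var_resid
#'   true variance components (>= 0).
#' @param seed default seed used by [generate_measurements()] when none is
#'   passed there.
#' @export
synthetic_design <- function(n_subjects, activities, mu = 20,
                             device_diff = 0,
                             var_subject = 0, var_activity = 0,
                             var_subject_device = 0,
                             var_subject_activity = 0,
                             var_device_activity = 0, var_resid = 1,
                             seed = 1L) {
  comp <- c(var_subject, var_activity, var_subject_device,
            var_subject_activity, var_device_activity, var_resid)
  if (any(comp < 0)) ag_argument_error("variances must be >= 0")
  if (n_subjects < 2L) ag_argument_error("need >= 2 subjects")
  if (is.list(activities) && !is.null(activities$label)) {
    activities <- list(activities)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), activities = activities, mu = mu,
    device_diff = device_diff, var_subject = var_subject,
    var_activity = var_activity, var_subject_device = var_subject_device,
    var_subject_activity = var_subject_activity,
    var_device_activity = var_device_activity, var_resid = var_resid,
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' COPD-like unbalanced design template
#'
#' A 21-subject, 11-activity schedule emulating the structure of the COPD
#' respiratory-rate study that motivates this package: "sitting" contributes
#' 6-7 paired readings per subject, "standing and walking" 1-3 (weighted
#' towards the maximum, as most subjects complete the full protocol), every
#' other activity 1, and the two treadmill activities are skipped by each
#' subject independently with probability 0.2 (some tasks are too strenuous
#' for some participants).  Per-subject paired-reading counts then fall in
#' 15-19 with mean about 18.  Default truth: the published variance
#' components (11.4, 16.6, 0.4, 6.0, 3.7, 10.5) and mean device difference
#' -1.28 breaths/min; overall mean 19 breaths/min (between the two devices'
#' observed medians).
#'
#' @param n_subjects number of subjects, default 21.
#' @param mu,device_diff fixed effects, see [synthetic_design()].
#' @param varcomp length-6 vector (subject, activity, subject-device,
#'   subject-activity, device-activity, residual).
#' @param seed default generation seed.
#' @export
copd_design <- function(n_subjects = 21, mu = 19, device_diff = -1.28,
                        varcomp = c(11.4, 16.6, 0.4, 6.0, 3.7, 10.5),
                        seed = 1L) {
  acts <- c(
    list(activity_spec("sitting", reps = c(6L, 7L), rep_prob = c(0.2, 0.8)),
         activity_spec("standing_walking", reps = 1:3,
                       rep_prob = c(0.05, 0.15, 0.8))),
    lapply(c("lying", "standing", "slow_walking", "fast_walking",
             "sweeping", "lifting", "stairs"), activity_spec),
    list(activity_spec("treadmill_flat", participation = 0.8),
         activity_spec("treadmill_slope", participation = 0.8))
  )
  synthetic_design(n_subjects, acts, mu = mu, device_diff = device_diff,
                   var_subject = varcomp[1], var_activity = varcomp[2],
                   var_subject_device = varcomp[3],
                   var_subject_activity = varcomp[4],
                   var_device_activity = varcomp[5], var_resid = varcomp[6],
                   seed = seed)
}

draw_schedule <- function(design) {
  rows <- list()
  for (i in seq_len(design$n_subjects)) {
    subj <- sprintf("S%02d", i)
    for (a in design$activities) {
      if (a$participation < 1 && stats::runif(1) > a$participation) next
      nrep <- if (length(a$reps) == 1L) a$reps else {
        sample(a$reps, 1L, prob = a$rep_prob)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, activity = a$label, replicate = seq_len(nrep),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic measurements from a design
#'
#' Draws every random effect of the full crossed model independently from
#' its normal distribution and assembles time-matched readings for both
#' devices ("reference" and "test").  The latent effect draws are attached
#' as attribute `latent` for white-box testing.  Deterministic given the
#' seed.
#'
#' @param design a [synthetic_design()].
#' @param seed integer seed (defaults to the design's).
#' @return a [measurement_table()] with attribute `latent`.
#' @export
generate_measurements <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "synthetic_design"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  sched <- draw_schedule(design)
  subjects <- unique(sched$subject)
  acts <- unique(sched$activity)
  devices <- c("reference", "test")
  beta <- c(reference = -design$device_diff / 2,
            test = design$device_diff / 2)
  rn <- function(n, v) if (v > 0) stats::rnorm(n, 0, sqrt(v)) else numeric(n)
  lat <- list(
    alpha = stats::setNames(rn(length(subjects), design$var_subject), subjects),
    gamma = stats::setNames(rn(length(acts), design$var_activity), acts),
    alpha_beta = matrix(rn(length(subjects) * 2, design$var_subject_device),
                        nrow = length(subjects),
                        dimnames = list(subjects, devices)),
    alpha_gamma = matrix(rn(length(subjects) * length(acts),
                            design$var_subject_activity),
                         nrow = length(subjects),
                         dimnames = list(subjects, acts)),
    beta_gamma = matrix(rn(2 * length(acts), design$var_device_activity),
                        nrow = 2, dimnames = list(devices, acts))
  )
  long <- rbind(cbind(sched, device = "reference", stringsAsFactors = FALSE),
                cbind(sched, device = "test", stringsAsFactors = FALSE))
  eps <- rn(nrow(long), design$var_resid)
  long$value <- design$mu + beta[long$device] +
    lat$alpha[long$subject] + lat$gamma[long$activity] +
    lat$alpha_beta[cbind(long$subject, long$device)] +
    lat$alpha_gamma[cbind(long$subject, long$activity)] +
    lat$beta_gamma[cbind(long$device, long$activity)] + eps
  tab <- measurement_table(long, reference_device = "reference")
  attr(tab, "latent") <- lat
  tab
}

#' Specify and generate synthetic paired differences
#'
#' Generates differences directly from the reduced model
#' \eqn{D_{ilt} = \mu^* + \alpha_i^* + \gamma_l^* + \epsilon^*_{ilt}} on the
#' same kind of schedule as [generate_measurements()].
#'
#' @param n_subjects number of subjects.
#' @param activities list of [activity_spec()]s.
#' @param mu_star mean difference.
#' @param var_subject_star,var_activity_star,var_resid_star variances.
#' @param seed integer seed.
#' @return a `paired_differences` table (pair averages are NA: no raw
#'   readings exist) with attribute `latent`.
#' @export
generate_differences <- function(n_subjects, activities, mu_star = 0,
                                 var_subject_star = 0, var_activity_star = 0,
                                 var_resid_star = 1, seed = 1L) {
  design <- synthetic_design(n_subjects, activities, mu = mu_star,
                             var_subject = var_subject_star,
                             var_activity = var_activity_star,
                             var_resid = var_resid_star, seed = seed)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sched <- draw_schedule(design)
  subjects <- unique(sched$subject)
  acts <- unique(sched$activity)
  rn <- function(n, v) if (v > 0) stats::rnorm(n, 0, sqrt(v)) else numeric(n)
  lat <- list(
    alpha_star = stats::setNames(rn(length(subjects), var_subject_star),
                                 subjects),
    gamma_star = stats::setNames(rn(length(acts), var_activity_star), acts)
  )
  d <- mu_star + lat$alpha_star[sched$subject] +
    lat$gamma_star[sched$activity] + rn(nrow(sched), var_resid_star)
  out <- paired_differences(sched$subject, sched$activity, sched$replicate,
                            unname(d))
  attr(out, "latent") <- lat
  out
}
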