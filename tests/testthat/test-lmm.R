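# Helper: evaluate the dense REML criterion at a fitted full model's
# estimates, assembling X and the Z indicator matrices from scratch.
dense_loglik_at_fit <- function(tab, fit) {
  df <- as.data.frame(tab)
  device <- factor(df$device, levels = c(attr(tab, "reference_device"),
                                         attr(tab, "test_device")))
  X <- cbind(1, ifelse(device == levels(device)[1], 1, -1))
  groups <- list(
    subject = df$subject, activity = df$activity,
    subject_device = paste(df$subject, df$device),
    subject_activity = paste(df$subject, df$activity),
    device_activity = paste(df$device, df$activity))
  Z <- lapply(groups, function(g) model.matrix(~ 0 + factor(g)))
  vc <- c(fit$var_subject, fit$var_activity, fit$var_subject_device,
          fit$var_subject_activity, fit$var_device_activity)
  dense_reml_loglik(df$value, X, Z, vc, fit$var_resid)
}

test_that("constant responses give boundary zero variances and mu = c", {
  tab <- toy_table(n_s = 3, n_a = 2, n_r = 2)
  fit <- fit_full_model(tab)
  expect_equal(fit$mu, 7)
  expect_equal(fit$device_diff, 0)
  comps <- unlist(fit[c("var_subject", "var_activity", "var_subject_device",
                        "var_subject_activity", "var_device_activity",
                        "var_resid")])
  expect_true(all(comps == 0))
  expect_true(all(fit$boundary))
  expect_true(fit$converged)
})

test_that("production REML criterion equals the dense oracle on small instances", {
  for (seed in c(2, 5, 9)) {
    des <- small_noisy_design(n_s = 5, n_a = 3, seed = seed)
    tab <- generate_measurements(des, seed = seed)  # 5*3*2*2 = 60 obs
    expect_lte(nrow(tab), 60)
    fit <- fit_full_model(tab)
    expect_true(is.finite(fit$reml_loglik))
    expect_lt(abs(fit$reml_loglik - dense_loglik_at_fit(tab, fit)), 1e-6)
  }
})

test_that("dense optimizer agrees with lme4 on criterion and components", {
  tab <- generate_measurements(small_noisy_design(n_s = 5, n_a = 2, seed = 3),
                               seed = 3)
  f_prod <- fit_full_model(tab, method = "lme4")
  f_dense <- fit_full_model(tab, method = "dense")
  # both should sit at (essentially) the same optimum of the same criterion
  expect_lt(abs(f_prod$reml_loglik - f_dense$reml_loglik), 1e-4)
  expect_equal(f_dense$device_diff, f_prod$device_diff, tolerance = 1e-3)
})

test_that("returned optimum beats probe points around it (local optimality)", {
  tab <- generate_measurements(small_noisy_design(n_s = 5, n_a = 3, seed = 4),
                               seed = 4)
  fit <- fit_full_model(tab)
  base <- dense_loglik_at_fit(tab, fit)
  set.seed(99)
  for (i in 1:20) {
    probe <- fit
    for (nm in c("var_subject", "var_activity", "var_subject_device",
                 "var_subject_activity", "var_device_activity", "var_resid")) {
      probe[[nm]] <- max(fit[[nm]] * runif(1, 0.6, 1.4), 1e-4)
    }
    expect_gte(base + 1e-6, dense_loglik_at_fit(tab, probe))
  }
})

test_that("fit is invariant to row order and label permutation", {
  tab <- generate_measurements(small_noisy_design(seed = 7), seed = 7)
  fit <- fit_full_model(tab)
  df <- as.data.frame(tab)
  set.seed(1)
  shuf <- df[sample(nrow(df)), ]
  fit2 <- fit_full_model(measurement_table(shuf, "reference"))
  relab <- df
  relab$subject <- paste0("zz_", relab$subject)
  relab$activity <- rev_map <- chartr("A", "Q", relab$activity)
  fit3 <- fit_full_model(measurement_table(relab, "reference"))
  for (f2 in list(fit2, fit3)) {
    expect_equal(f2$reml_loglik, fit$reml_loglik, tolerance = 1e-6)
    expect_equal(f2$var_subject, fit$var_subject, tolerance = 1e-5)
    expect_equal(f2$device_diff, fit$device_diff, tolerance = 1e-6)
  }
})

test_that("random terms with one level are dropped with a warning", {
  tab <- toy_table(n_s = 4, n_a = 1, n_r = 3,
                   value_fn = function(s, d, a, r) rnorm(1, 20, 3))
  expect_warning(fit <- fit_full_model(tab), "single activity")
  expect_equal(fit$var_activity, 0)
  expect_equal(fit$var_device_activity, 0)
  expect_true(is.finite(fit$reml_loglik))
})

test_that("differences model: constant differences collapse to the mean", {
  pp <- paired_differences(rep(c("P1", "P2"), each = 3),
                           rep(c("a", "b", "c"), 2), rep(1L, 6),
                           diff = rep(-1.6, 6))
  fit <- fit_diff_model(pp)
  expect_equal(fit$mu0_star, -1.6)
  expect_equal(fit$var_subject_star, 0)
  expect_equal(fit$var_activity_star, 0)
  expect_equal(fit$var_resid_star, 0)
})

test_that("differences-model components are recovered from synthetic data", {
  acts <- lapply(sprintf("A%03d", 1:160), activity_spec)
  pp <- generate_differences(150, acts, mu_star = -1.6,
                             var_subject_star = 1, var_activity_star = 8,
                             var_resid_star = 17, seed = 21)
  fit <- fit_diff_model(pp)
  est <- c(fit$var_subject_star, fit$var_activity_star, fit$var_resid_star)
  expect_true(all(abs(est - c(1, 8, 17)) / c(1, 8, 17) < 0.25))
  expect_equal(fit$mu0_star, -1.6, tolerance = 0.35)
})

test_that("dropping a truly-zero variance term barely moves the criterion", {
  acts <- lapply(sprintf("A%02d", 1:8), activity_spec, reps = 2L)
  des <- synthetic_design(40, acts, mu = 19, device_diff = -1,
                          var_subject = 8, var_activity = 10,
                          var_subject_device = 0,  # true zero
                          var_subject_activity = 4,
                          var_device_activity = 2, var_resid = 6)
  tab <- generate_measurements(des, seed = 31)
  df <- as.data.frame(tab)
  device <- factor(df$device, levels = c("reference", "test"))
  groups_full <- list(
    subject = df$subject, activity = df$activity,
    subject_device = paste(df$subject, df$device),
    subject_activity = paste(df$subject, df$activity),
    device_activity = paste(df$device, df$activity))
  f_full <- reml_fit(df$value, groups_full, device = device)
  f_red <- reml_fit(df$value, groups_full[-3], device = device)
  expect_lt(abs(f_full$reml_loglik - f_red$reml_loglik), 0.5)
})

test_that("fits serialize to JSON with component names and metadata", {
  tab <- generate_measurements(small_noisy_design(seed = 2), seed = 2)
  fit <- fit_full_model(tab)
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$var_subject, fit$var_subject)
  expect_true(is.logical(js$converged))
  expect_equal(js$n_obs, fit$n_obs)
  dm <- fit_diff_model(pair_differences(tab))
  js2 <- jsonlite::fromJSON(fit_to_json(dm))
  expect_equal(js2$mu0_star, dm$mu0_star)
})

test_that("degenerate inputs error cleanly", {
  expect_error(reml_fit(c(1, NA), list(g = c("a", "b"))),
               class = "agreemix_data_error")
  expect_error(reml_fit(rnorm(6), list(g = rep(1:3, 2)),
                        device = factor(rep("only", 6))),
               class = "agreemix_argument_error")
  expect_error(suppressWarnings(reml_fit(1, list())),
               class = "agreemix_data_error")  # n <= p
})
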