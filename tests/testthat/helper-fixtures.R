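# Small in-code fixtures shared across test files.

# A fully balanced toy table: n_s subjects x n_a activities x n_r replicates,
# both devices, values filled by `value_fn(subject, device, activity, rep)`.
toy_table <- function(n_s = 2, n_a = 1, n_r = 1,
                      value_fn = function(s, d, a, r) 7) {
  g <- expand.grid(subject = paste0("P", seq_len(n_s)),
                   device = c("gold", "chest"),
                   activity = paste0("act", seq_len(n_a)),
                   replicate = seq_len(n_r),
                   stringsAsFactors = FALSE)
  g$value <- mapply(value_fn, g$subject, g$device, g$activity, g$replicate)
  measurement_table(g, reference_device = "gold")
}

# COPD-published components, used all over the suite
copd_components <- c(var_subject = 11.4, var_activity = 16.6,
                     var_subject_device = 0.4, var_subject_activity = 6.0,
                     var_device_activity = 3.7, var_resid = 10.5)

copd_full_fit <- function(device_diff = -1.28) {
  full_model_fit(11.4, 16.6, 0.4, 6.0, 3.7, 10.5, device_diff = device_diff)
}

copd_diff_fit <- function() diff_model_fit(-1.60, 0.96, 7.57, 17.37)

# a small noisy design for fitting tests
small_noisy_design <- function(n_s = 6, n_a = 3, seed = 1) {
  acts <- lapply(paste0("A", seq_len(n_a)), activity_spec, reps = 2L)
  synthetic_design(n_s, acts, mu = 19, device_diff = -1.3,
                   var_subject = 8, var_activity = 10,
                   var_subject_device = 0.5, var_subject_activity = 4,
                   var_device_activity = 2, var_resid = 6, seed = seed)
}

write_toy_csv <- function(tab, path = tempfile(fileext = ".csv")) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  path
}
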