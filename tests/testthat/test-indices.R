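# Worked values below are functions of the published COPD variance
# components (11.4, 16.6, 0.4, 6.0, 3.7, 10.5) and mean device difference
# -1.28, all verified by direct arithmetic on those inputs.

test_that("MSD, TDI, CP, CIA, repeatability reproduce the worked values", {
  f <- copd_full_fit()
  m <- msd(f)
  expect_equal(m, 1.28^2 + 2 * (0.4 + 3.7 + 10.5))   # 30.8384
  expect_equal(round(m, 1), 30.8)
  expect_equal(round(tdi(m, 0.95), 1), 10.9)
  expect_equal(round(coverage_probability(m, 5), 2), 0.63)
  expect_equal(round(cia(f), 2), 0.68)
  expect_equal(round(repeatability_coefficient(f), 2), 8.98)
  expect_equal(round(ccc_repeated(f), 3), 0.688)
})

test_that("trivial limits behave: perfect agreement and zero inputs", {
  perfect <- full_model_fit(5, 3, 0, 2, 0, 0, device_diff = 0)
  expect_equal(ccc_repeated(perfect), 1)
  expect_equal(msd(perfect), 0)
  expect_equal(coverage_probability(0, 5), 1)
  expect_equal(coverage_probability(30.84, 1e6), 1)
  expect_equal(tdi(0, 0.95), 0)
  zero <- full_model_fit(0, 0, 0, 0, 0, 0)
  expect_equal(msd(zero), 0)
  expect_equal(repeatability_coefficient(zero), 0)
  expect_error(ccc_repeated(zero), class = "agreemix_argument_error")
  expect_error(cia(zero), class = "agreemix_argument_error")
  only_resid <- full_model_fit(0, 0, 0, 0, 0, 2, device_diff = 0)
  expect_equal(cia(only_resid), 1)   # beta1 = beta2, no device interactions
  expect_equal(repeatability_coefficient(full_model_fit(0, 0, 0, 0, 0, 0.5)),
               1.96)
})

test_that("argument validation on probability and sign constraints", {
  expect_error(coverage_probability(-1, 5), class = "agreemix_argument_error")
  expect_error(coverage_probability(30, -5), class = "agreemix_argument_error")
  expect_error(tdi(30, 1.2), class = "agreemix_argument_error")
  expect_error(tdi(-3, 0.9), class = "agreemix_argument_error")
  expect_error(agreement_settings(cad_delta = -5),
               class = "agreemix_argument_error")
})

test_that("CP/TDI duality holds to machine precision on a grid", {
  for (m in c(0.01, 1, 5.7, 30.84, 400)) {
    for (p in c(0.01, 0.1, 0.5, 0.8, 0.95, 0.999)) {
      expect_equal(coverage_probability(m, tdi(m, p)), p, tolerance = 1e-12)
    }
  }
})

test_that("CP/TDI monotonicity in delta, MSD and p", {
  msds <- c(5, 10, 30.84, 80)
  expect_true(all(diff(sapply(1:8, function(d)
    coverage_probability(30.84, d))) > 0))
  expect_true(all(diff(sapply(msds, function(m)
    coverage_probability(m, 5))) < 0))
  expect_true(all(diff(sapply(c(0.5, 0.8, 0.9, 0.95), function(p)
    tdi(30.84, p))) > 0))
  expect_true(all(diff(sapply(msds, function(m) tdi(m, 0.95))) > 0))
})

test_that("Monte Carlo simulation of model pairs matches MSD and CP closed forms", {
  # independent structural simulation of one time-matched pair per draw:
  # shared subject/activity effects cancel in the difference
  set.seed(202)
  n <- 1e6
  dd <- -1.28
  ab <- sqrt(0.4); bg <- sqrt(3.7); ee <- sqrt(10.5)
  y1 <- -dd / 2 + rnorm(n, 0, ab) + rnorm(n, 0, bg) + rnorm(n, 0, ee)
  y2 <- +dd / 2 + rnorm(n, 0, ab) + rnorm(n, 0, bg) + rnorm(n, 0, ee)
  d <- y2 - y1
  m_formula <- msd(copd_full_fit())
  expect_lt(abs(mean(d^2) - m_formula) / m_formula, 0.01)
  expect_lt(abs(mean(abs(d) < 5) - coverage_probability(m_formula, 5)), 0.003)
  # TDI(0.5) is the median absolute difference
  expect_lt(abs(median(abs(d)) - tdi(m_formula, 0.5)) / tdi(m_formula, 0.5),
            0.01)
})

test_that("CIA monotonicity and invariances", {
  base <- copd_components
  vals <- sapply(c(1, 0.75, 0.5, 0.25), function(scl) {
    cia(full_model_fit(base[1], base[2], scl * base[3], base[4],
                       scl * base[5], base[6], device_diff = -1.28))
  })
  expect_true(all(diff(vals) > 0))  # halving interactions raises CIA
  # CIA invariant to subject and activity variances
  f1 <- copd_full_fit()
  f2 <- full_model_fit(99, 0.1, 0.4, 6.0, 3.7, 10.5, device_diff = -1.28)
  expect_equal(cia(f1), cia(f2))
  # CCC increases in subject variance
  cccs <- sapply(c(5, 11.4, 20, 40), function(vs) {
    ccc_repeated(full_model_fit(vs, 16.6, 0.4, 6.0, 3.7, 10.5,
                                device_diff = -1.28))
  })
  expect_true(all(diff(cccs) > 0))
})

test_that("indices are invariant under device relabeling; LoA bias negates", {
  f <- copd_full_fit(device_diff = -1.28)
  g <- copd_full_fit(device_diff = +1.28)
  expect_equal(msd(f), msd(g))
  expect_equal(ccc_repeated(f), ccc_repeated(g))
  expect_equal(cia(f), cia(g))
  expect_equal(tdi(msd(f), 0.95), tdi(msd(g), 0.95))
  lf <- loa_from_full_model(f); lg <- loa_from_full_model(g)
  expect_equal(lf$bias, -lg$bias)
  expect_equal(lf$upper - lf$lower, lg$upper - lg$lower)
})

test_that("LoA from the differences model reproduces the worked limits", {
  l <- loa_from_diff_model(copd_diff_fit())
  expect_equal(l$bias, -1.60)
  expect_equal(round(l$lower, 2), -11.57)
  expect_equal(round(l$upper, 2), 8.37)  # published 8.38 differs by input rounding
  z <- loa_from_diff_model(diff_model_fit(3, 0, 0, 0))
  expect_equal(c(z$bias, z$lower, z$upper), c(3, 3, 3))
  u <- loa_from_diff_model(diff_model_fit(0, 1, 1, 2), multiplier = 1)
  expect_equal(c(u$lower, u$upper), c(-2, 2))
})

test_that("LoA from the full model matches its algebraic identity", {
  f <- copd_full_fit()
  l <- loa_from_full_model(f)
  expect_equal(l$bias, -1.28)
  expect_equal(round(l$lower, 2), -11.87)
  expect_equal(round(l$upper, 2), 9.31)
  # half-width^2 / m^2 = MSD - bias^2, for any fit
  for (dd in c(-2, 0, 1.5)) {
    ff <- full_model_fit(3, 1, 0.7, 2, 1.1, 4, device_diff = dd)
    ll <- loa_from_full_model(ff, multiplier = 1.96)
    expect_equal(((ll$upper - ll$lower) / 2 / 1.96)^2, msd(ff) - dd^2,
                 tolerance = 1e-12)
  }
  ident <- full_model_fit(3, 1, 0, 2, 0, 0, device_diff = 0)
  li <- loa_from_full_model(ident)
  expect_equal(c(li$bias, li$lower, li$upper), c(0, 0, 0))
})

test_that("naive indices on a hand-checkable toy", {
  # pairs (ref, test): (20,18), (16,14), (24,23), (20,17)
  ref <- c(20, 16, 24, 20); tst <- c(18, 14, 23, 17)
  pp <- paired_differences(paste0("P", 1:4), "a", 1L, diff = tst - ref,
                           avg = (tst + ref) / 2)
  ni <- naive_indices(pp)
  expect_equal(ni$pearson, cor(ref, tst))
  # Lin's CCC with 1/n moments, by direct arithmetic
  s12 <- mean((ref - mean(ref)) * (tst - mean(tst)))
  lin <- 2 * s12 / (mean((ref - mean(ref))^2) + mean((tst - mean(tst))^2) +
                      (mean(ref) - mean(tst))^2)
  expect_equal(ni$lin_ccc, lin)
  expect_equal(ni$simple_loa$bias, mean(tst - ref))
  expect_equal(ni$simple_loa$upper, mean(tst - ref) + 1.96 * sd(tst - ref))
  # identical devices
  pp2 <- paired_differences(paste0("P", 1:4), "a", 1L, diff = rep(0, 4),
                            avg = ref)
  ni2 <- naive_indices(pp2)
  expect_equal(ni2$pearson, 1)
  expect_equal(ni2$lin_ccc, 1)
  expect_equal(c(ni2$simple_loa$lower, ni2$simple_loa$upper), c(0, 0))
  expect_error(naive_indices(pp[1:2, ]), class = "agreemix_data_error")
})

test_that("ANOVA LoA reproduces the hand-worked unbalanced decomposition", {
  pp <- paired_differences(rep(c("P1", "P2"), each = 2), "a", c(1:2, 1:2),
                           diff = c(1, 3, 5, 7))
  l <- anova_loa(pp)
  # MSW = 2, MSB = 16, n0 = 2, sigma_b^2 = 7, SD = 3, bias = 4
  expect_equal(l$bias, 4)
  expect_equal(l$sd, 3)
  expect_equal(round(l$lower, 2), -1.88)
  expect_equal(round(l$upper, 2), 9.88)
  const <- paired_differences(rep(c("P1", "P2"), each = 2), "a", c(1:2, 1:2),
                              diff = rep(2.5, 4))
  lc <- anova_loa(const)
  expect_equal(c(lc$bias, lc$lower, lc$upper), c(2.5, 2.5, 2.5))
  singles <- paired_differences(c("P1", "P2", "P3"), "a", 1L, diff = 1:3)
  expect_error(anova_loa(singles), class = "agreemix_data_error")
})

test_that("build_report verdicts follow the CAD rules", {
  f <- copd_full_fit(); d <- copd_diff_fit()
  rep5 <- build_report(f, d, settings = agreement_settings(cad_delta = 5))
  expect_equal(rep5$verdicts$loa, "do not agree")
  expect_equal(rep5$verdicts$cp, "do not agree")
  expect_equal(rep5$verdicts$tdi, "do not agree")
  expect_equal(rep5$verdicts$cia, "do not agree")
  expect_true(is.na(rep5$verdicts$ccc))       # no CCC threshold supplied
  expect_equal(rep5$provenance$loa, "diff_model")
  # delta = 12 flips the CAD-scale verdicts; CP(12) from MSD 30.84 is 0.969
  rep12 <- build_report(f, d, settings = agreement_settings(cad_delta = 12))
  expect_equal(rep12$verdicts$loa, "agree")
  expect_equal(rep12$verdicts$tdi, "agree")
  expect_equal(round(rep12$indices$cp, 3), 0.969)
  expect_equal(rep12$verdicts$cp, "agree")
  expect_equal(rep12$verdicts$cia, "do not agree")  # CIA does not involve delta
  # perfect agreement: degenerate MSD = 0
  perfect <- full_model_fit(4, 2, 0, 1, 0, 0, device_diff = 0)
  repp <- build_report(perfect, settings = agreement_settings(cad_delta = 5))
  expect_true(repp$degenerate_msd)
  expect_equal(repp$verdicts$loa, "agree")
  expect_equal(repp$verdicts$cp, "agree")
  expect_equal(repp$verdicts$tdi, "agree")
  expect_equal(repp$verdicts$cia, "agree")
  expect_equal(repp$indices$cia, 1)
})

test_that("report serializes to JSON and passes the structural check", {
  f <- copd_full_fit(); d <- copd_diff_fit()
  rep <- build_report(f, d, settings = agreement_settings(cad_delta = 5,
                                                          ccc_threshold = 0.9))
  expect_equal(rep$verdicts$ccc, "do not agree")
  js <- report_to_json(rep)
  expect_true(check_report_json(js))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$indices$msd, msd(f))
  broken <- jsonlite::fromJSON(js)
  broken$indices$cp <- 1.4
  expect_error(check_report_json(broken), class = "agreemix_data_error")
})
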