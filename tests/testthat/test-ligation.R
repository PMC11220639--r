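test_that("accessible_conformers reproduces the threshold table", {
  expect_identical(accessible_conformers(0), c("I", "II", "III", "IV"))
  expect_identical(accessible_conformers(130), "IV")
  expect_identical(accessible_conformers(70), c("III", "IV"))
  expect_identical(accessible_conformers(30), c("II", "III", "IV"))
  expect_error(accessible_conformers(-1), "theta_min")
})

test_that("accessibility is monotone: larger theta_min never grows the set", {
  m <- conformer_model()
  sets <- lapply(seq(0, 175, by = 5), accessible_conformers, model = m)
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("effective_rate combines proportions and rates", {
  k <- 0.01
  m <- conformer_model(rates = rep(k, 4))
  expect_equal(effective_rate(0, m)$k_eff, k)
  expect_equal(effective_rate(130, m)$k_eff, 0.09 * k)
  theta <- seq(0, 175, by = 5)
  ks <- vapply(theta, function(t) effective_rate(t, m)$k_eff, numeric(1))
  expect_true(all(diff(ks) <= 0))
  # at most 4 distinct positive values across all theta_min
  expect_lte(length(unique(ks[ks > 0])), 4L)
})

test_that("repair_fraction follows the pseudo-first-order law", {
  expect_equal(repair_fraction(0, 600, 0.01), 0)
  k <- 0.002
  c50 <- log(2) / (k * 600)
  expect_equal(repair_fraction(c50, 600, k), 0.5)
  conc <- 10^seq(-2, 0.5, by = 0.25)
  f <- repair_fraction(conc, 600, k)
  expect_true(all(diff(f) > 0))
  expect_true(all(f < 1))
  expect_error(repair_fraction(-1, 600, k), ">= 0")
})

test_that("fit_c50 recovers a noiseless generating k_eff to 4 significant figures", {
  m <- conformer_model()
  gel <- simulate_gel_experiment(m, constructs = list(U = bow_construct(Inf)),
                                 noise_sd = 0, seed = 3)
  f <- fit_c50(gel, "U")
  k_true <- gel$truth$k_eff[1]
  expect_equal(f$k_eff, k_true, tolerance = 1e-4)
  expect_equal(f$c50_nM, log(2) / (k_true * 600), tolerance = 1e-4)
  expect_identical(f$flag, "ok")
})

test_that("doubling k_eff halves the fitted C50", {
  conc <- 10^seq(-1.5, 2, length.out = 12)
  mk <- function(k) data.frame(construct = "x", concentration_nM = conc,
                               repaired_fraction = repair_fraction(conc, 600, k))
  f1 <- fit_c50(mk(0.001), "x", time = 600)
  f2 <- fit_c50(mk(0.002), "x", time = 600)
  expect_equal(f1$c50_nM / f2$c50_nM, 2, tolerance = 1e-6)
})

test_that("non-crossing curves are flagged as bounds", {
  conc <- 10^seq(-1.5, 2, length.out = 12)
  low <- data.frame(construct = "x", concentration_nM = conc,
                    repaired_fraction = repair_fraction(conc, 600, 1e-6))
  expect_identical(fit_c50(low, "x", time = 600)$flag, "lower_bound")
  high <- data.frame(construct = "x", concentration_nM = conc,
                     repaired_fraction = repair_fraction(conc, 600, 0.5))
  expect_identical(fit_c50(high, "x", time = 600)$flag, "upper_bound")
  expect_error(fit_c50(low, "missing"), "not in dataset")
})

test_that("fit_c50 recovers k_eff within 3 standard errors at default noise", {
  m <- conformer_model()
  gel <- simulate_gel_experiment(m, seed = 9)
  for (cc in c("L10", "L30", "L80", "unconstrained_0")) {
    f <- fit_c50(gel, cc)
    k_true <- gel$truth$k_eff[gel$truth$construct == cc]
    expect_lt(abs(f$k_eff - k_true), 3 * f$k_se)
  }
})

test_that("detect_plateaus follows the gap rule", {
  expect_identical(detect_plateaus(c(2, 2, 2))$n_plateaus, 1L)
  dp <- detect_plateaus(c(1, 1.05, 10, 10.2))
  expect_identical(dp$n_plateaus, 2L)
  expect_identical(dp$cluster, c(1L, 1L, 2L, 2L))
  expect_error(detect_plateaus(5), "at least 2")
})

test_that("the default pipeline yields 4 plateaus matching the accessibility truth", {
  m <- conformer_model()
  gel <- simulate_gel_experiment(m, seed = 1)
  fits <- lapply(gel$truth$construct, function(cc) fit_c50(gel, cc))
  dp <- detect_plateaus(fits)
  expect_identical(dp$n_plateaus, 4L)
  # clusters must coincide with the partition by accessible-conformer set
  truth_groups <- as.integer(factor(gel$truth$accessible,
                                    levels = unique(gel$truth$accessible)))
  expect_identical(length(unique(paste(dp$cluster, truth_groups))),
                   4L)
})

test_that("spot-field simulation honours its probability model", {
  d1 <- simulate_spot_fields(5, 100, repair_prob = 1, seed = 2)
  expect_true(all(d1$fields$spots_after == 100))
  d2 <- simulate_spot_fields(5, 100, repair_prob = 0, cut_prob = 1, seed = 2)
  expect_true(all(d2$fields$spots_after == 0))
  d3 <- simulate_spot_fields(10, 300, repair_prob = 0, seed = 4)
  surv <- d3$fields$spots_after / d3$fields$spots_before
  se <- sqrt(0.06 * 0.94 / (10 * 300))
  expect_lt(abs(mean(surv) - 0.06), 3 * se)
  expect_error(simulate_spot_fields(0, 100, repair_prob = 0), "n_fields")
  expect_error(simulate_spot_fields(5, 100, repair_prob = 2), "probability")
})

test_that("analyze_spot_fields summarizes surviving fractions", {
  all_live <- data.frame(spots_before = rep(100, 4), spots_after = 100)
  s <- analyze_spot_fields(all_live)
  expect_equal(s$mean_surviving, 1)
  expect_equal(s$sd_surviving, 0)
  control <- data.frame(spots_before = rep(100, 10), spots_after = 6)
  s2 <- analyze_spot_fields(control)
  expect_equal(s2$mean_surviving, 0.06)
  expect_equal(s2$mean_lost, 0.94)
  shuffled <- control[sample(10), ]
  expect_equal(analyze_spot_fields(shuffled)$sd_surviving, s2$sd_surviving)
  with_zero <- rbind(control, data.frame(spots_before = 0, spots_after = 0))
  expect_warning(s3 <- analyze_spot_fields(with_zero), "zero spots")
  expect_identical(s3$n_fields, 10L)
})

test_that("gel simulation matches the deterministic curve at zero noise", {
  m <- conformer_model()
  gel <- simulate_gel_experiment(m, constructs = list(U = bow_construct(Inf)),
                                 noise_sd = 0, n_replicates = 2L, seed = 6)
  expected <- repair_fraction(gel$data$concentration_nM, 600,
                              gel$truth$k_eff[1])
  expect_equal(gel$data$repaired_fraction, expected, tolerance = 1e-12)
  expect_true(all(diff(unique(gel$data$concentration_nM)) > 0))
})

test_that("a fully blocked construct repairs nothing", {
  m <- conformer_model(thresholds = c(20, 60, 100, 120))
  gel <- simulate_gel_experiment(m, constructs = list(B = bow_construct(10)),
                                 noise_sd = 0, seed = 7)
  expect_identical(gel$truth$accessible[1], "")
  expect_true(all(gel$data$repaired_fraction == 0))
})

test_that("unconstrained dose-response is strictly increasing without noise", {
  m <- conformer_model()
  gel <- simulate_gel_experiment(m, constructs = list(U = bow_construct(Inf)),
                                 noise_sd = 0, n_replicates = 1L, seed = 8)
  expect_true(all(diff(gel$data$repaired_fraction) > 0))
})

test_that("conformer_model validates its inputs", {
  expect_error(conformer_model(proportions = c(0.5, 0.5, 0.1, -0.1)),
               "non-negative")
  expect_error(conformer_model(thresholds = c(60, 20, 100, Inf)),
               "non-decreasing")
  expect_error(conformer_model(angles = c(0, 60, 90, 100)),
               "below its threshold")
  expect_error(conformer_model(rates = c(-1, 1, 1, 1) * 0.001), "rates")
})
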