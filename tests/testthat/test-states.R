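fake_fit <- function(means, lens = rep(40L, length(means))) {
  ends <- cumsum(lens)
  starts <- c(0L, ends[-length(ends)])
  structure(list(plateaus = data.frame(start = starts, end = ends,
                                       mean = means),
                 rss = 0, n_steps = length(means) - 1L,
                 quality = numeric(0), selected_steps = 0L),
            class = "step_fit")
}

fake_states <- function(centers = c(0.27, 0.42, 0.67, 0.88),
                        hw = 0.05) {
  structure(list(centers = centers, sds = rep(0.02, length(centers)),
                 weights = rep(1 / length(centers), length(centers)),
                 assignment_halfwidth = hw, k = length(centers),
                 bic = NULL),
            class = "state_model")
}

test_that("a single tight cluster yields one center", {
  set.seed(1)
  s <- locate_state_peaks(rnorm(100, 0.5, 0.005))
  expect_identical(s$k, 1L)
  expect_equal(s$centers, 0.5, tolerance = 0.01)
})

test_that("four well-separated clusters are recovered within 0.01", {
  set.seed(2)
  x <- c(rnorm(200, 0.2, 0.02), rnorm(150, 0.4, 0.02),
         rnorm(100, 0.6, 0.02), rnorm(80, 0.85, 0.02))
  s <- locate_state_peaks(x)
  expect_identical(s$k, 4L)
  expect_lt(max(abs(s$centers - c(0.2, 0.4, 0.6, 0.85))), 0.01)
  expect_true(all(diff(s$centers) > 0))
})

test_that("too few plateau means is an error", {
  expect_error(locate_state_peaks(c(0.2, 0.4)), "too few")
})

test_that("trivial pattern calls follow the definitions", {
  st <- fake_states()
  expect_identical(classify_trace(fake_fit(c(0.27, 0.28, 0.26)), st)$pattern,
                   "I")
  a <- classify_trace(fake_fit(c(0.27, 0.67, 0.27, 0.67)), st)
  expect_identical(a$pattern, "III")
  expect_identical(a$n_excursions, 2L)
  expect_identical(a$visited_states, 3L)
  expect_identical(classify_trace(fake_fit(c(0.27, 0.42, 0.67, 0.27)),
                                  st)$pattern,
                   "mixed")
  expect_identical(classify_trace(fake_fit(c(0.27, 0.88, 0.27)), st)$pattern,
                   "IV")
})

test_that("a long out-of-window plateau voids the trace, a short one is ignored", {
  st <- fake_states()
  expect_identical(classify_trace(fake_fit(c(0.27, 0.55, 0.27)), st)$pattern,
                   "unassigned")
  short_mid <- fake_fit(c(0.27, 0.55, 0.27), lens = c(40L, 5L, 40L))
  expect_identical(classify_trace(short_mid, st)$pattern, "I")
})

test_that("short plateaus cannot establish a state visit on their own", {
  st <- fake_states()
  # 5-frame excursion-like plateau inside the 0.42 window, never seen long
  flicker <- fake_fit(c(0.27, 0.67, 0.43, 0.67, 0.27),
                      lens = c(60L, 40L, 5L, 40L, 60L))
  a <- classify_trace(flicker, st)
  expect_identical(a$pattern, "III")
  # short recurrences of an established state still count
  recur <- fake_fit(c(0.27, 0.67, 0.27, 0.67), lens = c(60L, 40L, 60L, 6L))
  expect_identical(classify_trace(recur, st)$n_excursions, 2L)
  # only-short high evidence: unresolved dynamics
  only_short <- fake_fit(c(0.27, 0.67, 0.27), lens = c(80L, 6L, 80L))
  expect_identical(classify_trace(only_short, st)$pattern, "unassigned")
})

test_that("pattern_percentages handles degenerate and seeded cases", {
  mk <- function(p) structure(list(trace_id = "t", pattern = p,
                                   visited_states = integer(0),
                                   n_excursions = 0L,
                                   plateau_states = NA_integer_),
                              class = "pattern_assignment")
  all_i <- replicate(10, mk("I"), simplify = FALSE)
  pct <- pattern_percentages(all_i, seed = 3)
  expect_equal(pct$fraction, c(1, 0, 0, 0, 0))
  expect_equal(pct$lower, pct$upper)
  a <- pattern_percentages(c(all_i, list(mk("II"), mk("mixed"))), seed = 7)
  b <- pattern_percentages(c(all_i, list(mk("II"), mk("mixed"))), seed = 7)
  expect_identical(a, b)
  expect_error(pattern_percentages(list(mk("unassigned"))), "no assigned")
})

test_that("the pipeline classifies a parallel ensemble without miscalls", {
  p <- trace_gen_params()
  ens <- simulate_trace_ensemble(p, 150, seed = 11)
  res <- suppressWarnings(analyze_trace_ensemble(ens))
  truth <- attr(ens, "manifest")$true_pattern
  called <- vapply(res$assignments, function(a) a$pattern, character(1))
  ok <- called != "unassigned"
  expect_gt(mean(ok), 0.9)
  expect_true(all(called[ok] == truth[ok]))
  expect_lt(max(abs(res$states$centers - p$state_efficiencies)), 0.03)
})

test_that("classification is stable under trace-order permutation", {
  p <- trace_gen_params()
  ens <- simulate_trace_ensemble(p, 40, seed = 13)
  res <- suppressWarnings(analyze_trace_ensemble(ens))
  rev_ens <- rev(ens)
  attr(rev_ens, "manifest") <- attr(ens, "manifest")[40:1, ]
  res_rev <- suppressWarnings(analyze_trace_ensemble(rev_ens))
  pats <- vapply(res$assignments, function(a) a$pattern, character(1))
  pats_rev <- vapply(res_rev$assignments, function(a) a$pattern, character(1))
  expect_identical(pats, rev(pats_rev))
})

test_that("the sequential null produces mixed traces and a valid p-value", {
  p <- trace_gen_params(topology = "sequential")
  ens <- simulate_trace_ensemble(p, 120,
                                 pattern_proportions = c(0, 1 / 3, 1 / 3, 1 / 3),
                                 seed = 7)
  res <- suppressWarnings(analyze_trace_ensemble(ens))
  called <- vapply(res$assignments, function(a) a$pattern, character(1))
  called <- called[called != "unassigned"]
  expect_gt(mean(called == "mixed"), 0.5)
  expect_error(
    parallel_vs_sequential_statistic(res$assignments, p, n_null = 0),
    "n_null")
})
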