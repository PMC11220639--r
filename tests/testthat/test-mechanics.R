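test_that("chord length follows the hinge geometry", {
  b30 <- bow_construct(30)
  expect_equal(chord_length(0, b30), 2 * 25 * 0.34)
  expect_equal(chord_length(180, b30), 0, tolerance = 1e-12)
  expect_equal(chord_length(60, b30), 17 * cos(pi / 6), tolerance = 1e-9)
  theta <- seq(0, 180, by = 5)
  expect_true(all(diff(chord_length(theta, b30)) < 0))
  expect_error(chord_length(-1, b30), "0, 180")
})

test_that("bow_construct handles unconstrained and invalid linkers", {
  expect_true(bow_construct(Inf)$unconstrained)
  expect_true(bow_construct(NA)$unconstrained)
  expect_false(bow_construct(10)$unconstrained)
  expect_error(bow_construct(-1), "linker_nt")
  expect_error(ssdna_params(contour_per_nt = 0), "positive")
})

test_that("FJC radial density normalizes and respects finite extensibility", {
  ss <- ssdna_params()
  r <- seq(0, 60, by = 0.05)
  for (nt in c(10, 80)) {
    dens <- fjc_radial_density(r, nt, ss, seed = 2)
    expect_equal(sum(dens) * 0.05, 1, tolerance = 0.02)
    contour <- ceiling(nt * ss$contour_per_nt / ss$kuhn_length) *
      ss$kuhn_length
    expect_true(all(dens[r > contour] == 0))
  }
  expect_error(fjc_radial_density(1, 0), "degenerate")
  expect_error(fjc_radial_density(-1, 10), "r")
})

test_that("FJC second moment matches N b^2 (Gaussian-chain limit)", {
  ss <- ssdna_params()
  nt <- 200                       # N = 84 Kuhn segments
  N <- ceiling(nt * ss$contour_per_nt / ss$kuhn_length)
  r <- seq(0, N * ss$kuhn_length, length.out = 4000)
  dens <- fjc_radial_density(r, nt, ss, seed = 5)
  m2 <- sum(r^2 * dens) * diff(r[1:2])
  expect_equal(m2, N * ss$kuhn_length^2, tolerance = 0.05)
  g <- fjc_radial_density(r, nt, ss, backend = "gaussian")
  m2g <- sum(r^2 * g) * diff(r[1:2])
  expect_equal(m2g, N * ss$kuhn_length^2, tolerance = 0.01)
})

test_that("bend-angle distribution normalizes; degenerate cases behave", {
  d <- bend_angle_distribution(bow_construct(30), seed = 3)
  expect_equal(sum(d$density) * diff(d$theta[1:2]), 1, tolerance = 1e-9)
  expect_equal(max(d$cdf), 1, tolerance = 1e-12)
  # zero-length linker: all mass at the folded end
  d0 <- bend_angle_distribution(bow_construct(0))
  expect_gt(d0$theta[which.max(d0$density)], 179)
  # unconstrained: free-hinge law, density proportional to sin(180 - theta)
  du <- bend_angle_distribution(bow_construct(Inf))
  ref <- sin((180 - du$theta) * pi / 180)
  ref <- ref / sum(ref) / diff(du$theta[1:2])
  expect_lt(max(abs(du$density - ref)), 1e-9)
})

test_that("a very long linker approaches the free-hinge law (TV < 0.05)", {
  d <- bend_angle_distribution(bow_construct(4000), backend = "gaussian")
  ref <- sin((180 - d$theta) * pi / 180)
  ref <- ref / sum(ref)
  p <- d$density * diff(d$theta[1:2])
  expect_lt(0.5 * sum(abs(p - ref)), 0.05)
})

test_that("bend-angle distribution matches a brute-force Monte-Carlo oracle", {
  # Oracle: draw hinge angles from the free solid-angle law, weight each
  # by an independent kernel estimate of the chain end-to-end density at
  # the required chord; compare on a 1 degree grid in total variation.
  ss <- ssdna_params()
  for (nt in c(10, 30, 80)) {
    con <- bow_construct(nt)
    d <- bend_angle_distribution(con, seed = 6)
    set.seed(1000 + nt)
    N <- ceiling(nt * ss$contour_per_nt / ss$kuhn_length)
    b <- ss$kuhn_length
    n_chain <- 2e5
    z <- matrix(runif(n_chain * N, -1, 1), n_chain, N)
    phi <- matrix(runif(n_chain * N, 0, 2 * pi), n_chain, N)
    s <- sqrt(1 - z^2)
    r_chain <- b * sqrt(rowSums(s * cos(phi))^2 +
                          rowSums(s * sin(phi))^2 + rowSums(z)^2)
    n_hinge <- 4e5
    inter <- acos(runif(n_hinge, -1, 1))          # solid-angle law
    theta_h <- 180 - inter * 180 / pi
    chord <- 2 * arm_length_nm(con) * cos(theta_h * pi / 360)
    # chain-distance counts on a fine grid, looked up per hinge sample
    r_brks <- seq(0, N * b + 0.1, by = 0.1)
    r_counts <- tabulate(findInterval(r_chain, r_brks),
                         nbins = length(r_brks))
    # closure weight: chain density per volume at the chord displacement
    wts <- r_counts[findInterval(chord, r_brks)] / pmax(chord, 1e-9)^2
    brks <- seq(0, 180, by = 1)
    oracle <- vapply(seq_len(180), function(i) {
      sum(wts[theta_h >= brks[i] & theta_h < brks[i + 1]])
    }, numeric(1))
    oracle <- oracle / sum(oracle)
    pkg <- vapply(seq_len(180), function(i) {
      sum(d$density[d$theta >= brks[i] & d$theta < brks[i + 1]])
    }, numeric(1))
    pkg <- pkg / sum(pkg)
    expect_lt(0.5 * sum(abs(pkg - oracle)), 0.05)
  }
})

test_that("min_bend_angle is monotone in linker length and quantile", {
  grid <- c(10, 15, 20, 25, 30, 40, 50, 60, 80)
  th <- vapply(grid, function(nt) min_bend_angle(bow_construct(nt), seed = 9),
               numeric(1))
  expect_true(all(diff(th) <= 0))
  con <- bow_construct(30)
  q <- c(2e-4, 1e-3, 1e-2, 0.1)
  thq <- vapply(q, function(qq) min_bend_angle(con, quantile = qq, seed = 9),
                numeric(1))
  expect_true(all(diff(thq) >= 0))
  expect_identical(min_bend_angle(bow_construct(Inf)), 0)
  expect_error(min_bend_angle(con, quantile = 0), "quantile")
  expect_error(min_bend_angle(con, quantile = 0.6), "quantile")
})

test_that("fret_vs_angle is calibrated, monotone, and matches the closed form", {
  expect_equal(fret_vs_angle(0), 0.27, tolerance = 1e-9)
  theta <- seq(0, 179, by = 1)
  expect_true(all(diff(fret_vs_angle(theta)) > 0))
  # hand evaluation: r = 7.14 cos(50 deg), R0 = 7.14 / (1/0.27 - 1)^(1/6)
  r <- 21 * 0.34 * cos(50 * pi / 180)
  r0 <- 21 * 0.34 / (1 / 0.27 - 1)^(1 / 6)
  expect_equal(fret_vs_angle(100), 1 / (1 + (r / r0)^6), tolerance = 1e-12)
  expect_equal(fret_vs_angle(100), 0.839838, tolerance = 1e-5)
  expect_error(fret_vs_angle(180), "0, 180")
})

test_that("conformer angles map to strictly increasing efficiencies", {
  geom <- conformer_geometry()
  e <- fret_vs_angle(geom$angles, geom)
  expect_true(all(diff(e) > 0))
  expect_equal(e[1], 0.27, tolerance = 1e-9)
})

test_that("Forster-radius calibration inverts the efficiency anchor", {
  r0 <- calibrate_forster_radius(e_straight = 0.4)
  geom <- conformer_geometry(forster_radius = r0)
  expect_equal(fret_vs_angle(0, geom), 0.4, tolerance = 1e-12)
})
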