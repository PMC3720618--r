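test_that("degenerate and targeted occupancies behave as specified", {
  tr <- sim_hbond_trajectory(
    tibble::tibble(label = "c", mean_distance = 1.8, sd = 0,
                   target_occupancy = 1),
    n_snapshots = 100, seed = 1)
  expect_true(all(tr$c == 1.8))
  expect_equal(hbond_stats(tr)$occupancy, 100)

  tr2 <- sim_hbond_trajectory(
    tibble::tibble(label = "p", mean_distance = 3.3, sd = 0.4,
                   target_occupancy = 0.70),
    n_snapshots = 10000, seed = 5)
  occ <- mean(tr2$p < 3.5)   # counting oracle
  expect_gte(occ, 0.68)
  expect_lte(occ, 0.72)
  expect_true(all(tr2$p > 0))
})

test_that("trajectory generation is deterministic in the seed", {
  pairs <- tibble::tibble(label = "x", mean_distance = 2.5, sd = 0.3,
                          target_occupancy = 0.9)
  a <- sim_hbond_trajectory(pairs, 200, seed = 77)
  b <- sim_hbond_trajectory(pairs, 200, seed = 77)
  expect_identical(a, b)
  c <- sim_hbond_trajectory(pairs, 200, seed = 78)
  expect_false(identical(a, c))
})

test_that("occupancy calibration holds across a grid of targets", {
  targets <- c(0.1, 0.25, 0.5, 0.7, 0.8, 0.9, 0.95, 0.99)
  pairs <- tibble::tibble(label = sprintf("t%02d", seq_along(targets)),
                          mean_distance = 2.5, sd = 0.35,
                          target_occupancy = targets)
  tr <- sim_hbond_trajectory(pairs, 4000, seed = 13)
  emp <- vapply(pairs$label, function(lb) mean(tr[[lb]] < 3.5), numeric(1))
  expect_true(all(abs(emp - targets) <= 0.02))
})

test_that("unreachable occupancies raise errors naming the pair", {
  expect_error(
    sim_hbond_trajectory(tibble::tibble(label = "bad", mean_distance = 1.8,
                                        sd = 0, target_occupancy = 0.5),
                         100, seed = 1),
    "bad")
  expect_error(
    sim_hbond_trajectory(tibble::tibble(label = "p1", mean_distance = 2,
                                        sd = 0.2, target_occupancy = 1),
                         100, seed = 1),
    "p1")
  expect_error(
    sim_hbond_trajectory(tibble::tibble(label = c("a", "a"),
                                        mean_distance = 2, sd = 0.1),
                         10, seed = 1),
    "unique")
})

test_that("umbrella sampler matches the harmonic closed form", {
  uw <- sim_umbrella_windows(function(x) 0 * x, centers = 1.3,
                             force_constants = 10, n_samples = 50000,
                             burn_in = 1000, seed = 3)
  s <- uw$windows$samples[[1]]
  target_var <- kT(298.15) / 10
  expect_lt(abs(var(s) - target_var) / target_var, 0.05)
  tau <- ess_tau(s)
  se <- sqrt(target_var * tau / length(s))
  expect_lt(abs(mean(s) - 1.3), 3 * se)
})

test_that("biased windows on a harmonic landscape are pulled toward the minimum", {
  # U = x^2 (k0 = 2); bias k = 10 at centers +-1: product-Gaussian mean
  # k*c/(k0 + k) = 10/12 * c
  uw <- sim_umbrella_windows(c(0, 0, 1), centers = c(-1, 1),
                             force_constants = 10, n_samples = 30000,
                             burn_in = 1000, seed = 8)
  for (i in 1:2) {
    s <- uw$windows$samples[[i]]
    expected <- 10 / 12 * uw$windows$center[i]
    se <- sqrt(var(s) * ess_tau(s) / length(s))
    expect_lt(abs(mean(s) - expected), 4 * se)
  }
})

test_that("umbrella generation is reproducible and reports acceptance", {
  a <- sim_umbrella_windows(c(0, 0, 1), centers = c(0, 0.5),
                            force_constants = 5, n_samples = 2000, seed = 4)
  b <- sim_umbrella_windows(c(0, 0, 1), centers = c(0, 0.5),
                            force_constants = 5, n_samples = 2000, seed = 4)
  expect_identical(a$windows$samples, b$windows$samples)
  expect_true(all(a$windows$acceptance > 0 & a$windows$acceptance < 1))

  expect_error(
    sim_umbrella_windows(c(0, 0, 1e8), centers = 0, force_constants = 1,
                         n_samples = 300, burn_in = 10,
                         proposal_width = 50, seed = 2),
    "proposal_width")
})

test_that("umbrella window files round-trip through the metadata convention", {
  uw <- sim_umbrella_windows(c(0, 0, 1), centers = c(-0.5, 0, 0.5),
                             force_constants = c(4, 8, 4),
                             n_samples = 500, burn_in = 100, seed = 21)
  dir <- withr::local_tempdir()
  meta <- write_umbrella(uw, dir)
  back <- read_umbrella(meta)
  expect_equal(back$windows$center, uw$windows$center)
  expect_equal(back$windows$force_constant, uw$windows$force_constant)
  expect_equal(back$temperature, uw$temperature)
  expect_equal(back$bias_convention, uw$bias_convention)
  for (i in 1:3) {
    expect_equal(back$windows$samples[[i]], uw$windows$samples[[i]],
                 tolerance = 1e-9)
  }
})

test_that("planted conformer tables are recovered exactly by the triage", {
  tab <- sim_conformer_table(18, planted = c("M14", "M15"), seed = 1)
  sel <- suppressMessages(select_conformers(tab))
  expect_setequal(sel$id, c("M14", "M15"))
  expect_setequal(oracle_conformer_gates(tab), c("M14", "M15"))

  one <- sim_conformer_table(1, planted = "only", seed = 2)
  expect_identical(suppressWarnings(
    suppressMessages(select_conformers(one)))$id, "only")

  s1 <- suppressMessages(select_conformers(sim_conformer_table(18, "A", seed = 10)))
  s2 <- suppressMessages(select_conformers(sim_conformer_table(18, "A", seed = 20)))
  expect_identical(sort(s1$id), sort(s2$id))

  expect_error(sim_conformer_table(1, c("a", "b"), seed = 1), "too small")
})

test_that("simulated progress curves include paired backgrounds and closed forms", {
  # no enzyme, no autoxidation: flat at zero
  p0 <- rate_params(k_auto = 0)
  fam0 <- sim_progress_curves(0.5, 0, seq(0, 10, 1), params = p0, seed = 1)
  expect_true(all(abs(fam0$signal) < 1e-10))

  # no enzyme, autoxidation only: S0 (1 - exp(-k t))
  p1 <- rate_params(k_auto = 0.02)
  fam1 <- sim_progress_curves(0.8, 0, seq(0, 50, 1), params = p1, seed = 1)
  bg <- fam1[fam1$background, ]
  expect_equal(bg$signal, 0.8 * (1 - exp(-0.02 * bg$time_min)),
               tolerance = 1e-8)

  # a background row accompanies every substrate concentration
  fam2 <- sim_progress_curves(c(0.3, 0.6), c(1, 5), seq(0, 5, 1),
                              params = p1, seed = 1)
  expect_setequal(unique(fam2$s0_uM[fam2$background]), c(0.3, 0.6))

  # seeded noise is reproducible
  n1 <- sim_progress_curves(0.4, 2, seq(0, 5, 0.5), noise_sd = 0.01, seed = 6)
  n2 <- sim_progress_curves(0.4, 2, seq(0, 5, 0.5), noise_sd = 0.01, seed = 6)
  expect_identical(n1, n2)
})
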