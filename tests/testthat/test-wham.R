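harmonic_windows <- function(seed = 5, n_samples = 10000) {
  # true potential U(x) = x^2, i.e. harmonic with curvature k0 = 2
  sim_umbrella_windows(c(0, 0, 1), centers = seq(-2, 2, 0.2),
                       force_constants = 10, n_samples = n_samples,
                       burn_in = 500, seed = seed)
}

test_that("unbiasing a single window on a flat landscape yields a flat profile", {
  uw <- sim_umbrella_windows(function(x) 0 * x, centers = 0,
                             force_constants = 1, n_samples = 20000,
                             burn_in = 500, proposal_width = 1, seed = 17)
  prof <- pmf_wham(uw, bin_width = 0.25)
  ok <- !is.na(prof$free_energy) & prof$count >= 200
  w <- prof$free_energy[ok]
  tau <- ess_tau(uw$windows$samples[[1]])
  noise <- kT(298.15) * sqrt(tau / min(prof$count[ok]))
  expect_lt(max(w) - min(w), 3 * 2 * noise)
})

test_that("WHAM recovers a known harmonic potential", {
  prof <- pmf_wham(harmonic_windows(), bin_width = 0.1)
  expect_true(attr(prof, "converged"))
  ok <- !is.na(prof$free_energy) & prof$count >= 25
  truth <- prof$coordinate[ok]^2
  w <- prof$free_energy[ok]
  off <- mean(w - truth)
  expect_lt(sqrt(mean((w - truth - off)^2)), 0.2)
})

test_that("WHAM recovers a double-well barrier within 0.3 kcal/mol", {
  # U(x) = 3 ((x)^2 - 1)^2: minima at +-1, barrier 3 at x = 0
  uw <- sim_umbrella_windows(c(3, 0, -6, 0, 3), centers = seq(-1.8, 1.8, 0.15),
                             force_constants = 20, n_samples = 10000,
                             burn_in = 500, proposal_width = 0.3, seed = 11)
  prof <- pmf_wham(uw, bin_width = 0.1)
  ok <- !is.na(prof$free_energy) & prof$count >= 25
  truth <- 3 * (prof$coordinate[ok]^2 - 1)^2
  w <- prof$free_energy[ok]
  off <- mean(w - truth)
  expect_lt(sqrt(mean((w - truth - off)^2)), 0.3)
  barrier <- prof$free_energy[which.min(abs(prof$coordinate))] -
    min(prof$free_energy, na.rm = TRUE)
  expect_lt(abs(barrier - 3), 0.3)
})

test_that("profile is gauge-invariant and independent of window order", {
  uw <- harmonic_windows(seed = 23, n_samples = 4000)
  prof <- pmf_wham(uw, bin_width = 0.1)

  # shifting the whole potential by a constant leaves the biased densities,
  # hence the samples and the profile, untouched
  uw_shift <- sim_umbrella_windows(c(7, 0, 1), centers = seq(-2, 2, 0.2),
                                   force_constants = 10, n_samples = 4000,
                                   burn_in = 500, seed = 23)
  expect_identical(uw_shift$windows$samples, uw$windows$samples)
  expect_equal(pmf_wham(uw_shift, bin_width = 0.1)$free_energy,
               prof$free_energy)

  perm <- withr::with_seed(99, sample(nrow(uw$windows)))
  uw_perm <- umbrella_windows(
    centers = uw$windows$center[perm],
    force_constants = uw$windows$force_constant[perm],
    samples = uw$windows$samples[perm],
    temperature = uw$temperature, bias = uw$bias_convention)
  prof_perm <- pmf_wham(uw_perm, bin_width = 0.1)
  expect_equal(prof_perm$free_energy, prof$free_energy, tolerance = 1e-5)
})

test_that("fixed-point WHAM agrees with the convex-minimization oracle", {
  uw <- harmonic_windows(seed = 41, n_samples = 3000)
  prof <- pmf_wham(uw, bin_width = 0.1, tol = 1e-10)
  ora <- oracle_wham(uw, bin_width = 0.1)
  got <- prof[!is.na(prof$free_energy), ]
  expect_equal(got$coordinate, ora$coordinate, tolerance = 1e-9)
  expect_lt(max(abs(got$free_energy - ora$free_energy)), 1e-3)
})

test_that("parameter recovery holds across independent seeds", {
  hits <- 0
  for (seed in 101:105) {
    prof <- pmf_wham(harmonic_windows(seed = seed, n_samples = 6000),
                     bin_width = 0.1)
    ok <- !is.na(prof$free_energy) & prof$count >= 25
    truth <- prof$coordinate[ok]^2
    w <- prof$free_energy[ok]
    off <- mean(w - truth)
    if (sqrt(mean((w - truth - off)^2)) < 0.2) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("non-overlapping windows fail loudly; unsampled bins are missing, not zero", {
  gap <- umbrella_windows(centers = c(0, 4), force_constants = 10,
                          samples = list(stats::rnorm(100, 0, 0.1),
                                         stats::rnorm(100, 4, 0.1)))
  expect_error(pmf_wham(gap, bin_width = 0.1), "do not overlap")

  holey <- umbrella_windows(centers = 0, force_constants = 1,
                            samples = list(c(rep(0.05, 40), rep(0.35, 60))))
  prof <- pmf_wham(holey, bin_width = 0.1)
  mid <- prof$count == 0
  expect_true(any(mid))
  expect_true(all(is.na(prof$free_energy[mid])))
  expect_equal(min(prof$free_energy, na.rm = TRUE), 0)
})

test_that("iteration cap flags non-convergence instead of erroring", {
  uw <- harmonic_windows(seed = 3, n_samples = 1500)
  expect_warning(prof <- pmf_wham(uw, bin_width = 0.1, max_iter = 2),
                 "did not converge")
  expect_false(attr(prof, "converged"))
})

test_that("binding free energy is minus the plateau height over the minimum", {
  x <- seq(0, 30, by = 0.1)
  flatten <- function(height) height * pmin(1, x / 15)^2
  mk <- function(w) tibble::tibble(coordinate = x, free_energy = w,
                                   count = rep(100L, length(x)))
  expect_equal(pmf_binding_energy(mk(rep(0, length(x))), plateau_span = 5), 0)
  expect_equal(pmf_binding_energy(mk(flatten(10.2)), plateau_span = 5), -10.2,
               tolerance = 0.05)
  expect_equal(pmf_binding_energy(mk(flatten(13.1)), plateau_span = 5), -13.1,
               tolerance = 0.05)

  ramp <- mk(x)   # never levels off
  expect_warning(pmf_binding_energy(ramp, plateau_span = 5), "not converged")
  expect_error(pmf_binding_energy(mk(rev(x)), plateau_span = 40), "extends only")
})

test_that("sub-fraction reanalysis is flat for converged sampling and flags starvation", {
  uw <- harmonic_windows(seed = 29, n_samples = 10000)
  cv <- pmf_convergence(uw, fractions = c(1, 1), bin_width = 0.1)
  expect_equal(cv$max_deviation, 0)

  cv3 <- pmf_convergence(uw, fractions = c(0.6, 0.8, 1.0), bin_width = 0.1)
  expect_lt(cv3$max_deviation, 0.2)

  starved <- harmonic_windows(seed = 59, n_samples = 700)
  cv_bad <- pmf_convergence(starved, fractions = c(0.1, 1.0), bin_width = 0.1,
                            min_count = 1)
  expect_gt(cv_bad$max_deviation, 0.2)
})

test_that("tidy, glance and the TSV writer expose the profile faithfully", {
  prof <- pmf_wham(harmonic_windows(seed = 2, n_samples = 2000), bin_width = 0.2)
  td <- tidy(prof)
  expect_named(td, c("coordinate", "free_energy", "count"))
  gl <- glance(prof)
  expect_true(gl$converged)
  expect_equal(gl$temperature, 298.15)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_pmf(prof, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$free_energy, prof$free_energy, tolerance = 1e-9)
})
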