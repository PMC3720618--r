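test_that("enzyme-free limits follow the autoxidation closed form", {
  p <- rate_params(k_auto = 0)
  pc <- simulate_progress(p, s0 = 0.5, e0 = 0, times = seq(0, 20, 0.5))
  expect_true(all(abs(pc$signal) < 1e-9))

  p2 <- rate_params(k_auto = 0.02)
  pc2 <- simulate_progress(p2, s0 = 0.5, e0 = 0, times = seq(0, 60, 1))
  expect_equal(pc2$signal, 0.5 * (1 - exp(-0.02 * pc2$time_min)),
               tolerance = 1e-6)
})

test_that("ligand and enzyme conservation hold to 1e-6 relative at all times", {
  grid <- expand.grid(s0 = c(0.34, 1), e0 = c(0.00322, 0.09666))
  for (i in seq_len(nrow(grid))) {
    pc <- simulate_progress(rate_params(), grid$s0[i], grid$e0[i],
                            times = seq(0, 90, 0.5))
    lig <- pc$S + pc$ES + pc$EP + pc$EPinh + pc$P
    enz <- pc$E + pc$ES + pc$EP + pc$EPinh
    expect_lt(max(abs(lig - grid$s0[i])) / grid$s0[i], 1e-6)
    expect_lt(max(abs(enz - grid$e0[i])) / grid$e0[i], 1e-6)
  }
})

test_that("the Michaelis-Menten limit is recovered when rebinding is ablated", {
  p <- rate_params(k_rel = 1e4, k_on_p = 0, k_off_p = 0, k_auto = 0)
  km_eff <- (p$k_off_s + p$k_cat) / p$k_on_s
  for (s0 in c(0.2, 0.5, 1.5)) {
    for (e0 in c(5e-4, 2e-3, 5e-3)) {
      pc <- simulate_progress(p, s0, e0, times = seq(0, 0.2, 0.01))
      i <- nrow(pc)
      v_obs <- p$k_cat * pc$ES[i]
      v_mm <- p$k_cat * e0 * pc$S[i] / (km_eff + pc$S[i])
      expect_lt(abs(v_obs - v_mm) / v_mm, 0.01)
    }
  }
})

test_that("noise-free product signal is non-decreasing", {
  pc <- simulate_progress(rate_params(), 0.34, 0.032, seq(0, 120, 0.5))
  expect_true(all(diff(pc$signal) > -1e-9))
})

test_that("slow-release tight-binding runs always decelerate", {
  p <- rate_params(k_rel = 0.3, k_on_p = 0.5, k_auto = 0)  # k_rel = 0.1 k_cat
  for (e0 in c(0.002, 0.01, 0.05)) {
    pc <- simulate_progress(p, 0.34, e0, seq(0, 120, 0.5))
    vr <- analyze_velocities(pc)
    expect_lte(vr$v_steady, vr$v0 + 1e-9)
  }
})

test_that("background subtraction is exact, linear and interpolation-aware", {
  p <- rate_params(k_auto = 0.01)
  pc <- simulate_progress(p, 0.4, 0.003, seq(0, 60, 0.5))
  zero <- subtract_background(pc, pc)
  expect_true(all(abs(zero$signal) < 1e-12))
  expect_true(attr(zero, "background_subtracted"))

  # enzyme+auto minus auto-only ~ enzyme-only in the small-k_auto limit
  p_small <- rate_params(k_auto = 1e-4)
  both <- simulate_progress(p_small, 0.4, 0.003, seq(0, 30, 0.5))
  bg <- simulate_progress(p_small, 0.4, 0, seq(0, 30, 0.5))
  enz_only <- simulate_progress(rate_params(k_auto = 0), 0.4, 0.003,
                                seq(0, 30, 0.5))
  diffc <- subtract_background(both, bg)
  expect_lt(max(abs(diffc$signal - enz_only$signal)), 2e-3)

  # mismatched grids: explicit error, then linear interpolation against the
  # analytic difference of the two closed forms
  fine <- simulate_progress(rate_params(k_auto = 0.02), 0.8, 0, seq(0, 30, 0.25))
  coarse <- simulate_progress(rate_params(k_auto = 0.05), 0.8, 0, seq(0, 30, 1))
  expect_error(subtract_background(fine, coarse), "interpolate")
  sub <- subtract_background(fine, coarse, interpolate = TRUE)
  analytic <- 0.8 * (1 - exp(-0.02 * fine$time_min)) -
    0.8 * (1 - exp(-0.05 * fine$time_min))
  expect_lt(max(abs(sub$signal - analytic)), 1e-3)
})

test_that("velocity analysis reads slopes and inflection off constructed curves", {
  t <- seq(0, 20, 0.25)
  line <- progress_curve(t, 2 * t)
  vr <- analyze_velocities(line)
  expect_equal(vr$v0, 2, tolerance = 1e-9)
  expect_equal(vr$v_steady, 2, tolerance = 1e-9)
  expect_equal(vr$feedback_index, 0, tolerance = 1e-9)

  y <- ifelse(t <= 10, 5 * t, 50 + 1 * (t - 10))
  pw <- progress_curve(t, y)
  vrp <- analyze_velocities(pw)
  expect_equal(vrp$v0, 5, tolerance = 1e-6)
  expect_equal(vrp$v_steady, 1, tolerance = 1e-6)
  expect_equal(vrp$inflection_time, 10, tolerance = 1)
  expect_gt(vrp$feedback_index, 0.7)

  expect_error(analyze_velocities(progress_curve(1:5, 1:5)), "at least 10")
  expect_error(analyze_velocities(line, initial_frac = 0.6, steady_frac = 0.6),
               "overlap")
})

test_that("a simulated low-enzyme tight-binding run shows a genuine velocity break", {
  pc <- simulate_progress(rate_params(k_auto = 0), 0.34, 0.00322,
                          seq(0, 120, 0.5))
  vr <- analyze_velocities(pc)
  expect_lt(vr$v_steady, vr$v0)
  expect_gt(vr$feedback_index, 0.2)
})

test_that("feedback classification switches monotonically along the titration", {
  fam <- sim_progress_curves(0.34, c(0.32, 3.22, 96.66), seq(0, 120, 0.5),
                             params = rate_params(k_auto = 0), seed = 1)
  v <- classify_feedback(fam[!fam$background, ])
  expect_identical(as.character(v$verdict), c("inhibited", "inhibited", "complete"))

  # once complete, always complete at higher enzyme
  flips <- diff(v$verdict == "complete")
  expect_true(all(flips >= 0))
})

test_that("very large enzyme excess always completes; ablation removes inhibition", {
  fam <- sim_progress_curves(0.34, c(500, 1000), seq(0, 40, 0.25),
                             params = rate_params(k_auto = 0), seed = 2)
  v <- classify_feedback(fam[!fam$background, ], horizon = 30)
  expect_true(all(v$verdict == "complete"))

  p_abl <- rate_params(k_rel = 30, k_on_p = 0, k_off_p = 0, k_auto = 0)
  fam2 <- sim_progress_curves(0.34, c(0.32, 3.22, 32.22, 96.66),
                              seq(0, 120, 0.5), params = p_abl, seed = 3)
  v2 <- classify_feedback(fam2[!fam2$background, ])
  expect_true(all(v2$verdict == "complete"))
})

test_that("classification demands a shared substrate and ordered titration", {
  fam <- sim_progress_curves(0.34, c(3.22, 0.32), seq(0, 40, 0.5),
                             params = rate_params(k_auto = 0), seed = 4)
  fam <- fam[!fam$background, ]
  # crossing() sorts e0 ascending, so scramble deliberately
  scrambled <- dplyr::arrange(fam, dplyr::desc(e0_nM), time_min)
  expect_error(classify_feedback(scrambled, horizon = 30), "increasing")
  expect_error(classify_feedback(fam[fam$e0_nM == 3.22, ], horizon = 30),
               "at least two")
})

test_that("progress curves round-trip through CSV", {
  pc <- simulate_progress(rate_params(), 0.34, 0.003, seq(0, 10, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_progress(pc, path)
  back <- read_progress(path)
  expect_equal(back$signal, pc$signal, tolerance = 1e-12)
  expect_equal(back$time_min, pc$time_min)
})
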