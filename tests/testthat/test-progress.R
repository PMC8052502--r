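test_that("simulation respects mass conservation and trivial limits", {
  p <- ref_vsc()
  t <- seq(0, 8000, by = 20)
  # no enzyme: nothing happens
  sim0 <- simulate_progress(p, S0 = 100e-9, E0 = 0, t_grid = t)
  expect_equal(sim0$P, rep(0, length(t)))
  expect_equal(sim0$signal, rep(p$baseline, length(t)))
  # irreversible mechanism runs to completion
  sim <- simulate_progress(p, S0 = 16e-9, E0 = 180e-12, t_grid = c(0, 5e5))
  expect_equal(sim$P[2L], 16e-9, tolerance = 1e-4)
  # conservation at every time on the default design
  for (S0 in c(16e-9, 500e-9)) {
    s <- simulate_progress(p, S0, 180e-12, seq(0, 8000, by = 20))
    expect_lt(max(abs(s$S + s$ES + s$P - S0)), 1e-6 * S0)
    expect_true(all(diff(s$P) >= -1e-6 * S0))
  }
  expect_error(simulate_progress(p, 1e-7, 1e-10, c(0, 10, 5)), "increasing")
})

test_that("adaptive ODE solution matches a fine-step RK4 oracle", {
  p <- ref_vsc()
  t_out <- seq(0, 8000, by = 400)
  for (S0 in c(16e-9, 500e-9)) {
    sim <- simulate_progress(p, S0, 180e-12, t_out)
    orc <- rk4_vsc(p$k1, p$kcat, S0, 180e-12, t_out, dt = 0.2)
    expect_lt(max(abs(sim$P - orc$P)) / S0, 1e-4)
    expect_lt(max(abs(sim$S - orc$S)) / S0, 1e-4)
  }
})

test_that("low-substrate curves approach the pseudo-first-order closed form", {
  p <- ref_vsc()
  E0 <- 180e-12
  t <- seq(0, 8000, by = 20)
  keff <- p$kcat / p$Km
  dev <- function(S0) {
    sim <- simulate_progress(p, S0, E0, t)
    closed <- S0 * (1 - exp(-keff * E0 * t))
    max(abs(sim$P - closed)) / S0
  }
  # deep in the S0 << Km limit (S0 = Km/100) the closed form holds to 2%
  expect_lt(dev(1.85e-9), 0.02)
  # the leading correction is first order in S0/Km: deviation grows ~10x
  # from S0 = 1.6 nM to 16 nM and stays below S0/Km itself
  d16 <- dev(16e-9)
  d1.6 <- dev(1.6e-9)
  expect_gt(d16 / d1.6, 5)
  expect_lt(d16, 16e-9 / p$Km)
})

test_that("initial velocities follow the steady-state rate law", {
  p <- ref_vsc()
  E0 <- 180e-12
  t <- seq(0, 24, by = 2)
  for (S0 in c(16, 62, 250, 500) * 1e-9) {
    sim <- simulate_progress(p, S0, E0, t)
    # slope between 4 s (past the ES transient) and 24 s (before depletion)
    v <- (sim$P[t == 24] - sim$P[t == 4]) / 20
    v_ss <- p$kcat * E0 * S0 / (p$Km + S0)
    expect_equal(v, v_ss, tolerance = 0.02)
  }
})

test_that("background correction is pointwise subtraction with interpolation", {
  t <- seq(0, 100, by = 5)
  raw <- assay_series(t, 2 + 0.1 * t, meta = list(S0 = 1e-7, E0 = 1e-10))
  expect_equal(correct_background(raw, raw)$y, rep(0, length(t)))
  ctrl <- assay_series(t, rep(0.5, length(t)))
  expect_equal(correct_background(raw, ctrl)$y, raw$y - 0.5)
  # control on a different (coarser) grid is interpolated
  ctrl2 <- assay_series(seq(0, 100, by = 25), 0.05 * seq(0, 100, by = 25))
  expect_equal(correct_background(raw, ctrl2)$y, 2 + 0.05 * t)
  # disjoint grids are rejected
  far <- assay_series(t + 1000, t)
  expect_error(correct_background(raw, far), "overlap")
  # generator round trip: raw minus matched control is the clean curve
  p <- ref_vsc()
  des <- progress_design(dt = 20, replicates = 1)
  d <- gen_progress(p, des, noise_model())
  corr <- correct_background(d$curves[[1]], d$controls[[1]])
  clean <- simulate_progress(p, series_meta(d$curves[[1]])$S0,
                             des$enzyme_conc, corr$x)$signal
  expect_equal(corr$y, clean, tolerance = 1e-12)
})

test_that("global fit recovers generating parameters from noise-free curves", {
  p <- ref_vsc()
  des <- progress_design(dt = 20, replicates = 1)
  d <- gen_progress(p, des, noise_model())
  curves <- Map(correct_background, d$curves, d$controls)
  fit <- fit_progress_global(curves)
  expect_true(fit$converged)
  expect_equal(fit$params$kcat, p$kcat, tolerance = 1e-3)
  expect_equal(fit$params$Km, p$Km, tolerance = 1e-3)
  expect_equal(fit$efficiency, fit$params$kcat / fit$params$Km)
})

test_that("noisy-data estimates are calibrated against their standard errors", {
  p <- ref_vsc()
  des <- progress_design(dt = 20)
  full_scale <- p$signal_gain * max(des$substrate_concs)
  z <- vapply(1:4, function(seed) {
    d <- gen_progress(p, des, noise_model("gaussian", sd = 0.005 * full_scale,
                                          seed = seed))
    curves <- Map(correct_background, d$curves, d$controls)
    fit <- fit_progress_global(curves)
    expect_true(fit$converged)
    c((fit$params$kcat - p$kcat) / fit$se[["kcat"]],
      (fit$params$Km - p$Km) / fit$se[["Km"]])
  }, c(0, 0))
  # unbiased recovery with honest standard errors: z-scores behave like
  # standard normal draws
  expect_lt(max(abs(z)), 5)
  expect_lt(mean(abs(z)), 2)
})

test_that("flat curves are rejected instead of yielding a confident kcat", {
  t <- seq(0, 1000, by = 10)
  flat <- lapply(c(16e-9, 500e-9), function(S0) {
    assay_series(t, rep(5, length(t)), meta = list(S0 = S0, E0 = 180e-12))
  })
  expect_error(fit_progress_global(flat), "signal")
})

test_that("catalytic efficiency is kcat/Km with input validation", {
  expect_equal(catalytic_efficiency(0.886, 185e-9), 4.79e6, tolerance = 5e-4)
  expect_equal(catalytic_efficiency(1, 1), 1)
  expect_equal(catalytic_efficiency(2.2, 1e-6), 2.2e6)
  expect_error(catalytic_efficiency(1, 0), "Km")
})
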