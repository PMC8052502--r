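test_that("analytic sensorgram matches numeric integration of the rate law", {
  for (drift in c(0, -0.02)) {
    p <- ref_langmuir(drift = drift, R_offset = 1.5)
    for (C in c(90e-9, 11.25e-9, 2.8e-9)) {
      s <- langmuir_response(p, C, t_assoc = 200, t_dissoc = 200, dt = 1)
      orc <- ode_langmuir(p$ka, p$kd, p$Rmax, p$drift, p$R_offset, C,
                          s$x, 200)
      expect_lt(max(abs(s$y - orc)), 1e-6 * p$Rmax)
    }
  }
})

test_that("sensorgram limiting cases behave", {
  p <- ref_langmuir()
  # blank cycle: response is the offset line
  s0 <- langmuir_response(p, 0, 200, 200)
  expect_equal(s0$y, rep(0, nrow(s0)))
  # plateau at C = KD is Rmax/2 for long association
  KD <- derive_KD(p$ka, p$kd)
  s <- langmuir_response(p, KD, t_assoc = 20000, t_dissoc = 10)
  expect_equal(max(s$y), p$Rmax / 2, tolerance = 1e-6)
  # observed rate at 90 nM reaches >95% of Req within the 200 s phase
  kobs <- p$ka * 90e-9 + p$kd
  expect_equal(kobs, 1.62e-2, tolerance = 1e-2)
  expect_gt(kobs * 200, 3)
  s90 <- langmuir_response(p, 90e-9, 200, 200)
  Req <- p$ka * 90e-9 * p$Rmax / kobs
  expect_gt(s90$y[s90$x == 200] / Req, 0.95)
  # no off-rate, no drift: dissociation phase is flat
  pk0 <- langmuir_params(13.1e4, 0, 35)
  sk0 <- langmuir_response(pk0, 90e-9, 200, 200)
  expect_equal(diff(sk0$y[sk0$x >= 200]), rep(0, sum(sk0$x >= 200) - 1L))
  expect_error(langmuir_response(p, -1e-9, 200, 200), ">= 0")
})

test_that("Req is monotone in concentration and saturates at Rmax", {
  p <- ref_langmuir()
  C <- 10^seq(-10, -5, length.out = 30)
  Req <- p$ka * C * p$Rmax / (p$ka * C + p$kd)
  expect_true(all(diff(Req) > 0))
  expect_lt(max(Req), p$Rmax)
  expect_equal(p$ka * 1 * p$Rmax / (p$ka * 1 + p$kd), p$Rmax, tolerance = 1e-6)
})

test_that("double referencing subtracts both reference traces", {
  t <- 0:100
  sam <- assay_series(t, sin(t / 10) + 0.1 * t, meta = list(conc = 1e-8))
  zero <- assay_series(t, rep(0, length(t)))
  expect_equal(double_reference(sam, zero, zero)$y, sam$y)
  # references summing to the systematic term recover the model exactly
  model <- sin(t / 10)
  b1 <- assay_series(t, 0.06 * t)
  b2 <- assay_series(t, 0.04 * t)
  expect_equal(double_reference(sam, b1, b2)$y, model)
  expect_equal(double_reference(sam, zero, sam)$y, rep(0, length(t)))
  # coarser reference grids are interpolated onto the sample grid
  b_coarse <- assay_series(seq(0, 100, by = 20), 0.1 * seq(0, 100, by = 20))
  expect_equal(double_reference(sam, b_coarse, zero)$y, model)
})

test_that("global Langmuir fit recovers parameters from noise-free cycles", {
  p <- ref_langmuir(drift = -0.01, R_offset = 2)
  cyc <- gen_sensorgrams(p, spr_design(top_conc = 90e-9))
  fit <- fit_sensorgrams_global(cyc)
  expect_true(fit$converged)
  expect_equal(fit$params$ka, p$ka, tolerance = 1e-3)
  expect_equal(fit$params$kd, p$kd, tolerance = 1e-3)
  expect_equal(fit$KD, derive_KD(p$ka, p$kd), tolerance = 1e-3)
  expect_equal(fit$KD * fit$params$ka, fit$params$kd)
  # KD is invariant to rescaling all responses (Rmax absorbs the scale)
  cyc2 <- lapply(cyc, function(s)
    assay_series(s$x, s$y * 7.5, kind = "time", meta = series_meta(s)))
  fit2 <- fit_sensorgrams_global(cyc2)
  expect_equal(fit2$KD, fit$KD, tolerance = 1e-6)
  expect_equal(fit2$params$Rmax, fit$params$Rmax * 7.5, tolerance = 1e-3)
})

test_that("global Langmuir fit brackets generating parameters under noise", {
  p <- ref_langmuir(drift = -0.005)
  cyc <- gen_sensorgrams(p, spr_design(top_conc = 90e-9),
                         noise_model("gaussian", sd = 0.5, seed = 7))
  fit <- fit_sensorgrams_global(cyc)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$ka - p$ka), 3 * fit$se[["ka"]])
  expect_lt(abs(fit$params$kd - p$kd), 3 * fit$se[["kd"]])
})

test_that("a no-dissociation generator yields kd pinned at the zero bound", {
  p <- langmuir_params(13.1e4, 0, 35)
  cyc <- gen_sensorgrams(p, spr_design(top_conc = 90e-9))
  fit <- fit_sensorgrams_global(cyc)
  expect_gte(fit$params$kd, 0)
  expect_lt(fit$params$kd, 1e-6)
})

test_that("fit input validation", {
  p <- ref_langmuir()
  cyc <- gen_sensorgrams(p, spr_design(top_conc = 90e-9, n_concs = 2))
  expect_error(fit_sensorgrams_global(cyc), "3 distinct")
})

test_that("KD derivation matches the tabulated kinetic constants", {
  expect_equal(derive_KD(13.1e4, 4.4e-3), 33.6e-9, tolerance = 1e-3)
  expect_equal(derive_KD(1.953e4, 9.10e-3), 466e-9, tolerance = 1e-3)
  expect_equal(derive_KD(5e4, 0), 0)
  expect_error(derive_KD(0, 1e-3), "ka")
  # every tabulated row: KD from mean rates within 3% of the tabulated mean KD
  tab <- c5a_binding_constants()
  for (i in seq_len(nrow(tab))) {
    expect_equal(derive_KD(tab$ka[i], tab$kd[i]), tab$KD[i], tolerance = 0.03)
  }
})

test_that("replicate KD statistics are computed per experiment first", {
  ka <- c(12.8e4, 13.1e4, 13.4e4)
  kd <- c(4.1e-3, 4.4e-3, 4.7e-3)
  bc <- summarize_binding_constants(ka, kd)
  expect_equal(bc$KD$n, 3L)
  expect_equal(bc$KD$mean, mean(kd / ka))
  # differs (slightly) from mean(kd)/mean(ka)
  expect_false(isTRUE(all.equal(bc$KD$mean, mean(kd) / mean(ka),
                                tolerance = 1e-12)))
})
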