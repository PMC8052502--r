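test_that("perfusion-cell concentration bookkeeping", {
  des <- itc_design()
  cc1 <- cell_concentrations(des, 1)
  # vanishing injected volume: Mt -> Mt0, Xt -> 0
  tiny <- itc_design(injection_volume = 1e-12)
  cc0 <- cell_concentrations(tiny, 1)
  expect_equal(cc0$Mt, 18e-6, tolerance = 1e-6)
  expect_lt(cc0$Xt, 1e-9)
  # first injection molar ratio ~0.118 at the default design
  expect_equal(cc1$molar_ratio, 0.1188, tolerance = 1e-3)
  # hand arithmetic with the displacement formulas at i = 19:
  # dV = 47.5 uL, f = 0.11875, Mt = 18(1-f)/(1+f), Xt = 170*0.2375/(1+f)
  cc19 <- cell_concentrations(des, 19)
  expect_equal(cc19$Mt, 18e-6 * 0.88125 / 1.11875, tolerance = 1e-12)
  expect_equal(cc19$Xt, 170e-6 * 0.2375 / 1.11875, tolerance = 1e-12)
  expect_equal(cc19$molar_ratio, 2.5453, tolerance = 1e-4)
  expect_error(cell_concentrations(des, 20), "out of range")
  expect_error(itc_design(n_injections = 100), "cell volume")
})

test_that("cumulative heat matches a mass-action equilibrium oracle", {
  des <- itc_design()
  V0 <- des$cell_volume
  Mt <- 15e-6
  for (KA in c(1e5, 1 / 30.8e-9, 1e9)) {
    p <- one_site_params(1, KA, -9.4)
    for (ratio in c(0.1, 0.5, 0.9, 1, 1.1, 2, 5)) {
      Xt <- ratio * p$N * Mt
      q <- total_heat(p, Mt, Xt, V0)
      bound <- bisect_complex(p$N * Mt, Xt, 1 / KA)
      q_orc <- p$dH * 1000 * V0 * bound
      expect_equal(q, q_orc, tolerance = 1e-9)
    }
  }
})

test_that("cumulative heat limits and monotonicity", {
  des <- itc_design()
  p <- ref_one_site()
  V0 <- des$cell_volume
  expect_equal(total_heat(p, 18e-6, 0, V0), 0)
  # tight binding, sub-stoichiometric titrant: all titrant bound
  p_tight <- one_site_params(1, 1e15, -9.4)
  Xt <- 9e-6
  expect_equal(total_heat(p_tight, 18e-6, Xt, V0),
               Xt * -9.4e3 * V0, tolerance = 1e-6)
  # saturation plateau N Mt dH V0
  expect_equal(total_heat(p, 18e-6, 5e-3, V0),
               18e-6 * -9.4e3 * V0, tolerance = 1e-3)
  # |Q| monotone toward the plateau
  Xts <- seq(0, 100e-6, length.out = 40)
  q <- total_heat(p, 18e-6, Xts, V0)
  expect_true(all(diff(abs(q)) >= -1e-15))
  expect_lte(max(abs(q)), abs(18e-6 * -9.4e3 * V0) * (1 + 1e-12))
})

test_that("per-injection heats conserve total binding heat", {
  des <- itc_design()
  p <- ref_one_site()
  ih <- injection_heats(p, des)
  expect_equal(nrow(ih), 19L)
  # athermal binding: zero heat everywhere
  ih0 <- injection_heats(one_site_params(1, 1 / 30.8e-9, 0), des)
  expect_equal(ih0$q_ucal, rep(0, 19))
  # heat conservation over a saturating titration
  total_expected <- p$N * des$cell_conc * des$cell_volume * p$dH * 1000
  expect_equal(sum(ih$q_cal), total_expected, tolerance = 0.05)
  # high-c Wiseman step: early per-mole heats ~dH, late ~0, midpoint near N
  expect_equal(ih$q_kcal_per_mol[2L], p$dH, tolerance = 0.03)
  expect_lt(abs(ih$q_kcal_per_mol[19L]), 0.05 * abs(p$dH))
  i_mid <- which(abs(ih$q_kcal_per_mol) <= abs(p$dH) / 2)[1L]
  expect_lt(abs(ih$molar_ratio[i_mid] - p$N), 0.15)
})

test_that("one-site fit recovers generating parameters from noise-free data", {
  des <- itc_design()
  p <- ref_one_site()
  dat <- gen_itc(p, des)
  fit <- fit_one_site(dat, des)
  expect_true(fit$converged)
  expect_equal(fit$params$N, 1, tolerance = 5e-3)
  expect_equal(fit$params$KA, p$KA, tolerance = 5e-3)
  expect_equal(fit$params$dH, -9.4, tolerance = 5e-3)
  expect_equal(fit$derived$KD_itc, 30.8e-9, tolerance = 5e-3)
  # derived energies at 298 K
  expect_equal(fit$derived$dG, -10.24, tolerance = 1e-2)
  expect_equal(fit$derived$dS, 2.81, tolerance = 1e-2)
  # thermodynamic identity holds exactly
  expect_equal(fit$derived$dG,
               fit$params$dH - fit$derived$temperature * fit$derived$dS / 1000)
})

test_that("one-site fit brackets generating parameters under noise", {
  des <- itc_design()
  p <- ref_one_site()
  dat <- gen_itc(p, des, noise_model("gaussian", sd = 0.2, seed = 3),
                 dilution_heat = -0.3)
  fit <- fit_one_site(dat, des)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$N - p$N), 3 * fit$se[["N"]])
  expect_lt(abs(fit$params$dH - p$dH), 3 * fit$se[["dH"]])
})

test_that("first-injection exclusion barely moves the noise-free fit", {
  des <- itc_design()
  dat <- gen_itc(ref_one_site(), des)
  fit_skip <- fit_one_site(dat, des, skip_first = TRUE)
  fit_all <- fit_one_site(dat, des, skip_first = FALSE)
  expect_equal(fit_skip$params$KA, fit_all$params$KA, tolerance = 0.01)
})

test_that("extreme c-values raise an identifiability warning", {
  des <- itc_design()
  p <- one_site_params(1, 1e12, -9.4)  # c ~ 1.8e7
  dat <- gen_itc(p, des)
  fit <- fit_one_site(dat, des)
  expect_true(any(grepl("c-value", fit$warnings)))
})
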