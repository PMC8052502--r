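#' Additive noise model for synthetic instrument data
#'
#' Homoscedastic Gaussian noise in signal units, or none. A seed is mandatory
#' for Gaussian noise: generators restore the caller's RNG state afterwards,
#' so identical (parameters, design, seed) reproduce identical data
#' bit-for-bit and no hidden global random state is consumed.
#'
#' @param kind `"none"` or `"gaussian"`.
#' @param sd Standard deviation in signal units (>= 0).
#' @param seed Integer seed; required when `kind = "gaussian"`.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "gaussian"), sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  if (kind == "gaussian" && is.null(seed)) {
    stop("a seed is required for gaussian noise", call. = FALSE)
  }
  structure(list(kind = kind, sd = sd, seed = seed), class = "noise_model")
}

# evaluate code under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# draw one noise vector; caller must already be inside .with_seed
.add_noise <- function(y, noise) {
  if (noise$kind == "none" || noise$sd == 0) return(y)
  y + stats::rnorm(length(y), 0, noise$sd)
}

#' Progress-curve assay design
#'
#' Defaults reproduce the fluorogenic cleavage assay layout: a 2-fold
#' substrate ladder 16-500 nM, 180 pM enzyme, 8000 s of acquisition at 2 s
#' intervals, quadruplicate wells.
#'
#' @param substrate_concs Substrate concentrations in M.
#' @param enzyme_conc Enzyme concentration in M (must be below the smallest
#'   substrate concentration; the fit assumes E0 << S0).
#' @param duration,dt Acquisition window and sampling interval in s.
#' @param replicates Wells per substrate concentration.
#' @return Object of class `progress_design`.
#' @export
progress_design <- function(substrate_concs = c(16, 31, 62, 125, 250, 500) * 1e-9,
                            enzyme_conc = 180e-12, duration = 8000, dt = 2,
                            replicates = 4) {
  stopifnot(all(substrate_concs > 0), enzyme_conc >= 0, duration > 0, dt > 0,
            replicates >= 1)
  if (enzyme_conc >= min(substrate_concs)) {
    stop("enzyme_conc must be below the smallest substrate concentration",
         call. = FALSE)
  }
  structure(list(substrate_concs = substrate_concs, enzyme_conc = enzyme_conc,
                 duration = duration, dt = dt, replicates = replicates),
            class = "progress_design")
}

#' Generate synthetic fluorogenic progress curves
#'
#' One curve per (substrate concentration, replicate) from the
#' Van Slyke-Cullen forward model, plus matched enzyme-free control series.
#' Spontaneous substrate hydrolysis is modelled as a slow linear signal rise
#' present in both raw curves and controls, so [correct_background()]
#' recovers the enzymatic curve.
#'
#' @param params A [vsc_params()].
#' @param design A [progress_design()].
#' @param noise A [noise_model()]; sd in AU. The conventional default noise
#'   level for this assay is 0.5% of full scale.
#' @param hydrolysis_rate Background signal slope in AU/s; default 0.1% of
#'   full scale per 1000 s.
#' @return List with `curves` and `controls`, each a list of `assay_series`
#'   with metadata `S0`, `E0`, `replicate`.
#' @export
gen_progress <- function(params, design, noise = noise_model(),
                         hydrolysis_rate = NULL) {
  stopifnot(inherits(params, "vsc_params"), inherits(design, "progress_design"),
            inherits(noise, "noise_model"))
  full_scale <- params$signal_gain * max(design$substrate_concs)
  if (is.null(hydrolysis_rate)) hydrolysis_rate <- 1e-3 * full_scale / 1000
  t <- seq(0, design$duration, by = design$dt)
  bg <- hydrolysis_rate * t

  clean <- lapply(design$substrate_concs, function(S0) {
    if (params$kcat == 0 || design$enzyme_conc == 0) {
      params$baseline + numeric(length(t))
    } else {
      simulate_progress(params, S0, design$enzyme_conc, t)$signal
    }
  })

  build <- function(signal_fn) {
    out <- list()
    for (j in seq_along(design$substrate_concs)) {
      for (r in seq_len(design$replicates)) {
        y <- signal_fn(j)
        out[[length(out) + 1L]] <- assay_series(
          t, .add_noise(y, noise), kind = "time",
          meta = list(S0 = design$substrate_concs[j],
                      E0 = design$enzyme_conc, replicate = r))
      }
    }
    out
  }
  gen <- function() {
    curves <- build(function(j) clean[[j]] + bg)
    # controls carry the spontaneous-hydrolysis drift only, with E0 = 0, so
    # raw - control recovers the enzymatic curve
    controls <- lapply(build(function(j) bg), function(s) {
      m <- series_meta(s); m$E0 <- 0
      assay_series(s$x, s$y, kind = "time", meta = m)
    })
    list(curves = curves, controls = controls)
  }
  if (noise$kind == "gaussian") .with_seed(noise$seed, gen()) else gen()
}

#' Biosensor concentration-series design
#'
#' A 2-fold dilution series of `n_concs` analyte concentrations from
#' `top_conc` down (a 32-fold range at the defaults), 200 s association and
#' 200 s dissociation, matching the instrument protocol emulated here.
#'
#' @param top_conc Highest analyte concentration in M.
#' @param n_concs Number of concentrations.
#' @param dilution_factor Serial dilution factor.
#' @param t_assoc,t_dissoc Phase durations in s.
#' @param dt Sampling interval in s.
#' @param immobilization_ru Nominal immobilized-ligand level in RU (30-40 on
#'   the emulated chip); informational.
#' @param concs Optional explicit concentration vector overriding the ladder
#'   (may include 0 for blank cycles).
#' @return Object of class `spr_design`.
#' @export
spr_design <- function(top_conc, n_concs = 6, dilution_factor = 2,
                       t_assoc = 200, t_dissoc = 200, dt = 1,
                       immobilization_ru = 35, concs = NULL) {
  stopifnot(t_assoc > 0, t_dissoc > 0, dt > 0)
  if (is.null(concs)) {
    stopifnot(top_conc > 0, n_concs >= 1, dilution_factor > 1)
    concs <- top_conc / dilution_factor^(seq_len(n_concs) - 1L)
  }
  structure(list(concs = concs, t_assoc = t_assoc, t_dissoc = t_dissoc,
                 dt = dt, immobilization_ru = immobilization_ru),
            class = "spr_design")
}

#' Generate synthetic sensorgram cycles
#'
#' One drifting-baseline 1:1 Langmuir sensorgram per analyte concentration,
#' with optional Gaussian noise (conventional default 0.5 RU for this
#' instrument class).
#'
#' @param params A [langmuir_params()] (its `drift`/`R_offset` apply to every
#'   cycle).
#' @param design An [spr_design()].
#' @param noise A [noise_model()]; sd in RU.
#' @return List of `assay_series` with metadata `conc`, `t_assoc`,
#'   `t_dissoc`.
#' @export
gen_sensorgrams <- function(params, design, noise = noise_model()) {
  stopifnot(inherits(params, "langmuir_params"), inherits(design, "spr_design"),
            inherits(noise, "noise_model"))
  gen <- function() {
    lapply(design$concs, function(C) {
      s <- langmuir_response(params, C, design$t_assoc, design$t_dissoc,
                             design$dt)
      assay_series(s$x, .add_noise(s$y, noise), kind = "time",
                   meta = series_meta(s))
    })
  }
  if (noise$kind == "gaussian") .with_seed(noise$seed, gen()) else gen()
}

#' Competition titration design
#'
#' Fixed enzyme at 700 nM titrated with competitor spanning 0-2000 nM; the
#' default ladder is a 2-fold series with the mandatory zero-competitor
#' anchor point.
#'
#' @param competitor_concs Total competitor concentrations in M (must
#'   include 0).
#' @param e_tot,kd_core,r_min Fixed assay parameters recorded with the
#'   design.
#' @return Object of class `competition_design`.
#' @export
competition_design <- function(competitor_concs = c(0, 2000 / 2^(7:0)) * 1e-9,
                               e_tot = 700e-9, kd_core = 240e-9, r_min = 0) {
  stopifnot(all(competitor_concs >= 0), e_tot > 0, kd_core > 0)
  if (!any(competitor_concs == 0)) {
    stop("competitor_concs must include 0 (uninhibited anchor point)",
         call. = FALSE)
  }
  structure(list(competitor_concs = competitor_concs, e_tot = e_tot,
                 kd_core = kd_core, r_min = r_min),
            class = "competition_design")
}

#' Generate a synthetic competition titration
#'
#' Equilibrium responses from [req_model()] at each competitor concentration
#' plus optional Gaussian noise (conventional default 1 RU).
#'
#' @param model A [competition_model()].
#' @param design A [competition_design()].
#' @param noise A [noise_model()]; sd in RU.
#' @return `assay_series` (`x` = total competitor concentration in M,
#'   `y` = Req in RU).
#' @export
gen_competition <- function(model, design, noise = noise_model()) {
  stopifnot(inherits(model, "competition_model"),
            inherits(design, "competition_design"),
            inherits(noise, "noise_model"))
  c_tot <- design$competitor_concs
  y <- req_model(model, c_tot)
  gen <- function() {
    assay_series(c_tot, .add_noise(y, noise), kind = "dose",
                 meta = list(e_tot = model$e_tot, kd_core = model$kd_core,
                             r_min = model$r_min))
  }
  if (noise$kind == "gaussian") .with_seed(noise$seed, gen()) else gen()
}

#' Generate a synthetic calorimetric titration
#'
#' Per-injection heats from the one-set-of-sites forward model plus a
#' constant dilution heat per injection and optional Gaussian noise on the
#' raw heats (conventional default 0.2 ucal).
#'
#' @param params A [one_site_params()].
#' @param design An [itc_design()].
#' @param noise A [noise_model()]; sd in ucal.
#' @param dilution_heat Constant offset per injection in ucal.
#' @return `data.frame` with `injection`, `molar_ratio`, `q_ucal`,
#'   `q_kcal_per_mol` (offset and noise included in both heat columns).
#' @export
gen_itc <- function(params, design, noise = noise_model(), dilution_heat = 0) {
  stopifnot(inherits(params, "one_site_params"), inherits(design, "itc_design"),
            inherits(noise, "noise_model"))
  ih <- injection_heats(params, design)
  gen <- function() {
    q_ucal <- .add_noise(ih$q_ucal + dilution_heat, noise)
    mol_inj <- design$syringe_conc * design$injection_volume
    data.frame(injection = ih$injection, molar_ratio = ih$molar_ratio,
               q_ucal = q_ucal,
               q_kcal_per_mol = q_ucal * 1e-6 / 1000 / mol_inj)
  }
  if (noise$kind == "gaussian") .with_seed(noise$seed, gen()) else gen()
}
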