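#' One-set-of-sites binding parameters
#'
#' @param N Stoichiometry (sites per macromolecule, > 0).
#' @param KA Association constant in M^-1 (> 0).
#' @param dH Binding enthalpy in kcal/mol.
#' @return Object of class `one_site_params`.
#' @export
#' @examples
#' one_site_params(N = 1, KA = 1 / 30.8e-9, dH = -9.4)
one_site_params <- function(N, KA, dH) {
  if (N <= 0) stop("N must be > 0", call. = FALSE)
  if (KA <= 0) stop("KA must be > 0", call. = FALSE)
  structure(list(N = N, KA = KA, dH = dH), class = "one_site_params")
}

#' Calorimeter titration design
#'
#' Perfusion (overflow) cell design: each injection displaces cell contents,
#' so working concentrations follow the standard displacement bookkeeping of
#' [cell_concentrations()].
#'
#' @param cell_volume Cell volume V0 in L.
#' @param cell_conc Initial macromolecule concentration in the cell, M.
#' @param syringe_conc Titrant concentration in the syringe, M.
#' @param injection_volume Volume per injection, L.
#' @param n_injections Number of injections.
#' @param temperature Run temperature in K.
#' @return Object of class `itc_design`.
#' @export
itc_design <- function(cell_volume = 200e-6, cell_conc = 18e-6,
                       syringe_conc = 170e-6, injection_volume = 2.5e-6,
                       n_injections = 19, temperature = 298.15) {
  stopifnot(cell_volume > 0, cell_conc > 0, syringe_conc > 0,
            injection_volume > 0, n_injections >= 1, temperature > 0)
  if (n_injections * injection_volume >= cell_volume) {
    stop("cumulative injected volume must stay below the cell volume",
         call. = FALSE)
  }
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volume = injection_volume,
                 n_injections = n_injections, temperature = temperature),
            class = "itc_design")
}

#' Working cell concentrations after i injections
#'
#' With cumulative injected volume dV = i * v_inj into a perfusion cell of
#' volume V0: Mt_i = Mt0 (1 - dV/2V0)/(1 + dV/2V0) and
#' Xt_i = Xs (dV/V0)/(1 + dV/2V0).
#'
#' @param design An [itc_design()].
#' @param i Injection index (vectorized, 1..n_injections).
#' @return `data.frame` with columns `injection`, `Mt`, `Xt`, `molar_ratio`
#'   (= Xt/Mt), concentrations in M.
#' @export
#' @examples
#' cell_concentrations(itc_design(), 1)$molar_ratio  # ~0.118
cell_concentrations <- function(design, i) {
  stopifnot(inherits(design, "itc_design"))
  if (any(i < 1) || any(i > design$n_injections)) {
    stop("injection index out of range", call. = FALSE)
  }
  dv <- i * design$injection_volume
  v0 <- design$cell_volume
  f <- dv / (2 * v0)
  Mt <- design$cell_conc * (1 - f) / (1 + f)
  Xt <- design$syringe_conc * (dv / v0) / (1 + f)
  data.frame(injection = i, Mt = Mt, Xt = Xt, molar_ratio = Xt / Mt)
}

#' Cumulative heat of the one-set-of-sites isotherm
#'
#' Closed-form cumulative heat content of the cell:
#' Q = (N Mt dH V0 / 2) \[B - sqrt(B^2 - 4 Xt/(N Mt))\] with
#' B = 1 + Xt/(N Mt) + 1/(N KA Mt). Returned in calories (dH is kcal/mol).
#'
#' @param params A [one_site_params()].
#' @param Mt Macromolecule concentration in the cell, M (> 0); vectorized.
#' @param Xt Titrant concentration in the cell, M (>= 0); vectorized.
#' @param V0 Cell volume in L.
#' @return Cumulative heat in cal; has the sign of `dH` and magnitude at most
#'   |N Mt dH V0|.
#' @export
total_heat <- function(params, Mt, Xt, V0) {
  stopifnot(inherits(params, "one_site_params"))
  if (any(Mt <= 0) || any(Xt < 0)) {
    stop("Mt must be > 0 and Xt >= 0", call. = FALSE)
  }
  nmt <- params$N * Mt
  B <- 1 + Xt / nmt + 1 / (params$KA * nmt)
  disc <- B^2 - 4 * Xt / nmt
  disc[disc < 0] <- 0  # rounding guard; analytically disc > 0
  dh_cal <- params$dH * 1000
  (nmt * dh_cal * V0 / 2) * (B - sqrt(disc))
}

#' Per-injection heats of a titration
#'
#' Differences of the cumulative heat with the standard perfusion-cell
#' displacement correction:
#' dQ_i = Q_i - Q_(i-1) + (v_inj/V0) (Q_i + Q_(i-1))/2, Q_0 = 0.
#'
#' @param params A [one_site_params()].
#' @param design An [itc_design()].
#' @return `data.frame` with `injection`, `molar_ratio`, `q_cal` (raw
#'   per-injection heat, cal), `q_ucal` (ucal) and `q_kcal_per_mol` (kcal per
#'   mole of injectant, the quantity plotted against molar ratio).
#' @export
injection_heats <- function(params, design) {
  stopifnot(inherits(params, "one_site_params"), inherits(design, "itc_design"))
  cc <- cell_concentrations(design, seq_len(design$n_injections))
  Q <- total_heat(params, cc$Mt, cc$Xt, design$cell_volume)
  Qprev <- c(0, Q[-length(Q)])
  vr <- design$injection_volume / design$cell_volume
  dq <- Q - Qprev + vr * (Q + Qprev) / 2
  mol_inj <- design$syringe_conc * design$injection_volume
  data.frame(injection = cc$injection, molar_ratio = cc$molar_ratio,
             q_cal = dq, q_ucal = dq * 1e6,
             q_kcal_per_mol = dq / 1000 / mol_inj)
}

#' Derived thermodynamic quantities of a one-site fit
#'
#' KD = 1/KA; dG = -R T ln(KA) in kcal/mol; dS = (dH - dG) * 1000 / T in
#' cal mol^-1 K^-1, so dG = dH - T dS/1000 holds exactly by construction.
#' The c-value N KA Mt0 measures isotherm steepness.
#'
#' @param params A [one_site_params()].
#' @param temperature Reporting temperature in K (default 298, the reference
#'   temperature of the energy tables).
#' @param cell_conc Optional initial cell concentration in M for the c-value.
#' @return List of class `itc_derived`: `KD_itc` (M), `dG` (kcal/mol), `dS`
#'   (cal mol^-1 K^-1), `c_value` (or NA).
#' @export
itc_derived <- function(params, temperature = bk_constants()$T_ref,
                        cell_conc = NA_real_) {
  stopifnot(inherits(params, "one_site_params"))
  R <- bk_constants()$R_cal
  dG <- -R * temperature * log(params$KA) / 1000
  structure(
    list(KD_itc = 1 / params$KA,
         dG = dG,
         dS = (params$dH - dG) * 1000 / temperature,
         c_value = params$N * params$KA * cell_conc,
         temperature = temperature),
    class = "itc_derived"
  )
}

#' Fit the one-set-of-sites model to integrated injection heats
#'
#' Nonlinear least squares over (N, KA, dH) plus an optional constant
#' dilution-heat offset, against per-injection heats normalized per mole of
#' injectant. KA is fitted on the log scale; N and dH on the natural scale
#' with N bounded below. The first injection is discarded by default (the
#' usual partial-delivery artifact of the instrument class).
#'
#' @param series `data.frame` (or `assay_series`) with columns/fields
#'   `injection` and `q_kcal_per_mol`.
#' @param design The [itc_design()] of the titration.
#' @param skip_first Discard injection 1 before fitting (default `TRUE`).
#' @param fit_offset Fit a constant dilution-heat offset (kcal/mol of
#'   injectant) alongside the binding parameters (default `TRUE`).
#' @param temperature Reporting temperature for derived energies, K.
#' @param control `minpack.lm::nls.lm.control` list.
#' @return Object of class `one_site_fit`: `params` ([one_site_params()]),
#'   `se`, `offset`, `derived` ([itc_derived()]), `converged`,
#'   `residual_norm`, `warnings`.
#' @export
fit_one_site <- function(series, design, skip_first = TRUE, fit_offset = TRUE,
                         temperature = bk_constants()$T_ref,
                         control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(inherits(design, "itc_design"))
  df <- as.data.frame(series)
  if (inherits(series, "assay_series")) {
    df <- data.frame(injection = series$x, q_kcal_per_mol = series$y)
  }
  if (!all(c("injection", "q_kcal_per_mol") %in% names(df))) {
    stop("series needs columns 'injection' and 'q_kcal_per_mol'", call. = FALSE)
  }
  keep <- if (skip_first) df$injection > 1L else rep(TRUE, nrow(df))
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 8L) stop("need at least 8 informative injections", call. = FALSE)

  # initial guesses: dH from the early plateau, N from the molar ratio at the
  # transition midpoint, KA from a moderate-steepness assumption
  q <- df$q_kcal_per_mol
  ratio <- cell_concentrations(design, df$injection)$molar_ratio
  dH0 <- q[1L]
  mid <- (q[1L] + q[length(q)]) / 2
  past <- if (dH0 < 0) which(q >= mid) else which(q <= mid)
  N0 <- if (length(past)) max(ratio[past[1L]], 0.1) else 1
  KA0 <- 50 / (N0 * design$cell_conc)

  model_q <- function(N, KA, dH, offset) {
    p <- one_site_params(N, KA, dH)
    injection_heats(p, design)$q_kcal_per_mol[df$injection] + offset
  }
  resid_fn <- function(theta) {
    off <- if (fit_offset) theta[4L] else 0
    q - model_q(theta[1L], exp(theta[2L]), theta[3L], off)
  }
  n_par <- if (fit_offset) 4L else 3L
  theta0 <- c(N0, log(KA0), dH0, if (fit_offset) 0)
  lower <- c(1e-3, -Inf, -Inf, if (fit_offset) -Inf)
  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn, lower = lower,
                            control = control)
  theta <- fit$par
  N <- theta[1L]; KA <- exp(theta[2L]); dH <- theta[3L]
  offset <- if (fit_offset) theta[4L] else 0
  n_obs <- length(fit$fvec)
  sigma2 <- fit$deviance / max(n_obs - n_par, 1L)
  cov <- tryCatch(solve(fit$hessian) * sigma2, error = function(e) NULL)
  se_theta <- if (!is.null(cov) && all(diag(cov) >= 0)) sqrt(diag(cov)) else
    rep(Inf, n_par)
  se <- c(N = se_theta[1L], KA = KA * se_theta[2L], dH = se_theta[3L])

  warns <- character(0)
  c_val <- N * KA * design$cell_conc
  if (c_val > 1e4) {
    warns <- c(warns, sprintf(
      "c-value %.3g > 1e4: KA poorly identified from isotherm shape", c_val))
  }
  params <- one_site_params(N, KA, dH)
  structure(
    list(params = params, se = se, offset = offset,
         derived = itc_derived(params, temperature, design$cell_conc),
         converged = fit$info %in% 1:4,
         residual_norm = sqrt(fit$deviance),
         n_obs = n_obs, warnings = warns, info = fit$info),
    class = "one_site_fit"
  )
}

#' @export
print.one_site_fit <- function(x, ...) {
  p <- x$params
  d <- x$derived
  cat(sprintf("One-set-of-sites fit (%d injections)\n", x$n_obs))
  cat(sprintf("  N = %.3g +/- %.2g, KA = %.4g M^-1, dH = %.3g kcal/mol\n",
              p$N, x$se[["N"]], p$KA, p$dH))
  cat(sprintf("  KD = %.4g nM, dG = %.3f kcal/mol, dS = %.2f cal/mol/K\n",
              d$KD_itc * 1e9, d$dG, d$dS))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
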