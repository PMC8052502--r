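#' 1:1 Langmuir sensorgram parameters
#'
#' Parameters of the single-site reversible surface-binding model
#' dR'/dt = ka C (Rmax - R') - kd R', plus a linear baseline drift and a
#' response offset as fitted by drifting-baseline biosensor analysis.
#'
#' @param ka Association rate constant in M^-1 s^-1 (> 0).
#' @param kd Dissociation rate constant in s^-1 (>= 0).
#' @param Rmax Surface capacity in RU (> 0).
#' @param drift Linear baseline slope in RU s^-1.
#' @param R_offset Response offset in RU.
#' @return Object of class `langmuir_params`.
#' @export
#' @examples
#' langmuir_params(ka = 13.1e4, kd = 4.4e-3, Rmax = 35)
langmuir_params <- function(ka, kd, Rmax, drift = 0, R_offset = 0) {
  if (ka <= 0) stop("ka must be > 0", call. = FALSE)
  if (kd < 0) stop("kd must be >= 0", call. = FALSE)
  if (Rmax <= 0) stop("Rmax must be > 0", call. = FALSE)
  structure(list(ka = ka, kd = kd, Rmax = Rmax, drift = drift,
                 R_offset = R_offset),
            class = "langmuir_params")
}

#' Analytic 1:1 Langmuir sensorgram with drifting baseline
#'
#' Association phase: R(t) = R_offset + drift t + Req (1 - exp(-(ka C + kd) t))
#' with Req = ka C Rmax / (ka C + kd). Dissociation (analyte concentration
#' switched to 0 at `t_assoc`): the bound response at the phase boundary
#' decays as exp(-kd (t - t_assoc)) while the drift line continues.
#'
#' @param params A [langmuir_params()].
#' @param C Analyte concentration in M (>= 0).
#' @param t_assoc,t_dissoc Phase durations in s (> 0).
#' @param dt Sampling interval in s.
#' @return `assay_series` (time grid covering both phases) with metadata
#'   `conc`, `t_assoc`, `t_dissoc`.
#' @export
langmuir_response <- function(params, C, t_assoc, t_dissoc, dt = 1) {
  stopifnot(inherits(params, "langmuir_params"))
  if (C < 0) stop("analyte concentration must be >= 0", call. = FALSE)
  stopifnot(t_assoc > 0, t_dissoc > 0, dt > 0)
  t <- seq(0, t_assoc + t_dissoc, by = dt)
  y <- .langmuir_signal(params$ka, params$kd, params$Rmax, params$drift,
                        params$R_offset, C, t, t_assoc)
  assay_series(t, y, kind = "time",
               meta = list(conc = C, t_assoc = t_assoc, t_dissoc = t_dissoc))
}

# vectorized over t; shared by generator and fitter
.langmuir_signal <- function(ka, kd, Rmax, drift, offset, C, t, t_assoc) {
  kobs <- ka * C + kd
  Req <- if (C > 0) ka * C * Rmax / kobs else 0
  bound_assoc <- if (C > 0) Req * (1 - exp(-kobs * pmin(t, t_assoc))) else
    rep(0, length(t))
  bound_end <- if (C > 0) Req * (1 - exp(-kobs * t_assoc)) else 0
  bound <- ifelse(t <= t_assoc, bound_assoc,
                  bound_end * exp(-kd * (t - t_assoc)))
  offset + drift * t + bound
}

#' Double referencing of a sensorgram
#'
#' Subtracts both the reference flow-cell trace and a buffer-blank cycle from
#' a sample sensorgram, pointwise, to remove bulk refractive-index and
#' systematic injection artifacts.
#'
#' @param sample,reference_cell,buffer_blank `assay_series` on overlapping
#'   time grids (interpolated onto the sample grid when they differ).
#' @return Referenced `assay_series`.
#' @export
double_reference <- function(sample, reference_cell, buffer_blank) {
  stopifnot(inherits(sample, "assay_series"))
  ref <- .interp_onto(sample, reference_cell, "reference cell series")
  blank <- .interp_onto(sample, buffer_blank, "buffer blank series")
  meta <- series_meta(sample)
  meta$double_referenced <- TRUE
  assay_series(sample$x, sample$y - ref - blank, kind = "time", meta = meta)
}

#' Equilibrium dissociation constant from kinetic rate constants
#'
#' @param ka Association rate constant in M^-1 s^-1 (> 0).
#' @param kd Dissociation rate constant in s^-1.
#' @return KD = kd/ka in M.
#' @export
#' @examples
#' derive_KD(13.1e4, 4.4e-3) * 1e9  # 33.6 nM
derive_KD <- function(ka, kd) {
  if (any(ka <= 0)) stop("ka must be > 0", call. = FALSE)
  kd / ka
}

#' Global 1:1 Langmuir fit of a concentration series of sensorgrams
#'
#' ka, kd and Rmax are shared across all cycles; the baseline drift slope and
#' response offset are fitted per cycle (the drifting-baseline convention of
#' biosensor evaluation software). Nonlinear least squares over all cycles
#' jointly; ka and Rmax are fitted on the log scale, kd on the natural scale
#' with a lower bound of 0 so a no-dissociation limit is representable.
#'
#' @param cycles List of referenced `assay_series`, each with metadata `conc`
#'   (analyte concentration, M) and `t_assoc` (s). At least 3 distinct
#'   nonzero concentrations are required.
#' @param shared_drift If `TRUE`, one drift slope for all cycles.
#' @param control `minpack.lm::nls.lm.control` list.
#' @return Object of class `langmuir_fit`: `params` ([langmuir_params()] with
#'   the global estimates; drift is the per-cycle mean), `se`, `KD`, `KD_se`,
#'   `chi2` (reduced), `drift` and `R_offset` per cycle, `converged`.
#' @export
fit_sensorgrams_global <- function(cycles, shared_drift = FALSE,
                                   control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(is.list(cycles), length(cycles) >= 1L)
  C <- vapply(cycles, function(s) series_meta(s)$conc %||% NA_real_, 0)
  t_assoc <- vapply(cycles, function(s) series_meta(s)$t_assoc %||% NA_real_, 0)
  if (anyNA(C) || anyNA(t_assoc)) {
    stop("every cycle needs conc and t_assoc metadata", call. = FALSE)
  }
  if (length(unique(C[C > 0])) < 3L) {
    stop("need at least 3 distinct nonzero analyte concentrations",
         call. = FALSE)
  }
  n_cyc <- length(cycles)

  # data-driven initial guesses from the highest-concentration cycle
  i_top <- which.max(C)
  top <- cycles[[i_top]]
  assoc <- top[top$x <= t_assoc[i_top], ]
  dissoc <- top[top$x >= t_assoc[i_top], ]
  Rmax0 <- max(max(top$y), 1e-3) * 1.5
  # kd from the time for the dissociation to fall halfway to its final value
  d_amp <- dissoc$y[1L] - dissoc$y[nrow(dissoc)]
  kd0 <- if (is.finite(d_amp) && d_amp > 0) {
    i_half <- which(dissoc$y <= dissoc$y[1L] - d_amp / 2)[1L]
    t_half <- dissoc$x[i_half] - dissoc$x[1L]
    if (is.finite(t_half) && t_half > 0) log(2) / t_half else 1 / diff(range(dissoc$x))
  } else 1e-4
  # kobs from the association half-time
  a_amp <- max(assoc$y) - assoc$y[1L]
  i_half <- which(assoc$y >= assoc$y[1L] + a_amp / 2)[1L]
  kobs0 <- if (is.finite(i_half) && assoc$x[i_half] > 0) log(2) / assoc$x[i_half] else
    5 / t_assoc[i_top]
  ka0 <- max((kobs0 - kd0) / C[i_top], 0.1 / (C[i_top] * t_assoc[i_top]))

  n_drift <- if (shared_drift) 1L else n_cyc
  theta0 <- c(log(ka0), kd0, log(Rmax0), rep(0, n_drift), rep(0, n_cyc))
  lower <- c(-Inf, 0, -Inf, rep(-Inf, n_drift + n_cyc))

  resid_fn <- function(theta) {
    ka <- exp(theta[1L]); kd <- theta[2L]; Rmax <- exp(theta[3L])
    drift <- theta[4:(3 + n_drift)]
    offset <- theta[(4 + n_drift):(3 + n_drift + n_cyc)]
    unlist(lapply(seq_len(n_cyc), function(i) {
      d_i <- if (shared_drift) drift[1L] else drift[i]
      cycles[[i]]$y - .langmuir_signal(ka, kd, Rmax, d_i, offset[i],
                                       C[i], cycles[[i]]$x, t_assoc[i])
    }), use.names = FALSE)
  }

  fit <- minpack.lm::nls.lm(par = theta0, fn = resid_fn, lower = lower,
                            control = control)
  theta <- fit$par
  ka <- exp(theta[1L]); kd <- theta[2L]; Rmax <- exp(theta[3L])
  drift <- theta[4:(3 + n_drift)]
  offset <- theta[(4 + n_drift):(3 + n_drift + n_cyc)]
  n_obs <- length(fit$fvec)
  n_par <- length(theta)
  sigma2 <- fit$deviance / max(n_obs - n_par, 1L)
  cov <- tryCatch(solve(fit$hessian) * sigma2, error = function(e) NULL)
  se_theta <- if (!is.null(cov) && all(diag(cov) >= 0)) sqrt(diag(cov)) else
    rep(Inf, n_par)
  se <- c(ka = ka * se_theta[1L], kd = se_theta[2L], Rmax = Rmax * se_theta[3L])
  KD <- derive_KD(ka, kd)
  KD_se <- if (kd > 0) KD * sqrt(se_theta[1L]^2 + (se[["kd"]] / kd)^2) else
    se[["kd"]] / ka

  structure(
    list(
      params = langmuir_params(ka, kd, Rmax, drift = mean(drift),
                               R_offset = mean(offset)),
      se = se,
      KD = KD, KD_se = KD_se,
      chi2 = sigma2,
      drift = drift, R_offset = offset,
      converged = fit$info %in% 1:4,
      n_obs = n_obs, info = fit$info, message = fit$message
    ),
    class = "langmuir_fit"
  )
}

#' @export
print.langmuir_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("1:1 Langmuir global fit (%d points, chi2 = %.3g)\n",
              x$n_obs, x$chi2))
  cat(sprintf("  ka = %.4g +/- %.2g M^-1 s^-1\n", p$ka, x$se[["ka"]]))
  cat(sprintf("  kd = %.4g +/- %.2g s^-1\n", p$kd, x$se[["kd"]]))
  cat(sprintf("  KD = %.4g nM\n", x$KD * 1e9))
  invisible(x)
}

#' Replicate statistics of kinetic binding constants
#'
#' Per-experiment KD values are formed first (KD_i = kd_i/ka_i), then each of
#' ka, kd and KD is summarized as mean and sample standard deviation across
#' experiments. This matches the convention of tabulating mean KD from
#' per-experiment KDs rather than mean(kd)/mean(ka); the two differ by a few
#' percent on real replicate scatter.
#'
#' @param ka,kd Numeric vectors of per-experiment estimates (equal length).
#' @return List of class `binding_constants` with `ka`, `kd`, `KD` as
#'   [summarize_replicates()] objects.
#' @export
summarize_binding_constants <- function(ka, kd) {
  stopifnot(length(ka) == length(kd), length(ka) >= 1L)
  structure(
    list(ka = summarize_replicates(ka),
         kd = summarize_replicates(kd),
         KD = summarize_replicates(derive_KD(ka, kd))),
    class = "binding_constants"
  )
}
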