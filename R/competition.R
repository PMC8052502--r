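#' Solution-competition binding model
#'
#' Competition between an enzyme binding a fixed immobilized ligand on the
#' sensor surface (dissociation constant `kd_core`) and a solution competitor
#' (dissociation constant `kd_sol`, the fitted unknown). The equilibrium
#' surface response at each total competitor concentration reports the free
#' enzyme remaining in solution.
#'
#' @param e_tot Total enzyme concentration in M (> 0).
#' @param kd_core Surface-ligand dissociation constant in M (> 0).
#' @param kd_sol Solution dissociation constant in M (> 0).
#' @param r_max,r_min Maximum and minimum equilibrium responses in RU
#'   (`r_max > r_min`).
#' @return Object of class `competition_model`.
#' @export
#' @examples
#' competition_model(kd_sol = 11.1e-9, r_max = 100)
competition_model <- function(e_tot = 700e-9, kd_core = 240e-9, kd_sol,
                              r_max, r_min = 0) {
  stopifnot(e_tot > 0, kd_core > 0, kd_sol > 0)
  if (r_max <= r_min) stop("r_max must exceed r_min", call. = FALSE)
  structure(list(e_tot = e_tot, kd_core = kd_core, kd_sol = kd_sol,
                 r_max = r_max, r_min = r_min),
            class = "competition_model")
}

#' Equilibrium solution-complex concentration (exact quadratic root)
#'
#' Solves the 1:1 mass-action equilibrium E + C <-> EC at total
#' concentrations `e_tot`, `c_tot` and dissociation constant `kd_sol`:
#' \[EC\] = (s - sqrt(s^2 - 4 e_tot c_tot))/2 with s = e_tot + c_tot + kd_sol,
#' the physically valid (minus) root. Evaluated in the conjugate form
#' 2 e_tot c_tot / (s + sqrt(s^2 - 4 e_tot c_tot)), which avoids catastrophic
#' cancellation when the two terms are nearly equal (e.g. c_tot >> e_tot).
#'
#' @param e_tot Total enzyme in M (> 0).
#' @param c_tot Total competitor in M (>= 0); vectorized.
#' @param kd_sol Dissociation constant in M (> 0).
#' @return Complex concentration in M, in \[0, min(e_tot, c_tot)\].
#' @export
#' @examples
#' complex_concentration(700e-9, 2000e-9, 11.1e-9) * 1e9  # ~694 nM
complex_concentration <- function(e_tot, c_tot, kd_sol) {
  if (any(e_tot <= 0) || any(kd_sol <= 0) || any(c_tot < 0)) {
    stop("e_tot and kd_sol must be > 0, c_tot >= 0", call. = FALSE)
  }
  s <- e_tot + c_tot + kd_sol
  disc <- s^2 - 4 * e_tot * c_tot
  disc[disc < 0] <- 0  # guard against rounding; true disc >= kd_sol^2 > 0
  2 * e_tot * c_tot / (s + sqrt(disc))
}

#' Equilibrium surface response under competition
#'
#' Free enzyme E_free = e_tot - \[EC\] feeds the surface-binding hyperbola:
#' Req = r_min + (r_max - r_min) E_free / (kd_core + E_free).
#'
#' @param model A [competition_model()].
#' @param c_tot Total competitor concentration(s) in M (>= 0).
#' @return Equilibrium response(s) in RU, in \[r_min, r_max).
#' @export
req_model <- function(model, c_tot) {
  stopifnot(inherits(model, "competition_model"))
  e_free <- model$e_tot - complex_concentration(model$e_tot, c_tot, model$kd_sol)
  model$r_min + (model$r_max - model$r_min) * e_free / (model$kd_core + e_free)
}

#' Fit the solution dissociation constant from a competition titration
#'
#' Nonlinear least squares over (kd_sol, r_max) with e_tot, kd_core and r_min
#' held at their supplied fixed values; kd_sol is fitted on the log scale.
#' A titration without a zero-competitor anchor point is accepted but flagged
#' in the fit metadata; an unidentifiable fit (kd_sol far above the probed
#' concentration range, flat curve) is flagged via `identifiable = FALSE`
#' when the standard error on log kd_sol exceeds one decade.
#'
#' @param series `assay_series` with `x` = total competitor concentration (M)
#'   and `y` = equilibrium response (RU); at least 4 concentrations.
#' @param e_tot,kd_core,r_min Fixed model parameters.
#' @param control `minpack.lm::nls.lm.control` list.
#' @return Object of class `competition_fit`: `kd_sol`, `kd_sol_se`, `r_max`,
#'   `r_max_se`, `identifiable`, `warnings`, `converged`, `residual_norm`.
#' @export
fit_kdsol <- function(series, e_tot = 700e-9, kd_core = 240e-9, r_min = 0,
                      control = minpack.lm::nls.lm.control(maxiter = 200)) {
  stopifnot(inherits(series, "assay_series"))
  c_tot <- series$x
  req <- series$y
  if (length(unique(c_tot)) < 4L) {
    stop("need at least 4 competitor concentrations", call. = FALSE)
  }
  warns <- character(0)
  if (!any(c_tot == 0)) {
    warns <- c(warns, "no zero-competitor anchor point")
  }

  # initial guesses: invert the c_tot = 0 hyperbola for r_max; kd_sol from
  # the concentration at which the response has fallen halfway
  req0 <- if (any(c_tot == 0)) mean(req[c_tot == 0]) else max(req)
  r_max0 <- max((req0 - r_min) * (kd_core + e_tot) / e_tot + r_min, 1e-3)
  half <- r_min + (req0 - r_min) / 2
  below <- which(req <= half & c_tot > 0)
  kd_sol0 <- if (length(below)) {
    max(min(c_tot[below]) - e_tot / 2, min(c_tot[c_tot > 0]) / 10, 1e-12)
  } else {
    max(c_tot) * 10  # curve barely drops: start above the probed range
  }

  resid_fn <- function(theta) {
    m <- competition_model(e_tot, kd_core, exp(theta[1L]),
                           r_max = theta[2L], r_min = r_min)
    req - req_model(m, c_tot)
  }
  fit <- minpack.lm::nls.lm(par = c(log(kd_sol0), r_max0), fn = resid_fn,
                            control = control)
  kd_sol <- exp(fit$par[1L]); r_max <- fit$par[2L]
  n_obs <- length(fit$fvec)
  sigma2 <- fit$deviance / max(n_obs - 2L, 1L)
  cov <- tryCatch(solve(fit$hessian) * sigma2, error = function(e) NULL)
  se_theta <- if (!is.null(cov) && all(diag(cov) >= 0)) sqrt(diag(cov)) else
    rep(Inf, 2L)
  identifiable <- is.finite(se_theta[1L]) && se_theta[1L] < log(10)

  structure(
    list(kd_sol = kd_sol, kd_sol_se = kd_sol * se_theta[1L],
         r_max = r_max, r_max_se = se_theta[2L],
         fixed = list(e_tot = e_tot, kd_core = kd_core, r_min = r_min),
         identifiable = identifiable, warnings = warns,
         converged = fit$info %in% 1:4,
         residual_norm = sqrt(fit$deviance), n_obs = n_obs),
    class = "competition_fit"
  )
}

#' @export
print.competition_fit <- function(x, ...) {
  cat(sprintf("Competition fit: KDsol = %.4g +/- %.2g nM (r_max = %.4g RU)%s\n",
              x$kd_sol * 1e9, x$kd_sol_se * 1e9, x$r_max,
              if (!x$identifiable) " [poorly identified]" else ""))
  invisible(x)
}
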