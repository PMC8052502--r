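# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms: fixed-step RK4 for the kinetic ODE, bisection
# on the mass-action equilibrium for binding, and a numeric ODE route for
# the Langmuir sensorgram.

# fixed-step RK4 integration of the Van Slyke-Cullen system; returns state
# at the requested output times (which must be multiples of dt)
rk4_vsc <- function(k1, k2, S0, E0, t_out, dt) {
  rhs <- function(y) {
    E <- E0 - y[2L]
    v1 <- k1 * E * y[1L]
    v2 <- k2 * y[2L]
    c(-v1, v1 - v2, v2)
  }
  t_end <- max(t_out)
  n <- round(t_end / dt)
  y <- c(S0, 0, 0)
  keep <- matrix(NA_real_, nrow = length(t_out), ncol = 3L)
  idx <- round(t_out / dt)
  if (any(abs(idx * dt - t_out) > 1e-9)) stop("t_out must align with dt")
  if (any(idx == 0L)) keep[idx == 0L, ] <- rep(y, each = sum(idx == 0L))
  for (s in seq_len(n)) {
    k_1 <- rhs(y)
    k_2 <- rhs(y + dt / 2 * k_1)
    k_3 <- rhs(y + dt / 2 * k_2)
    k_4 <- rhs(y + dt * k_3)
    y <- y + dt / 6 * (k_1 + 2 * k_2 + 2 * k_3 + k_4)
    hit <- which(idx == s)
    if (length(hit)) keep[hit, ] <- rep(y, each = length(hit))
  }
  data.frame(time = t_out, S = keep[, 1L], ES = keep[, 2L], P = keep[, 3L])
}

# bisection on the 1:1 mass-action equilibrium: complex x solves
# (e - x)(c - x) = kd * x, x in [0, min(e, c)]
bisect_complex <- function(e_tot, c_tot, kd, iter = 200L) {
  vapply(seq_along(c_tot), function(i) {
    c_i <- c_tot[i]
    if (c_i == 0) return(0)
    lo <- 0
    hi <- min(e_tot, c_i)
    g <- function(x) (e_tot - x) * (c_i - x) - kd * x
    for (k in seq_len(iter)) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, 0)
}

# numeric-ODE sensorgram: integrate dR'/dt = ka C (Rmax - R') - kd R' through
# association, then C = 0 through dissociation; add drift line afterwards
ode_langmuir <- function(ka, kd, Rmax, drift, offset, C, t, t_assoc) {
  rhs <- function(tt, y, p) list(p$ka * p$C * (p$Rmax - y) - p$kd * y)
  t_a <- sort(unique(c(0, t[t <= t_assoc], t_assoc)))
  sol_a <- deSolve::lsoda(c(R = 0), t_a, rhs,
                          parms = list(ka = ka, kd = kd, Rmax = Rmax, C = C),
                          rtol = 1e-11, atol = 1e-12)
  R_end <- sol_a[nrow(sol_a), "R"]
  t_d <- sort(unique(c(t_assoc, t[t >= t_assoc])))
  sol_d <- deSolve::lsoda(c(R = R_end), t_d, rhs,
                          parms = list(ka = ka, kd = kd, Rmax = Rmax, C = 0),
                          rtol = 1e-11, atol = 1e-12)
  bound <- ifelse(t <= t_assoc,
                  stats::approx(sol_a[, 1L], sol_a[, 2L], xout = t)$y,
                  stats::approx(sol_d[, 1L], sol_d[, 2L], xout = t)$y)
  offset + drift * t + bound
}

# canonical generating parameters used throughout the tests
ref_vsc <- function() vsc_params(kcat = 0.886, Km = 185e-9,
                                 signal_gain = 2e9, baseline = 10)
ref_langmuir <- function(drift = 0, R_offset = 0)
  langmuir_params(ka = 13.1e4, kd = 4.4e-3, Rmax = 35,
                  drift = drift, R_offset = R_offset)
ref_one_site <- function() one_site_params(N = 1, KA = 1 / 30.8e-9, dH = -9.4)
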