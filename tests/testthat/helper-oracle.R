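# Independent reference integration of the two-moment system: its own
# RHS definition and an implicit Runge-Kutta (Radau IIA) solver at tight
# tolerance, so package results are checked against a genuinely separate
# numerical path.
oracle_moments <- function(params, times, rtol = 1e-10, atol_frac = 1e-12) {
  rhs <- function(t, y, p) {
    m <- max(p$m_total - y[[1L]], 0)
    list(c(2 * p$k_plus * m * y[[2L]],
           p$k_n * m^p$n_c + p$k_2 * m^p$n_2 * y[[1L]]))
  }
  grid <- if (times[[1L]] > 0) c(0, times) else times
  sol <- deSolve::radau(
    y = c(M = params$M_0, P = params$P_0), times = grid, func = rhs,
    parms = params, rtol = rtol, atol = atol_frac * params$m_total)
  if (times[[1L]] > 0) sol <- sol[-1L, , drop = FALSE]
  sol[, "M"]
}

# Half-time by bisection on a dense oracle curve (spline-interpolated),
# independent of the package's crossing/interpolation code.
oracle_halftime <- function(params, t_max, frac_of_plateau = NULL) {
  tt <- seq(0, t_max, length.out = 2000L)
  M <- oracle_moments(params, tt)
  plateau <- M[[length(M)]]
  target <- params$M_0 + (plateau - params$M_0) / 2
  f <- stats::splinefun(tt, M, method = "hyman")
  lo <- 0
  hi <- t_max
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random valid parameter sets around the package's default regime, on
# log-uniform scales wide enough to exercise the integrator.
random_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      kinetic_params(
        k_n = 10^stats::runif(1, -7.5, -5),
        k_2 = 10^stats::runif(1, -4.5, -2.5),
        k_plus = 10^stats::runif(1, 3.2, 4.5),
        m_total = stats::runif(1, 1, 5),
        M_0 = 0, P_0 = 0)
    })
  })
}

default_truth_factor <- function(dose, f_top = 0.1, dose_top = 10,
                                 f_plus_top = 0.5) {
  ifelse(dose == 0, 1,
         f_top^(dose / dose_top) * ifelse(dose >= dose_top, f_plus_top, 1))
}
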