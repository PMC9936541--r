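#' Aggregation curve container
#'
#' A time series of fibril mass (model space, uM) or ThT fluorescence
#' (measurement space, a.u.) for one well or condition.
#'
#' @param times Strictly increasing time grid, hours.
#' @param values Finite numeric values, same length as `times`.
#' @param kind `"model-mass"` or `"fluorescence"`.
#' @param metadata Optional named list of condition labels.
#' @return An object of class `aggregation_curve`.
#' @export
aggregation_curve <- function(times, values,
                              kind = c("model-mass", "fluorescence"),
                              metadata = list()) {
  kind <- match.arg(kind)
  if (length(times) != length(values))
    stop_input("times and values must have equal length")
  if (length(times) < 2L || any(diff(times) <= 0))
    stop_input("times must be strictly increasing with >= 2 points")
  if (any(!is.finite(values)))
    stop_input("values must be finite")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind, metadata = metadata),
            class = "aggregation_curve")
}

#' @export
print.aggregation_curve <- function(x, ...) {
  cat(sprintf("<aggregation_curve: %s, %d points, t in [%.3g, %.3g] h>\n",
              x$kind, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

moments_rhs <- function(t, y, p) {
  M <- y[[1L]]
  m <- p$m_total - M
  if (m < 0) m <- 0
  dM <- 2 * p$k_plus * m * y[[2L]]
  dP <- p$k_n * m^p$n_c + p$k_2 * m^p$n_2 * M
  list(c(dM, dP))
}

#' Integrate the two-moment aggregation model
#'
#' Solves the quiescent moment equations for fibril number P and fibril
#' mass M under the monomer conservation constraint
#' `m(t) = m_total - M(t)`:
#' \deqn{dP/dt = k_n m^{n_c} + k_2 m^{n_2} M, \quad dM/dt = 2 k_+ m P}
#' with a stiff-capable adaptive integrator.
#'
#' @param params A `kinetic_params` object.
#' @param times Time grid in hours, starting at or after 0.
#' @param rtol,atol Relative and absolute integration tolerances. The
#'   absolute tolerance is expressed as a fraction of `m_total`.
#' @param method deSolve integration method; default `"lsoda"`.
#' @return An `aggregation_curve` of kind `"model-mass"` containing M(t)
#'   in uM; the fibril number series is attached as attribute `"number"`.
#' @examples
#' p <- default_params()
#' curve <- integrate_moments(p, seq(0, 4, by = 1 / 30))
#' halftime(curve)
#' @export
integrate_moments <- function(params, times, rtol = 1e-10, atol = 1e-12,
                              method = "lsoda") {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(times) < 2L || any(diff(times) <= 0) || times[[1L]] < 0)
    stop_input("times must be strictly increasing and non-negative")
  grid <- times
  prepend <- grid[[1L]] > 0
  if (prepend) grid <- c(0, grid)
  # solver complaints (step-size underflow at hopeless parameter sets
  # during multi-start fitting) are diagnosed from the returned object,
  # not from warnings
  sol <- suppressWarnings(deSolve::ode(
    y = c(M = params$M_0, P = params$P_0),
    times = grid, func = moments_rhs, parms = params,
    method = method, rtol = rtol, atol = atol * params$m_total
  ))
  if (prepend) sol <- sol[-1L, , drop = FALSE]
  M <- sol[, "M"]
  P <- sol[, "P"]
  if (nrow(sol) != length(times) || any(!is.finite(M)) || any(!is.finite(P)))
    abort(sprintf(
      "moment integration failed (k_n=%.3g, k_2=%.3g, k_plus=%.3g, m_total=%.3g, M_0=%.3g, P_0=%.3g)",
      params$k_n, params$k_2, params$k_plus, params$m_total,
      params$M_0, params$P_0),
      "amylokin_integration_failure")
  # clip integrator jitter at the conservation boundaries
  M <- pmin(pmax(M, 0), params$m_total)
  out <- aggregation_curve(times, M, kind = "model-mass",
                           metadata = list(params = params))
  attr(out, "number") <- P
  out
}

#' Closed-form unseeded mass fraction
#'
#' Fast analytical approximation to the unseeded solution of the
#' two-moment model, accurate in the secondary-nucleation-dominated
#' regime (kappa >> lambda). Uses the standard fixed-point solution
#' \deqn{M(t)/m_{tot} = 1 - \left(\frac{B_+ + C_+}{B_+ + C_+ e^{\kappa t}}
#'   \cdot \frac{B_- + C_+ e^{\kappa t}}{B_- + C_+}\right)^{k_\infty^2 /
#'   (\kappa \bar k_\infty)} e^{-k_\infty t}}
#' with the usual definitions of the combined rates.
#'
#' @inheritParams integrate_moments
#' @return An `aggregation_curve` of kind `"model-mass"` (uM).
#' @export
analytical_mass_fraction <- function(params, times) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$M_0 != 0 || params$P_0 != 0)
    abort("closed-form path supports unseeded reactions only (M_0 = P_0 = 0)",
          "amylokin_unsupported_input")
  if (length(times) < 2L || any(diff(times) <= 0) || times[[1L]] < 0)
    stop_input("times must be strictly increasing and non-negative")
  m0 <- params$m_total
  dr <- derived_rates(params)
  lam <- dr$lambda_rate
  kap <- dr$kappa_rate
  if (lam == 0) # no primary nucleation and no seeds: nothing ever forms
    return(aggregation_curve(times, rep(0, length(times)), "model-mass",
                             metadata = list(params = params)))
  if (kap == 0) {
    # primary-only limit: M = m0 (1 - sech(lambda' t)^...) is not needed at
    # the package's regimes; fall back to the integrator for correctness.
    return(integrate_moments(params, times))
  }
  Cp <- lam^2 / (2 * kap^2)
  Cm <- -Cp
  kinf <- sqrt(2 * kap^2 / (params$n_2 * (params$n_2 + 1)) +
                 2 * lam^2 / params$n_c)
  kbar <- sqrt(kinf^2 - 4 * Cp * Cm * kap^2)
  Bp <- (kinf + kbar) / (2 * kap)
  Bm <- (kinf - kbar) / (2 * kap)
  kt <- kap * times
  # log(B + Cp * exp(kt)) computed overflow-safe as kt + log(Cp + B exp(-kt))
  logBpE <- kt + log(Cp + Bp * exp(-kt))
  logBmE <- kt + log(Cp + Bm * exp(-kt))
  logbracket <- (log(Bp + Cp) - logBpE) + (logBmE - log(Bm + Cp))
  logfrac <- (kinf^2 / (kap * kbar)) * logbracket - kinf * times
  M <- m0 * (1 - exp(logfrac))
  M <- pmin(pmax(M, 0), m0)
  aggregation_curve(times, M, "model-mass", metadata = list(params = params))
}

#' Half-time of a sigmoidal aggregation curve
#'
#' The half-time t1/2 is the earliest time at which the
#' baseline-subtracted signal crosses half of the baseline-subtracted
#' plateau, linearly interpolated between samples. Baseline and plateau
#' are estimated as the means of the first and last `k` points unless
#' given explicitly. The statistic is invariant under affine transforms
#' of the signal.
#'
#' @param curve An `aggregation_curve`, or a numeric vector of values
#'   (then `times` must be supplied).
#' @param times Time grid when `curve` is a plain numeric vector.
#' @param k Number of points averaged for the baseline and plateau
#'   estimates.
#' @param baseline,plateau Optional explicit baseline/plateau values,
#'   overriding the window estimates.
#' @param flat_tol A curve is considered converged to its plateau when
#'   the signal gain over the final 15% of the window is at most
#'   `flat_tol` of the total rise.
#' @return The half-time in hours.
#' @export
halftime <- function(curve, times = NULL, k = 5, baseline = NULL,
                     plateau = NULL, flat_tol = 0.05) {
  if (inherits(curve, "aggregation_curve")) {
    y <- curve$values
    t <- curve$times
  } else {
    y <- as.numeric(curve)
    t <- times
    if (is.null(t)) stop_input("supply 'times' with a plain numeric curve")
  }
  n <- length(y)
  if (n < 2 * k) stop_input("curve too short for half-time extraction")
  b <- if (is.null(baseline)) mean(y[seq_len(k)]) else baseline
  p <- if (is.null(plateau)) mean(y[seq.int(n - k + 1L, n)]) else plateau
  rise <- p - b
  scale <- max(abs(y), 1e-300)
  if (!is.finite(rise) || rise <= 1e-9 * scale)
    abort("flat or decreasing curve: no aggregation signal to halve",
          "amylokin_degenerate_curve")
  # plateau convergence: the late window must have stopped rising
  t_span <- t[n] - t[1L]
  i_late <- which(t >= t[n] - 0.15 * t_span)
  if (length(i_late) >= 2L) {
    late_gain <- mean(y[i_late[seq.int(max(1L, length(i_late) - k + 1L),
                                       length(i_late))]]) -
      mean(y[i_late[seq_len(min(k, length(i_late)))]])
    if (late_gain > flat_tol * rise)
      abort("curve has not converged to a plateau within the sampled window",
            "amylokin_not_converged")
  }
  half <- b + rise / 2
  above <- which(y >= half)
  if (length(above) == 0L)
    abort("signal never reaches half of the estimated plateau",
          "amylokin_not_converged")
  i <- above[[1L]]
  if (i == 1L) return(t[[1L]])
  # linear interpolation between the bracketing samples
  t[[i - 1L]] + (half - y[[i - 1L]]) / (y[[i]] - y[[i - 1L]]) *
    (t[[i]] - t[[i - 1L]])
}
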