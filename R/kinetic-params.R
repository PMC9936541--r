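#' Kinetic parameters for one Abeta42 aggregation reaction
#'
#' Bundles the microscopic rate constants, reaction orders and initial
#' moments of the quiescent aggregation model. Concentrations are in uM
#' (monomer equivalents), time in hours, so e.g. `k_plus` is in 1/(uM h).
#'
#' The three microscopic processes are: primary nucleation (rate constant
#' `k_n`, depends on free monomer only), secondary nucleation (`k_2`,
#' catalysed by existing fibril mass), and elongation (`k_plus`, addition
#' of monomers to growth-competent fibril ends).
#'
#' @param k_n Primary nucleation rate constant, uM^(1-n_c)/h.
#' @param k_2 Secondary nucleation rate constant, uM^(-n_2)/h.
#' @param k_plus Elongation rate constant, 1/(uM h).
#' @param n_c Primary nucleation reaction order (>= 1).
#' @param n_2 Secondary nucleation reaction order (>= 1).
#' @param m_total Total monomer-equivalent concentration, uM.
#' @param M_0 Initial fibril mass concentration, uM monomer equivalents
#'   (seed mass); 0 for unseeded reactions.
#' @param P_0 Initial fibril number concentration, uM. Must be positive
#'   whenever `M_0 > 0`.
#' @return An object of class `kinetic_params` (a validated named list).
#' @examples
#' p <- kinetic_params(k_n = 1.1e-6, k_2 = 7e-4, k_plus = 1e4, m_total = 2)
#' derived_rates(p)
#' @export
kinetic_params <- function(k_n, k_2, k_plus, n_c = 2, n_2 = 2,
                           m_total, M_0 = 0, P_0 = 0) {
  for (nm in c("k_n", "k_2", "k_plus", "n_c", "n_2", "m_total", "M_0", "P_0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_input(sprintf("'%s' must be a single finite number", nm))
  }
  if (k_n < 0 || k_2 < 0 || k_plus < 0)
    stop_input("rate constants k_n, k_2, k_plus must be non-negative")
  if (n_c < 1 || n_2 < 1)
    stop_input("reaction orders n_c, n_2 must be >= 1")
  if (m_total <= 0)
    stop_input("m_total must be positive")
  if (M_0 < 0 || M_0 >= m_total)
    stop_input("M_0 must satisfy 0 <= M_0 < m_total")
  if (P_0 < 0)
    stop_input("P_0 must be non-negative")
  if (M_0 > 0 && P_0 <= 0)
    stop_input("seeded reactions (M_0 > 0) need a positive fibril number P_0")
  structure(
    list(k_n = k_n, k_2 = k_2, k_plus = k_plus, n_c = n_c, n_2 = n_2,
         m_total = m_total, M_0 = M_0, P_0 = P_0),
    class = "kinetic_params"
  )
}

#' Default ground-truth parameters for the synthetic assays
#'
#' Literature-plausible constants for Abeta42 at 2 uM monomer under
#' quiescent conditions: elongation near the diffusion-limited regime
#' (`k_plus` = 1e4 /(uM h), about 3e6 /(M s)) with nucleation constants
#' chosen so the unseeded half-time is ~0.77 h and the reaction is
#' secondary-nucleation dominated (kappa/lambda ~ 35).
#'
#' @param m_total Total monomer concentration, uM.
#' @param seed_mass_fraction Fraction of `m_total` supplied as preformed
#'   fibril mass (0 for unseeded).
#' @param seed_length Mean seed length in monomers; sets
#'   `P_0 = M_0 / seed_length`.
#' @return A `kinetic_params` object.
#' @export
default_params <- function(m_total = 2, seed_mass_fraction = 0,
                           seed_length = 500) {
  M0 <- seed_mass_fraction * m_total
  kinetic_params(k_n = 1.1e-6, k_2 = 7e-4, k_plus = 1e4,
                 n_c = 2, n_2 = 2, m_total = m_total,
                 M_0 = M0, P_0 = if (M0 > 0) M0 / seed_length else 0)
}

#' Apply multiplicative modulator factors to rate constants
#'
#' @param params A `kinetic_params` object.
#' @param factors Numeric vector `c(f_n, f_2, f_plus)` of positive
#'   multiplicative factors applied to `(k_n, k_2, k_plus)`.
#' @return A new `kinetic_params` object.
#' @export
apply_factors <- function(params, factors) {
  stopifnot(inherits(params, "kinetic_params"))
  if (length(factors) != 3L || any(!is.finite(factors)) || any(factors <= 0))
    stop_input("factors must be three positive finite numbers (f_n, f_2, f_plus)")
  kinetic_params(k_n = params$k_n * factors[[1L]],
                 k_2 = params$k_2 * factors[[2L]],
                 k_plus = params$k_plus * factors[[3L]],
                 n_c = params$n_c, n_2 = params$n_2,
                 m_total = params$m_total, M_0 = params$M_0, P_0 = params$P_0)
}

#' Combined proliferation rates lambda and kappa
#'
#' `lambda = sqrt(2 k_plus k_n m_total^n_c)` measures proliferation
#' through primary nucleation, `kappa = sqrt(2 k_plus k_2
#' m_total^(n_2+1))` through secondary nucleation; both in 1/h. Their
#' ratio identifies the dominant nucleation pathway, and only the
#' underlying products `k_plus*k_n` and `k_plus*k_2` are identifiable
#' from unseeded normalized kinetics.
#'
#' @param params A `kinetic_params` object.
#' @return A list with elements `lambda_rate` and `kappa_rate` (1/h).
#' @export
derived_rates <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  list(
    lambda_rate = sqrt(2 * params$k_plus * params$k_n *
                         params$m_total^params$n_c),
    kappa_rate = sqrt(2 * params$k_plus * params$k_2 *
                        params$m_total^(params$n_2 + 1))
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Aggregation kinetic parameters (uM, h):\n")
  cat(sprintf("  k_n = %.4g  k_2 = %.4g  k_plus = %.4g  (n_c = %g, n_2 = %g)\n",
              x$k_n, x$k_2, x$k_plus, x$n_c, x$n_2))
  cat(sprintf("  m_total = %.4g uM  M_0 = %.4g uM  P_0 = %.4g uM\n",
              x$m_total, x$M_0, x$P_0))
  dr <- derived_rates(x)
  cat(sprintf("  lambda = %.4g /h  kappa = %.4g /h\n",
              dr$lambda_rate, dr$kappa_rate))
  invisible(x)
}
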