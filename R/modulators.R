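#' Modulator specification
#'
#' Describes how a small molecule perturbs the microscopic rate
#' constants as a function of dose (in molar equivalents, ME, i.e.
#' multiples of the monomer concentration). The effect is multiplicative
#' on `(k_n, k_2, k_plus)`; a dose of 0 always maps to factors
#' `(1, 1, 1)`.
#'
#' Modes:
#' \itemize{
#'   \item `inhibitor` / `accelerator` / `null`: factors follow
#'     `effect_fn(dose)` directly.
#'   \item `micellar-switch`: an amphiphile that inhibits in its
#'     monomeric state but, above its critical assembly concentration
#'     (`switch_threshold`, ME), self-assembles into structures whose
#'     surface accelerates aggregation. Below the threshold
#'     `effect_fn(dose)` is used; at or above it, `micellar_fn(dose)`.
#' }
#'
#' @param name Compound label.
#' @param mode One of `"inhibitor"`, `"accelerator"`, `"null"`,
#'   `"micellar-switch"`.
#' @param effect_fn Function mapping a dose (ME) to positive factors
#'   `c(f_n, f_2, f_plus)`. Defaults to no effect.
#' @param switch_threshold Dose (ME) at which a micellar-switch compound
#'   converts from its monomeric to its assembled behaviour.
#' @param micellar_fn Factor function used at or above
#'   `switch_threshold` (micellar-switch mode only).
#' @return An object of class `modulator_spec`.
#' @export
modulator_spec <- function(name, mode = c("inhibitor", "accelerator", "null",
                                          "micellar-switch"),
                           effect_fn = NULL, switch_threshold = 0.3,
                           micellar_fn = NULL) {
  mode <- match.arg(mode)
  if (mode == "null" || is.null(effect_fn))
    effect_fn <- function(dose) c(1, 1, 1)
  if (mode == "micellar-switch" && is.null(micellar_fn))
    stop_input("micellar-switch modulators need a micellar_fn")
  structure(list(name = name, mode = mode, effect_fn = effect_fn,
                 switch_threshold = switch_threshold,
                 micellar_fn = micellar_fn),
            class = "modulator_spec")
}

#' Evaluate a modulator's rate-constant factors at a dose
#'
#' @param modulator A `modulator_spec`.
#' @param dose Dose in molar equivalents (>= 0).
#' @return Numeric `c(f_n, f_2, f_plus)`, all positive; `c(1, 1, 1)` at
#'   dose 0 and for null modulators.
#' @export
modulator_factors <- function(modulator, dose) {
  stopifnot(inherits(modulator, "modulator_spec"))
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0)
    stop_input("dose must be a single non-negative number (ME)")
  if (dose == 0 || modulator$mode == "null") return(c(1, 1, 1))
  fn <- if (modulator$mode == "micellar-switch" &&
              dose >= modulator$switch_threshold)
    modulator$micellar_fn else modulator$effect_fn
  f <- as.numeric(fn(dose))
  if (length(f) != 3L || any(!is.finite(f)) || any(f <= 0))
    stop_input(sprintf("effect_fn of '%s' must return three positive factors",
                       modulator$name))
  f
}

#' Canonical modulator constructors for the synthetic assays
#'
#' Convenience specs mirroring the behaviours seen in vitamin-metabolite
#' screens of Abeta42 aggregation:
#' \itemize{
#'   \item `modulator_simple()`: dose-independent factors on
#'     `(k_n, k_2)`, used for screen-style single-dose conditions.
#'   \item `retinoid_like()`: a dose-dependent nucleation inhibitor with
#'     exponentially decreasing `f_n`, `f_2` (reaching `f_top` at
#'     `dose_top`) and unaffected elongation except at the top dose,
#'     where `f_plus = f_plus_top`.
#'   \item `tocopherol_like()`: an amphiphilic micellar-switch compound,
#'     monomeric inhibitor below `switch_threshold` ME and accelerator
#'     above it.
#' }
#'
#' @param name Compound label.
#' @param f_n,f_2,f_plus Multiplicative factors (simple spec).
#' @param mode Direction label for the simple spec.
#' @return A `modulator_spec`.
#' @export
modulator_simple <- function(name, f_n = 1, f_2 = 1, f_plus = 1,
                             mode = if (f_n < 1 || f_2 < 1) "inhibitor"
                                    else if (f_n > 1 || f_2 > 1) "accelerator"
                                    else "null") {
  force(f_n); force(f_2); force(f_plus)
  modulator_spec(name, mode = mode,
                 effect_fn = function(dose) c(f_n, f_2, f_plus))
}

#' @rdname modulator_simple
#' @param f_top Factor on `k_n` and `k_2` reached at `dose_top`.
#' @param dose_top Top dose of the series (ME).
#' @param f_plus_top Elongation factor applied at `dose >= dose_top`
#'   only.
#' @export
retinoid_like <- function(name = "retinoic-acid-like", f_top = 0.1,
                          dose_top = 10, f_plus_top = 0.5) {
  force(f_top); force(dose_top); force(f_plus_top)
  modulator_spec(name, mode = "inhibitor", effect_fn = function(dose) {
    f <- f_top^(dose / dose_top)   # monotone decreasing, 1 -> f_top
    c(f, f, if (dose >= dose_top) f_plus_top else 1)
  })
}

#' @rdname modulator_simple
#' @param f_inhibit Nucleation factor of the monomeric (sub-threshold)
#'   form at its reference dose.
#' @param f_accelerate Nucleation factor of the micellar form at 1 ME.
#' @param switch_threshold Critical assembly concentration, ME.
#' @export
tocopherol_like <- function(name = "alpha-tocopherol-like",
                            f_inhibit = 0.5, f_accelerate = 8,
                            switch_threshold = 0.3) {
  force(f_inhibit); force(f_accelerate); force(switch_threshold)
  modulator_spec(
    name, mode = "micellar-switch", switch_threshold = switch_threshold,
    effect_fn = function(dose) {
      # monomeric inhibition strengthens smoothly with sub-CMC dose
      f <- f_inhibit^(dose / switch_threshold)
      c(f, f, 1)
    },
    micellar_fn = function(dose) {
      f <- f_accelerate^pmin(dose, 1)  # surface catalysis saturates by 1 ME
      c(f, f, 1)
    })
}

#' Plate-reader noise model
#'
#' Measurement imperfections applied to noiseless model curves:
#' per-well lognormal spread of the fluorescence amplitude
#' (`amplitude_cv`), additive Gaussian noise per time point (`point_sd`,
#' as a fraction of the plateau amplitude), a constant baseline offset
#' and a slow linear drift.
#'
#' @param amplitude_cv Coefficient of variation of the per-well plateau
#'   amplitude (lognormal).
#' @param point_sd Additive per-point Gaussian SD, fraction of plateau.
#' @param baseline_offset Baseline fluorescence, a.u.
#' @param drift_slope Linear baseline drift, a.u. per hour.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(amplitude_cv = 0.05, point_sd = 0.02,
                        baseline_offset = 0.15, drift_slope = 0.002) {
  vals <- c(amplitude_cv, point_sd, baseline_offset, drift_slope)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_input("noise model parameters must be finite and non-negative")
  structure(list(amplitude_cv = amplitude_cv, point_sd = point_sd,
                 baseline_offset = baseline_offset,
                 drift_slope = drift_slope),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
noise_free <- function() noise_model(0, 0, 0, 0)
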