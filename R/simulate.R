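#' Plate dataset container
#'
#' The unit of I/O for screens and kinetic fits: long-format well time
#' series plus a plate map, optional compound annotations and — for
#' synthetic data only — a per-well ground-truth table of kinetic
#' parameters.
#'
#' @param wells data.frame with columns `well`, `time` (hours),
#'   `value` (fluorescence, a.u.).
#' @param plate_map data.frame with columns `well`, `sample_type`
#'   (`control_vehicle`, `positive_control` or `compound`), `compound`,
#'   `dose_ME`, `seed_fraction`, `monomer_uM`, `replicate`; mixture
#'   designs add `dose_A_ME` and `dose_B_ME`.
#' @param annotations Optional compound annotation data.frame.
#' @param truth Optional per-well ground-truth data.frame.
#' @return An object of class `plate_dataset`.
#' @export
plate_dataset <- function(wells, plate_map, annotations = NULL, truth = NULL) {
  need_w <- c("well", "time", "value")
  need_m <- c("well", "sample_type", "compound", "dose_ME", "seed_fraction",
              "monomer_uM", "replicate")
  if (!all(need_w %in% names(wells)))
    stop_input("wells must have columns well, time, value")
  if (!all(need_m %in% names(plate_map)))
    stop_input(sprintf("plate_map must have columns %s",
                       paste(need_m, collapse = ", ")))
  orphan <- setdiff(unique(wells$well), plate_map$well)
  if (length(orphan) > 0L)
    stop_input(sprintf("wells missing from plate map: %s",
                       paste(utils::head(orphan, 5L), collapse = ", ")))
  structure(list(wells = wells, plate_map = plate_map,
                 annotations = annotations, truth = truth),
            class = "plate_dataset")
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat(sprintf("<plate_dataset: %d wells, %d conditions, %d time points/well>\n",
              nrow(x$plate_map),
              nrow(unique(x$plate_map[, c("compound", "dose_ME",
                                          "seed_fraction")])),
              if (nrow(x$plate_map) > 0)
                sum(x$wells$well == x$plate_map$well[[1L]]) else 0L))
  invisible(x)
}

# Evaluate code with a temporary, restorable RNG state.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Draw the measurement layer for one well given its noiseless mass curve.
measure_well <- function(mass_frac, times, noise, amplitude = 1) {
  A <- amplitude
  if (noise$amplitude_cv > 0) {
    sig <- sqrt(log(1 + noise$amplitude_cv^2))
    A <- amplitude * stats::rlnorm(1L, meanlog = -sig^2 / 2, sdlog = sig)
  }
  y <- noise$baseline_offset + noise$drift_slope * times + A * mass_frac
  if (noise$point_sd > 0)
    y <- y + stats::rnorm(length(times), sd = noise$point_sd * amplitude)
  y
}

#' Simulate one plate-reader well
#'
#' Generates a ThT fluorescence time series for one well: the two-moment
#' model is integrated with the modulator's dose-dependent factors
#' applied to the rate constants, scaled to fluorescence (taken
#' proportional to fibril mass) and passed through the noise model.
#' With `noise_free()` the result is exactly an affine transform of the
#' model mass curve.
#'
#' @param params Baseline `kinetic_params` for the well.
#' @param modulator A `modulator_spec`.
#' @param dose Dose in molar equivalents (ME), >= 0.
#' @param noise A `noise_model`.
#' @param times Time grid, hours.
#' @param amplitude Mean plateau amplitude, a.u.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return An `aggregation_curve` of kind `"fluorescence"`.
#' @export
simulate_well <- function(params, modulator, dose, noise = noise_model(),
                          times = default_time_grid(), amplitude = 1,
                          seed = NULL) {
  f <- modulator_factors(modulator, dose)
  p <- apply_factors(params, f)
  curve <- integrate_moments(p, times)
  with_rng_seed(seed, {
    y <- measure_well(curve$values / params$m_total, times, noise, amplitude)
    aggregation_curve(times, y, kind = "fluorescence",
                      metadata = list(modulator = modulator$name, dose = dose,
                                      factors = f))
  })
}

#' Default plate-reader time grids
#'
#' `default_time_grid()` is the screen grid (0-4 h, 2-min cycle,
#' matching plateau sampling at 4 h for unseeded 2 uM reactions).
#' Unseeded dose series use a longer window so strongly inhibited top
#' doses still plateau; high-seed plates use a fast kinetic cycle
#' because seeded elongation completes within minutes.
#'
#' @param arm One of `"screen"`, `"unseeded-dose"`, `"low-seed"`,
#'   `"high-seed"`, `"mixture"`.
#' @return Numeric time grid in hours.
#' @export
default_time_grid <- function(arm = "screen") {
  switch(arm,
         "screen" = seq(0, 4, by = 2 / 60),
         "unseeded-dose" = seq(0, 10, by = 2 / 60),
         "low-seed" = seq(0, 4, by = 2 / 60),
         "high-seed" = seq(0, 0.3, by = 5 / 3600),
         "mixture" = seq(0, 6, by = 2 / 60),
         stop_input(sprintf("unknown assay arm '%s'", arm)))
}

# Internal: build one simulated condition block (n replicate wells).
# `cache` memoises noiseless mass-fraction curves across identical truths.
sim_condition <- function(state, label, sample_type, modulator, dose,
                          seed_fraction, n, times, design,
                          dose_a = NA_real_, dose_b = NA_real_,
                          factors = NULL) {
  if (is.null(factors)) factors <- modulator_factors(modulator, dose)
  base <- default_params(m_total = design$m_total,
                         seed_mass_fraction = seed_fraction,
                         seed_length = design$seed_length)
  p <- apply_factors(base, factors)
  key <- paste(signif(c(p$k_n, p$k_2, p$k_plus, p$n_c, p$n_2, p$m_total,
                        p$M_0, p$P_0), 15), collapse = "|")
  key <- paste(key, length(times), times[[1L]], times[[length(times)]])
  if (is.null(state$cache[[key]]))
    state$cache[[key]] <- integrate_moments(p, times)$values / p$m_total
  mf <- state$cache[[key]]
  for (r in seq_len(n)) {
    state$i <- state$i + 1L
    wid <- sprintf("W%04d", state$i)
    y <- measure_well(mf, times, design$noise, design$amplitude)
    state$wells[[wid]] <- data.frame(well = wid, time = times, value = y)
    state$map[[wid]] <- data.frame(
      well = wid, sample_type = sample_type, compound = label,
      dose_ME = dose, seed_fraction = seed_fraction,
      monomer_uM = design$m_total, replicate = r,
      dose_A_ME = dose_a, dose_B_ME = dose_b)
    state$truth[[wid]] <- data.frame(
      well = wid, k_n = p$k_n, k_2 = p$k_2, k_plus = p$k_plus,
      n_c = p$n_c, n_2 = p$n_2, m_total = p$m_total, M_0 = p$M_0,
      P_0 = p$P_0, f_n = factors[[1L]], f_2 = factors[[2L]],
      f_plus = factors[[3L]])
  }
  invisible(state)
}

sim_state <- function() {
  e <- new.env(parent = emptyenv())
  e$i <- 0L
  e$wells <- list()
  e$map <- list()
  e$truth <- list()
  e$cache <- list()
  e
}

sim_collect <- function(state, annotations = NULL, drop_ab = TRUE) {
  map <- do.call(rbind, unname(state$map))
  if (drop_ab) map$dose_A_ME <- map$dose_B_ME <- NULL
  rownames(map) <- NULL
  wells <- do.call(rbind, unname(state$wells))
  rownames(wells) <- NULL
  truth <- do.call(rbind, unname(state$truth))
  if (!is.null(truth)) rownames(truth) <- NULL
  plate_dataset(wells, map, annotations = annotations, truth = truth)
}

#' Assay design settings for the synthetic generators
#'
#' @param replicates Technical replicates per condition.
#' @param m_total Monomer concentration, uM.
#' @param noise A `noise_model`.
#' @param amplitude Mean plateau amplitude, a.u.
#' @param seed_length Mean seed length in monomers (`P_0 = M_0 /
#'   seed_length`).
#' @param effect_factors Named list mapping qualitative screen effect
#'   labels to `(f_n, f_2, f_plus)` factor vectors.
#' @param positive_factors Factors of the accelerator positive control.
#' @param dose_ME Screen dose, molar equivalents.
#' @return A list of class `assay_design`.
#' @export
assay_design <- function(replicates = 3, m_total = 2, noise = noise_model(),
                         amplitude = 1, seed_length = 500,
                         effect_factors = list(
                           "inhibition" = c(0.2, 0.2, 1),
                           "acceleration" = c(5, 5, 1),
                           "no effect" = c(1, 1, 1)),
                         positive_factors = c(5, 5, 1),
                         dose_ME = 10) {
  structure(list(replicates = replicates, m_total = m_total, noise = noise,
                 amplitude = amplitude, seed_length = seed_length,
                 effect_factors = effect_factors,
                 positive_factors = positive_factors, dose_ME = dose_ME),
            class = "assay_design")
}

#' Generate a synthetic single-dose modulator screen
#'
#' Emulates a ThT screen of compounds at one dose (default 10 ME)
#' against 2 uM monomer: one condition per annotation row plus vehicle
#' and accelerator positive controls, `replicates` wells each. Truth
#' factors are taken from the design's `effect_factors` according to
#' each compound's qualitative effect label.
#'
#' @param annotations data.frame with columns `metabolite` (or
#'   `compound`) and `effect` in `acceleration` / `inhibition` /
#'   `no effect`.
#' @param design An `assay_design`.
#' @param times Time grid, hours.
#' @param seed RNG seed; identical seeds give bit-identical datasets.
#' @return A `plate_dataset` with truth sidecar.
#' @examples
#' ann <- read_metabolite_annotations()
#' ds <- generate_screen(ann, seed = 1)
#' @export
generate_screen <- function(annotations, design = assay_design(),
                            times = default_time_grid("screen"), seed = 1L) {
  if (!is.data.frame(annotations))
    stop_input("annotations must be a data.frame")
  cmp_col <- intersect(c("metabolite", "compound"), names(annotations))[1]
  if (nrow(annotations) > 0 &&
        (is.na(cmp_col) || !"effect" %in% names(annotations)))
    stop_input("annotations need a metabolite/compound column and an effect column")
  bad <- setdiff(unique(annotations$effect), names(design$effect_factors))
  if (length(bad) > 0L)
    stop_input(sprintf("unknown effect label(s): %s",
                       paste(bad, collapse = ", ")))
  with_rng_seed(seed, {
    st <- sim_state()
    null_mod <- modulator_spec("vehicle", "null")
    sim_condition(st, "DMSO", "control_vehicle", null_mod, 0, 0,
                  design$replicates, times, design)
    sim_condition(st, "positive-control", "positive_control", NULL,
                  design$dose_ME, 0, design$replicates, times, design,
                  factors = design$positive_factors)
    for (i in seq_len(nrow(annotations))) {
      f <- design$effect_factors[[annotations$effect[[i]]]]
      sim_condition(st, as.character(annotations[[cmp_col]][[i]]), "compound",
                    NULL, design$dose_ME, 0, design$replicates, times, design,
                    factors = f)
    }
    sim_collect(st, annotations = annotations)
  })
}

#' Generate a synthetic dose series in three seeding arms
#'
#' Emulates the mechanistic dose-response design: a dose titration of
#' one modulator in unseeded, low-seeded (2% fibril mass) and
#' high-seeded (30% fibril mass) kinetic assays, each arm with its own
#' dose-0 control. The high-seed arm is sampled on a fast kinetic cycle
#' because elongation of preformed seeds completes within minutes.
#'
#' @param modulator A `modulator_spec`.
#' @param doses Doses in ME; 0 is added if absent.
#' @param seed_fractions Seeding arms as fibril mass fractions.
#' @param design An `assay_design`.
#' @param seed RNG seed.
#' @return A `plate_dataset` with truth sidecar.
#' @export
generate_dose_series <- function(modulator, doses = c(0, 1, 3, 5, 7, 10),
                                 seed_fractions = c(0, 0.02, 0.30),
                                 design = assay_design(), seed = 1L) {
  if (any(doses < 0)) stop_input("doses must be non-negative (ME)")
  doses <- sort(unique(c(0, doses)))
  with_rng_seed(seed, {
    st <- sim_state()
    for (sf in seed_fractions) {
      arm <- if (sf == 0) "unseeded-dose"
             else if (sf >= 0.2) "high-seed" else "low-seed"
      times <- default_time_grid(arm)
      for (d in doses) {
        sim_condition(st, modulator$name, if (d == 0) "control_vehicle"
                        else "compound",
                      modulator, d, sf, design$replicates, times, design)
      }
    }
    sim_collect(st)
  })
}

#' Generate a two-modulator mixture dose grid
#'
#' Simulates unseeded wells over the Cartesian grid of doses of two
#' modulators; their rate-constant factors combine multiplicatively.
#' The (0, 0) cell is the vehicle control.
#'
#' @param modulator_a,modulator_b `modulator_spec` objects for the two
#'   axes.
#' @param doses_a,doses_b Dose grids (ME); 0 is added if absent.
#' @param design An `assay_design`.
#' @param times Time grid, hours.
#' @param seed RNG seed.
#' @return A `plate_dataset` whose plate map carries `dose_A_ME` and
#'   `dose_B_ME` columns.
#' @export
generate_mixture <- function(modulator_a, modulator_b,
                             doses_a = c(0, 1, 3, 5, 7),
                             doses_b = c(0, 1, 3, 5, 7),
                             design = assay_design(),
                             times = default_time_grid("mixture"),
                             seed = 1L) {
  doses_a <- sort(unique(c(0, doses_a)))
  doses_b <- sort(unique(c(0, doses_b)))
  with_rng_seed(seed, {
    st <- sim_state()
    for (da in doses_a) for (db in doses_b) {
      fa <- modulator_factors(modulator_a, da)
      fb <- modulator_factors(modulator_b, db)
      label <- sprintf("%s:%g + %s:%g", modulator_a$name, da,
                       modulator_b$name, db)
      stype <- if (da == 0 && db == 0) "control_vehicle" else "compound"
      sim_condition(st, label, stype, NULL, da + db, 0, design$replicates,
                    times, design, dose_a = da, dose_b = db,
                    factors = fa * fb)
    }
    sim_collect(st, drop_ab = FALSE)
  })
}
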