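test_that("modulator factor evaluation honours mode and dose contracts", {
  null_mod <- modulator_spec("v", "null")
  expect_identical(modulator_factors(null_mod, 5), c(1, 1, 1))
  inh <- modulator_simple("i", f_n = 0.2, f_2 = 0.2)
  expect_identical(inh$mode, "inhibitor")
  expect_identical(modulator_factors(inh, 0), c(1, 1, 1))
  expect_equal(modulator_factors(inh, 10), c(0.2, 0.2, 1))
  expect_error(modulator_factors(inh, -1), class = "amylokin_input_error")
  # micellar switch flips from monomeric inhibition to surface catalysis
  toc <- tocopherol_like(switch_threshold = 0.3)
  expect_lt(modulator_factors(toc, 0.2)[[1L]], 1)
  expect_gt(modulator_factors(toc, 0.4)[[1L]], 1)
})

test_that("noiseless wells are exact affine transforms of the model mass", {
  p <- default_params()
  tt <- default_time_grid("screen")
  nm <- noise_model(0, 0, baseline_offset = 0.15, drift_slope = 0)
  w <- simulate_well(p, modulator_spec("v", "null"), 0, nm, tt,
                     amplitude = 2.5)
  M <- integrate_moments(p, tt)$values
  expect_equal(w$values, 0.15 + 2.5 * M / p$m_total, tolerance = 1e-12)
  # composed with exact-window normalization this recovers M / m_total
  nc <- normalize_curve(w, baseline = 0.15, plateau = 0.15 + 2.5)
  expect_lt(max(abs(nc$values - M / p$m_total)), 1e-9)
})

test_that("modulators shift noiseless half-times in the expected direction", {
  p <- default_params()
  tt <- default_time_grid("screen")
  nf <- noise_free()
  ht0 <- halftime(simulate_well(p, modulator_spec("v", "null"), 0, nf, tt))
  inh <- modulator_simple("i", f_n = 0.2, f_2 = 0.2)
  expect_gt(halftime(simulate_well(p, inh, 10, nf, tt)), ht0)
  toc <- tocopherol_like()
  expect_gte(halftime(simulate_well(p, toc, 0.2, nf, tt)), ht0)
  expect_lte(halftime(simulate_well(p, toc, 0.5, nf, tt)), ht0)
})

test_that("screen generation covers controls, compounds and determinism", {
  ann <- read_metabolite_annotations()
  expect_identical(nrow(ann), 18L)
  des <- assay_design(replicates = 2)
  tt <- seq(0, 4, by = 0.05)
  ds <- generate_screen(ann, design = des, times = tt, seed = 3)
  expect_identical(length(unique(ds$plate_map$compound)), 20L)  # 18 + 2 controls
  expect_identical(sum(ds$plate_map$sample_type == "compound"), 36L)
  # replicates of a condition share identical truth parameters
  tr <- merge(ds$plate_map, ds$truth)
  by_cond <- split(tr$k_2, tr$compound)
  expect_true(all(vapply(by_cond, function(x) length(unique(x)) == 1L,
                         logical(1))))
  # empty annotation table: controls only
  ds0 <- generate_screen(ann[0, ], design = des, times = tt, seed = 3)
  expect_true(all(ds0$plate_map$sample_type != "compound"))
  # unknown label rejected
  bad <- data.frame(metabolite = "x", effect = "mystery")
  expect_error(generate_screen(bad, design = des, times = tt),
               class = "amylokin_input_error")
  # determinism: same seed, bit-identical
  ds2 <- generate_screen(ann, design = des, times = tt, seed = 3)
  expect_identical(ds$wells, ds2$wells)
  expect_identical(ds$truth, ds2$truth)
  ds3 <- generate_screen(ann, design = des, times = tt, seed = 4)
  expect_false(identical(ds$wells$value, ds3$wells$value))
})

test_that("dose series carries all seeding arms with sensible kinetics", {
  mod <- retinoid_like()
  des <- assay_design(replicates = 1, noise = noise_free())
  ds <- generate_dose_series(mod, doses = c(0, 5), design = des, seed = 1)
  expect_setequal(unique(ds$plate_map$seed_fraction), c(0, 0.02, 0.30))
  # high-seed dose-0 well starts growing immediately (seeded elongation)
  w <- ds$plate_map$well[ds$plate_map$seed_fraction == 0.30 &
                           ds$plate_map$dose_ME == 0]
  y <- ds$wells[ds$wells$well == w, ]
  expect_gt(y$value[[5L]] - y$value[[1L]], 0)
  # inhibitor: noiseless unseeded half-times strictly increase with dose
  ds2 <- generate_dose_series(mod, doses = c(0, 1, 3, 5, 7, 10),
                              seed_fractions = 0, design = des, seed = 1)
  ht <- screen_halftimes(ds2)
  ht <- ht[order(ht$dose_ME), ]
  expect_true(all(diff(ht$halftime) > 0))
  # doses = 0 only: control wells only
  ds3 <- generate_dose_series(mod, doses = 0, seed_fractions = 0,
                              design = des, seed = 1)
  expect_true(all(ds3$plate_map$sample_type == "control_vehicle"))
})

test_that("inhibitor wells exceed control half-times at default noise", {
  # truth recoverability under the default noise model
  p <- default_params()
  tt <- default_time_grid("screen")
  nm <- noise_model()
  inh <- modulator_simple("i", f_n = 0.2, f_2 = 0.2)
  null_mod <- modulator_spec("v", "null")
  hits <- withr::with_seed(99, {
    vapply(seq_len(200), function(i) {
      h1 <- halftime(simulate_well(p, inh, 10, nm, tt))
      h0 <- halftime(simulate_well(p, null_mod, 0, nm, tt))
      h1 > h0
    }, logical(1))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("datasets round-trip through the CSV directory format", {
  dir <- withr::local_tempdir()
  ann <- read_metabolite_annotations()[1:3, ]
  des <- assay_design(replicates = 2)
  cases <- list(
    screen = generate_screen(ann, design = des,
                             times = seq(0, 4, by = 0.05), seed = 5),
    dose = generate_dose_series(retinoid_like(), doses = c(0, 5),
                                seed_fractions = c(0, 0.02), design = des,
                                seed = 5),
    controls = generate_screen(ann[0, ], design = des,
                               times = seq(0, 4, by = 0.05), seed = 5))
  for (nm in names(cases)) {
    d <- file.path(dir, nm)
    write_dataset(cases[[nm]], d)
    back <- read_dataset(d)
    expect_equal(back$wells$time, cases[[nm]]$wells$time, tolerance = 1e-12)
    expect_equal(back$wells$value, cases[[nm]]$wells$value, tolerance = 1e-12)
    expect_equal(back$plate_map, cases[[nm]]$plate_map)
    expect_equal(back$truth$k_2, cases[[nm]]$truth$k_2, tolerance = 1e-12)
  }
  # writing is deterministic: byte-identical files for identical input
  d1 <- file.path(dir, "rep1"); d2 <- file.path(dir, "rep2")
  write_dataset(cases$screen, d1)
  write_dataset(cases$screen, d2)
  expect_identical(readLines(file.path(d1, "timeseries.csv")),
                   readLines(file.path(d2, "timeseries.csv")))
})

test_that("kinetic parameters round-trip through a flat YAML config", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("k_n: 2.0e-6", "k_2: 5.0e-4", "k_plus: 9000",
               "m_total_uM: 3", "seed_mass_fraction: 0.02",
               "seed_length: 400"), cfg)
  p <- read_params_config(cfg)
  expect_equal(p$k_n, 2e-6)
  expect_equal(p$m_total, 3)
  expect_equal(p$M_0, 0.06)
  expect_equal(p$P_0, 0.06 / 400)
  # defaults fill unspecified keys
  cfg2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("m_total_uM: 5", cfg2)
  p2 <- read_params_config(cfg2)
  expect_equal(p2$k_2, default_params()$k_2)
  expect_equal(p2$M_0, 0)
})
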