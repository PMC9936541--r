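test_that("normalization is a monotone affine map with the right anchors", {
  tt <- seq(0, 4, length.out = 100)
  y <- 1 / (1 + exp(-(tt - 2) / 0.15))
  # already effectively normalized: returned unchanged up to the
  # logistic's residual tails inside the anchor windows
  nc <- normalize_curve(y, times = tt)
  expect_equal(nc$values, y, tolerance = 1e-4)
  # with exact anchors the identity is recovered to machine precision
  nc_exact <- normalize_curve(y, times = tt, baseline = 0, plateau = 1)
  expect_equal(nc_exact$values, y, tolerance = 1e-12)
  # affine midpoint: raw 350 between baseline 100 and plateau 600 -> 0.5
  raw <- 100 + 500 * y
  nc2 <- normalize_curve(raw, times = tt, baseline = 100, plateau = 600)
  i <- which.min(abs(raw - 350))
  expect_equal(nc2$values[[i]], (raw[[i]] - 100) / 500)
  expect_error(normalize_curve(rep(5, 100), times = tt),
               class = "amylokin_degenerate_curve")
  expect_error(normalize_curve(y[1:10], times = tt[1:10]),
               class = "amylokin_input_error")
})

test_that("half-time statistic is invariant to affine transforms of the raw signal", {
  des <- assay_design(replicates = 2)
  ann <- data.frame(metabolite = "x", effect = "inhibition")
  ds <- generate_screen(ann, design = des, times = seq(0, 4, by = 0.05),
                        seed = 2)
  ht1 <- screen_halftimes(ds)
  ds2 <- ds
  ds2$wells$value <- 3.7 * ds2$wells$value + 42
  ht2 <- screen_halftimes(ds2)
  expect_equal(ht1$halftime, ht2$halftime, tolerance = 1e-9)
})

test_that("excluded wells are reported with reasons, never dropped silently", {
  des <- assay_design(replicates = 2)
  ds <- generate_screen(data.frame(metabolite = "x", effect = "no effect"),
                        design = des, times = seq(0, 4, by = 0.05), seed = 2)
  # sabotage one well into a flat trace
  w1 <- ds$plate_map$well[[1L]]
  ds$wells$value[ds$wells$well == w1] <- 0.15
  ht <- screen_halftimes(ds)
  expect_identical(nrow(ht), nrow(ds$plate_map))
  expect_true(ht$excluded[ht$well == w1])
  expect_match(ht$reason[ht$well == w1], "degenerate|flat")
  expect_false(any(ht$excluded[ht$well != w1]))
})

test_that("overwhelming effects are called with the right sign", {
  # +10 SD shift must be called inhibitor, -symmetric an accelerator
  base <- data.frame(
    well = sprintf("W%02d", 1:9),
    sample_type = rep(c("control_vehicle", "compound", "compound"), each = 3),
    compound = rep(c("DMSO", "slow", "fast"), each = 3),
    dose_ME = rep(c(0, 10, 10), each = 3), seed_fraction = 0,
    monomer_uM = 2, replicate = rep(1:3, 3),
    halftime = c(1.00, 1.01, 0.99, 3.00, 3.02, 2.98, 0.30, 0.31, 0.29),
    excluded = FALSE, reason = "")
  res <- call_hits(base, control = "DMSO", alpha = 0.05)
  expect_identical(res$call[res$compound == "slow"], "inhibitor")
  expect_identical(res$call[res$compound == "fast"], "accelerator")
  expect_true(all(res$p_adj < 0.01))
  expect_error(call_hits(base, control = "water"),
               class = "amylokin_input_error")
  # single-replicate condition excluded with reason, others unaffected
  base2 <- rbind(base, data.frame(
    well = "W10", sample_type = "compound", compound = "lonely", dose_ME = 10,
    seed_fraction = 0, monomer_uM = 2, replicate = 1, halftime = 2,
    excluded = FALSE, reason = ""))
  res2 <- call_hits(base2, control = "DMSO")
  expect_true(res2$excluded[res2$compound == "lonely"])
  expect_identical(res2$call[res2$compound == "slow"], "inhibitor")
})

test_that("stronger inhibition never flips a call toward accelerator", {
  ann <- data.frame(metabolite = "x", effect = "inhibition")
  tt <- seq(0, 4, by = 0.05)
  calls <- sapply(c(0.5, 0.3, 0.15), function(f) {
    des <- assay_design(effect_factors = list("inhibition" = c(f, f, 1),
                                              "acceleration" = c(5, 5, 1),
                                              "no effect" = c(1, 1, 1)))
    ds <- generate_screen(ann, design = des, times = tt, seed = 8)
    res <- analyze_screen(ds)
    res$call[res$compound == "x"]
  })
  expect_false(any(calls == "accelerator"))
  # and the strongest effect is a confident inhibitor call
  expect_identical(calls[[3L]], "inhibitor")
})

test_that("the packaged metabolite screen reproduces the expected hit pattern", {
  ann <- read_metabolite_annotations()
  ds <- generate_screen(ann, seed = 20240915)
  res <- analyze_screen(ds, control = "DMSO", alpha = 0.05)
  cmp <- res[res$sample_type == "compound", ]
  expect_identical(sum(cmp$call == "inhibitor"), 3L)
  expect_identical(sum(cmp$call == "accelerator"), 4L)
  # the inhibitors are the vitamin K and A metabolites
  expect_setequal(cmp$compound[cmp$call == "inhibitor"],
                  c("menaquinone", "menadione", "retinoic acid"))
  expect_setequal(cmp$compound[cmp$call == "accelerator"],
                  c("cobalamin", "cholecalciferol", "ergocalciferol",
                    "alpha-tocopherol"))
})

test_that("balanced Dunnett quadrature matches the multivariate-t reference", {
  # independent route: mvtnorm's randomized integration at high budget
  k <- 6
  df <- 20
  ts <- c(0.4, 1.5, 2.2, 2.9, 3.5, 1.0)
  corr <- matrix(0.5, k, k)
  diag(corr) <- 1
  ref <- withr::with_seed(7, vapply(ts, function(t0)
    1 - mvtnorm::pmvt(lower = rep(-abs(t0), k), upper = rep(abs(t0), k),
                      df = df, corr = corr,
                      algorithm = mvtnorm::GenzBretz(maxpts = 50000,
                                                     abseps = 1e-5))[1],
    numeric(1)))
  expect_equal(dunnett_p_balanced(ts, df), ref, tolerance = 5e-4)
  # and the two routes agree end-to-end: calls from an unbalanced copy
  # of a balanced table (forcing the multcomp path) match
  ht <- data.frame(
    well = sprintf("W%02d", 1:12), sample_type = "compound",
    compound = rep(c("DMSO", "a", "b", "c"), each = 3), dose_ME = 10,
    seed_fraction = 0, monomer_uM = 2, replicate = rep(1:3, 4),
    halftime = c(1.0, 1.02, 0.98, 1.6, 1.55, 1.62, 1.01, 0.97, 1.03,
                 0.55, 0.5, 0.52),
    excluded = FALSE, reason = "")
  bal <- call_hits(ht, control = "DMSO")
  unbal <- call_hits(rbind(ht, data.frame(
    well = "W13", sample_type = "compound", compound = "a", dose_ME = 10,
    seed_fraction = 0, monomer_uM = 2, replicate = 4, halftime = 1.58,
    excluded = FALSE, reason = "")), control = "DMSO")
  expect_identical(bal$call[bal$compound %in% c("b")], "no-effect")
  expect_identical(unbal$call[unbal$compound == "a"], "inhibitor")
  expect_identical(bal$call[bal$compound == "a"], "inhibitor")
  expect_identical(bal$call[bal$compound == "c"], "accelerator")
})
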