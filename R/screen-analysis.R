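#' Normalize a raw ThT curve to [0, 1]
#'
#' Monotone affine rescaling of a raw fluorescence series: the mean of
#' the first `k` points (baseline) maps to 0 and the mean of the last
#' `k` points (plateau) maps to 1. Explicit `baseline` / `plateau`
#' values may be supplied instead, e.g. when they are known exactly.
#'
#' @param curve An `aggregation_curve` or numeric vector.
#' @param times Time grid when `curve` is a plain vector.
#' @param k Window size for the baseline and plateau estimates.
#' @param baseline,plateau Optional explicit values overriding the
#'   window estimates.
#' @return An `aggregation_curve` with values on the normalized scale.
#' @export
normalize_curve <- function(curve, times = NULL, k = 5, baseline = NULL,
                            plateau = NULL) {
  if (inherits(curve, "aggregation_curve")) {
    y <- curve$values
    t <- curve$times
    meta <- curve$metadata
  } else {
    y <- as.numeric(curve)
    t <- times
    meta <- list()
    if (is.null(t)) stop_input("supply 'times' with a plain numeric curve")
  }
  n <- length(y)
  if (n < 20L) stop_input("normalization needs at least 20 time points")
  b <- if (is.null(baseline)) mean(y[seq_len(k)]) else baseline
  p <- if (is.null(plateau)) mean(y[seq.int(n - k + 1L, n)]) else plateau
  if (!is.finite(p - b) || p <= b)
    abort("plateau does not exceed baseline: degenerate curve",
          "amylokin_degenerate_curve")
  aggregation_curve(t, (y - b) / (p - b), kind = "fluorescence",
                    metadata = meta)
}

#' Per-well half-times for a plate dataset
#'
#' Applies [normalize_curve()] then [halftime()] to every well. Wells
#' whose curves are degenerate or have not plateaued are reported as
#' excluded with the reason — never silently dropped.
#'
#' @param ds A `plate_dataset`.
#' @param k Baseline/plateau window size.
#' @return A data.frame: the plate map plus columns `halftime` (hours,
#'   `NA` when excluded), `excluded` (logical) and `reason`.
#' @export
screen_halftimes <- function(ds, k = 5) {
  stopifnot(inherits(ds, "plate_dataset"))
  map <- ds$plate_map
  split_wells <- split(ds$wells, ds$wells$well)
  res <- map
  res$halftime <- NA_real_
  res$excluded <- FALSE
  res$reason <- ""
  for (i in seq_len(nrow(map))) {
    w <- split_wells[[map$well[[i]]]]
    ht <- tryCatch({
      nc <- normalize_curve(w$value, times = w$time, k = k)
      halftime(nc, k = k)
    }, amylokin_error = function(e) e)
    if (inherits(ht, "condition")) {
      res$excluded[[i]] <- TRUE
      res$reason[[i]] <- conditionMessage(ht)
    } else {
      res$halftime[[i]] <- ht
    }
  }
  res
}

#' Call screen hits with one-way ANOVA and Dunnett comparisons
#'
#' Compares each condition's per-well half-times to the vehicle control
#' with Dunnett's many-to-one multiple-comparison procedure on a
#' one-way ANOVA, and classifies each compound as `inhibitor` (half-time
#' significantly above control), `accelerator` (below) or `no-effect`.
#'
#' @param ht_table Output of [screen_halftimes()].
#' @param control Compound label of the vehicle control.
#' @param alpha Significance level on the Dunnett-adjusted p-values.
#' @param maxpts,abseps Quadrature budget and absolute error tolerance
#'   of the multivariate-t integration behind the adjusted p-values;
#'   the defaults resolve p-values to ~0.002, ample for screening
#'   decisions at conventional alpha levels.
#' @return A data.frame of class `screen_result`, one row per
#'   non-control condition: `compound`, `sample_type`, `n`,
#'   `mean_halftime`, `sem`, `delta` (vs control mean), `p_adj`, `call`,
#'   plus `excluded`/`reason` for conditions dropped from the test. The
#'   control summary is attached as attribute `"control"`.
#' @export
call_hits <- function(ht_table, control = "DMSO", alpha = 0.05,
                      maxpts = 2500, abseps = 0.002) {
  tab <- ht_table[!ht_table$excluded & is.finite(ht_table$halftime), ,
                  drop = FALSE]
  if (!control %in% tab$compound)
    stop_input(sprintf("control condition '%s' missing or fully excluded",
                       control))
  cnt <- table(tab$compound)
  singles <- names(cnt)[cnt < 2L]
  singles <- setdiff(singles, control)
  kept <- tab[!tab$compound %in% singles, , drop = FALSE]
  if (cnt[[control]] < 2L)
    stop_input("control needs at least 2 replicate half-times")
  # control first so Dunnett compares everything against it
  lev <- c(control, setdiff(unique(kept$compound), control))
  kept$condition <- factor(kept$compound, levels = lev)
  ctrl_ht <- kept$halftime[kept$compound == control]
  summ <- function(x) c(n = length(x), mean = mean(x),
                        sem = stats::sd(x) / sqrt(length(x)))
  out <- do.call(rbind, lapply(setdiff(lev, control), function(cc) {
    x <- kept$halftime[kept$compound == cc]
    s <- summ(x)
    data.frame(compound = cc,
               sample_type = kept$sample_type[kept$compound == cc][[1L]],
               n = s[["n"]], mean_halftime = s[["mean"]], sem = s[["sem"]],
               delta = s[["mean"]] - mean(ctrl_ht),
               p_adj = NA_real_, call = "no-effect",
               excluded = FALSE, reason = "")
  }))
  if (length(lev) > 1L) {
    fit <- stats::aov(halftime ~ condition, data = kept)
    cnt_kept <- table(kept$condition)
    if (length(unique(as.integer(cnt_kept))) == 1L) {
      # balanced design: the Dunnett correlation is exactly
      # equicorrelated (rho = 1/2) and the two-sided family
      # probability has a deterministic 2-D quadrature form
      mns <- tapply(kept$halftime, kept$condition, mean)
      est <- as.numeric(mns[-1L] - mns[[1L]])
      n_per <- as.integer(cnt_kept[[1L]])
      sig2 <- sum(stats::resid(fit)^2) / stats::df.residual(fit)
      tstat <- est / sqrt(sig2 * 2 / n_per)
      pad <- dunnett_p_balanced(tstat, df = stats::df.residual(fit))
    } else {
      glt <- multcomp::glht(fit,
                            linfct = multcomp::mcp(condition = "Dunnett"))
      # the multivariate-t quadrature behind the adjusted p-values is
      # randomized; pin its RNG stream for reproducibility, and drop
      # its accuracy warnings (harmless at screening alpha levels)
      alg <- mvtnorm::GenzBretz(maxpts = maxpts, abseps = abseps)
      sm <- with_rng_seed(1L, suppressWarnings(summary(
        glt, test = multcomp::adjusted("single-step", algorithm = alg))))
      est <- as.numeric(sm$test$coefficients)
      pad <- as.numeric(sm$test$pvalues)
    }
    # Dunnett comparisons are in factor-level order = row order of `out`
    for (j in seq_along(pad)) {
      out$p_adj[[j]] <- pad[[j]]
      if (pad[[j]] <= alpha && est[[j]] != 0)
        out$call[[j]] <- if (est[[j]] > 0) "inhibitor" else "accelerator"
    }
  }
  if (length(singles) > 0L) {
    out <- rbind(out, data.frame(
      compound = singles, sample_type = NA_character_, n = 1L,
      mean_halftime = NA_real_, sem = NA_real_, delta = NA_real_,
      p_adj = NA_real_, call = "no-effect", excluded = TRUE,
      reason = "fewer than 2 replicate half-times"))
  }
  rownames(out) <- NULL
  attr(out, "control") <- data.frame(compound = control,
                                     n = length(ctrl_ht),
                                     mean_halftime = mean(ctrl_ht),
                                     sem = stats::sd(ctrl_ht) /
                                       sqrt(length(ctrl_ht)))
  attr(out, "alpha") <- alpha
  class(out) <- c("screen_result", class(out))
  out
}

#' Run the full screen analysis on a plate dataset
#'
#' Convenience wrapper: [screen_halftimes()] followed by [call_hits()].
#'
#' @inheritParams screen_halftimes
#' @inheritParams call_hits
#' @return A `screen_result` (see [call_hits()]); the per-well half-time
#'   table is attached as attribute `"halftimes"`.
#' @export
analyze_screen <- function(ds, control = "DMSO", alpha = 0.05, k = 5) {
  ht <- screen_halftimes(ds, k = k)
  res <- call_hits(ht, control = control, alpha = alpha)
  attr(res, "halftimes") <- ht
  res
}


#' Two-sided Dunnett adjusted p-values for a balanced one-way design
#'
#' With equal replication in every group (control included) the
#' many-to-one t statistics are equicorrelated with rho = 1/2, and the
#' family-wise probability P(max_j |T_j| <= q) reduces to a double
#' integral over the shared control variate and the pooled-variance
#' chi scale. Both integrals are evaluated by fixed Gauss quadrature,
#' so the result is deterministic to ~1e-6 — the classical computation
#' behind Dunnett's tables.
#'
#' @param tstat Observed many-to-one t statistics (one per treatment).
#' @param df Residual degrees of freedom of the pooled variance.
#' @param n_nodes Gauss node counts `c(hermite, legendre)`.
#' @return Adjusted two-sided p-values, same length as `tstat`.
#' @export
dunnett_p_balanced <- function(tstat, df, n_nodes = c(48, 48)) {
  k <- length(tstat)
  q <- abs(tstat)
  gh <- pracma::gaussHermite(n_nodes[[1L]])
  # chi scale s = sqrt(chi^2_df / df): integrate its density on a
  # bracket covering all but ~1e-12 of its mass
  s_lo <- sqrt(stats::qchisq(1e-12, df) / df)
  s_hi <- sqrt(stats::qchisq(1 - 1e-12, df) / df)
  gl <- pracma::gaussLegendre(n_nodes[[2L]], s_lo, s_hi)
  lg <- (df / 2) * log(df / 2) - lgamma(df / 2)
  dens_s <- exp(lg + log(2) + (df - 1) * log(gl$x) - df * gl$x^2 / 2)
  w <- sqrt(2) * gh$x             # standard-normal nodes
  ww <- gh$w / sqrt(pi)           # weights for E_W[.]
  vapply(q, function(qi) {
    # inner normal integral for each chi node: E_W prod_j P(|T_j|<=qi s)
    inner <- vapply(gl$x, function(s) {
      a <- sqrt(2) * qi * s
      sum(ww * (stats::pnorm(w + a) - stats::pnorm(w - a))^k)
    }, numeric(1))
    p <- 1 - sum(gl$w * dens_s * inner)
    min(max(p, 0), 1)
  }, numeric(1))
}
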