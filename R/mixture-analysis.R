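#' Half-time grid over a two-modulator dose mixture
#'
#' Summarizes a mixture dataset (plate map with `dose_A_ME` and
#' `dose_B_ME` columns) into a matrix of replicate-mean half-times per
#' dose cell, the heat-map representation of a two-compound
#' cancellation experiment. Cells with no usable wells are reported as
#' missing, never imputed.
#'
#' @param ds A `plate_dataset` whose plate map carries `dose_A_ME` and
#'   `dose_B_ME`.
#' @param k Normalization window size.
#' @return An object of class `mixture_grid`: dose axes `doses_a`,
#'   `doses_b`; matrices `mean`, `sem`, `n` (rows = A doses, columns =
#'   B doses); `control_halftime`; and `missing`, a data.frame of empty
#'   cells.
#' @export
mixture_halftime_grid <- function(ds, k = 5) {
  stopifnot(inherits(ds, "plate_dataset"))
  map <- ds$plate_map
  if (!all(c("dose_A_ME", "dose_B_ME") %in% names(map)))
    stop_input("plate map needs dose_A_ME and dose_B_ME columns")
  ht <- screen_halftimes(ds, k = k)
  ok <- ht[!ht$excluded & is.finite(ht$halftime), , drop = FALSE]
  doses_a <- sort(unique(map$dose_A_ME))
  doses_b <- sort(unique(map$dose_B_ME))
  if (nrow(ok[ok$dose_A_ME == 0 & ok$dose_B_ME == 0, ]) == 0L)
    stop_input("control cell (0, 0) absent or fully excluded")
  dims <- c(length(doses_a), length(doses_b))
  mn <- sem <- matrix(NA_real_, dims[[1L]], dims[[2L]],
                      dimnames = list(doses_a, doses_b))
  nn <- matrix(0L, dims[[1L]], dims[[2L]], dimnames = list(doses_a, doses_b))
  missing <- list()
  for (i in seq_along(doses_a)) for (j in seq_along(doses_b)) {
    x <- ok$halftime[ok$dose_A_ME == doses_a[[i]] &
                       ok$dose_B_ME == doses_b[[j]]]
    if (length(x) == 0L) {
      missing[[length(missing) + 1L]] <-
        data.frame(dose_A = doses_a[[i]], dose_B = doses_b[[j]])
      next
    }
    mn[i, j] <- mean(x)
    sem[i, j] <- if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
    nn[i, j] <- length(x)
  }
  structure(list(doses_a = doses_a, doses_b = doses_b, mean = mn, sem = sem,
                 n = nn, control_halftime = mn[match(0, doses_a),
                                              match(0, doses_b)],
                 missing = if (length(missing) > 0L)
                   do.call(rbind, missing)
                 else data.frame(dose_A = numeric(0), dose_B = numeric(0))),
            class = "mixture_grid")
}

#' @export
print.mixture_grid <- function(x, ...) {
  cat(sprintf("<mixture_grid: %d x %d cells, control t1/2 = %.3g h>\n",
              length(x$doses_a), length(x$doses_b), x$control_halftime))
  print(round(x$mean, 3))
  invisible(x)
}

#' Near-zero net-effect region of a mixture grid
#'
#' Identifies the dose cells whose half-time is within a relative
#' tolerance of the control half-time — the region where an inhibitor
#' and an accelerator cancel to a near-zero net effect on aggregation.
#' The comparison is purely phenomenological (half-times only); no
#' mechanistic model of the cancellation is assumed. The boundary is
#' inclusive.
#'
#' @param grid A `mixture_grid`.
#' @param tolerance Relative half-time deviation defining "near zero".
#' @return A list: `cells`, a data.frame of in-region cells
#'   (`dose_A`, `dose_B`, `halftime`, `ratio`); and `mask`, a logical
#'   matrix aligned to `grid$mean` (missing cells are `FALSE`).
#' @export
zero_net_region <- function(grid, tolerance = 0.10) {
  stopifnot(inherits(grid, "mixture_grid"))
  if (!is.numeric(tolerance) || tolerance < 0)
    stop_input("tolerance must be non-negative")
  ratio <- grid$mean / grid$control_halftime
  mask <- abs(ratio - 1) <= tolerance
  mask[is.na(mask)] <- FALSE
  idx <- which(mask, arr.ind = TRUE)
  cells <- data.frame(
    dose_A = grid$doses_a[idx[, 1L]],
    dose_B = grid$doses_b[idx[, 2L]],
    halftime = grid$mean[mask],
    ratio = ratio[mask])
  cells <- cells[order(cells$dose_A, cells$dose_B), , drop = FALSE]
  rownames(cells) <- NULL
  list(cells = cells, mask = mask)
}
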