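# Turbidostat growth rates, pigment equations, qPCR and ROS fold-changes,
# and the shared Welch-t + BH testing utility.

#' Turbidostat growth segments and rates
#'
#' Detects dilution events in an OD680 trace (a relative drop exceeding
#' half the turbidostat band within one sampling step) and fits each
#' inter-dilution segment by least squares on `log2(OD680)`. The slope is
#' the relative growth rate (1/h) and its inverse the doubling time.
#'
#' @param trace an `od680` [kinetic_trace] with `x` in hours.
#' @param band turbidostat half-width as a fraction of the target density
#'   (the culture cycles between `(1 - band)` and `(1 + band)` times the
#'   target).
#' @param min_points minimum points per fitted segment.
#' @return data.frame of segments: `start_h`, `end_h`, `n`, `slope`
#'   (log2 OD per h), `doubling_h` (`NA` when slope <= 0), `r2`.
#' @export
detect_cycles <- function(trace, band = 0.08, min_points = 3L) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (any(trace$y <= 0)) stop("OD trace must be positive")
  t <- trace$x; od <- trace$y
  rel_drop <- -diff(od) / od[-length(od)]
  cuts <- which(rel_drop > band / 2)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, length(od))
  segs <- list()
  for (i in seq_along(starts)) {
    idx <- starts[i]:ends[i]
    if (length(idx) < min_points) next
    fit <- stats::lm(log2(od[idx]) ~ t[idx])
    slope <- unname(stats::coef(fit)[2L])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    segs[[length(segs) + 1L]] <- data.frame(
      start_h = t[idx[1L]], end_h = t[idx[length(idx)]], n = length(idx),
      slope = slope,
      doubling_h = if (slope > 0) 1 / slope else NA_real_, r2 = r2)
  }
  if (length(segs) == 0L) {
    warning("no complete growth segment in trace")
    return(data.frame(start_h = numeric(0), end_h = numeric(0),
                      n = integer(0), slope = numeric(0),
                      doubling_h = numeric(0), r2 = numeric(0)))
  }
  do.call(rbind, segs)
}

#' Pigment concentrations from absorbance readings
#'
#' Evaluates the standard methanol-extract equations:
#' `chl_total = 22.12 A652 + 2.71 A665`,
#' `chl_a = 16.29 A665 - 8.54 A652`,
#' `chl_b = 30.66 A652 - 13.58 A665`, and
#' `carotenoids = (1000 A470 - 2.86 chl_a - 129.2 chl_b) / 221`
#' (all ug/mL). The coefficients are exactly additive:
#' `chl_a + chl_b == chl_total`. Negative concentrations are returned
#' unclipped with `out_of_range = TRUE`.
#'
#' @param a470,a652,a665 absorbance readings (>= 0).
#' @param cells_per_ml optional cell density; adds per-cell values in
#'   pg/cell.
#' @return data.frame with `chl_a`, `chl_b`, `chl_total`, `carotenoids`
#'   (ug/mL), ratios `chl_ab_ratio`, `chl_car_ratio`, `out_of_range`, and
#'   (given `cells_per_ml`) `chl_pg_cell`, `car_pg_cell`.
#' @export
pigments <- function(a470, a652, a665, cells_per_ml = NULL) {
  if (any(c(a470, a652, a665) < 0)) stop("absorbances must be >= 0")
  chl_a <- 16.29 * a665 - 8.54 * a652
  chl_b <- 30.66 * a652 - 13.58 * a665
  chl_total <- 22.12 * a652 + 2.71 * a665
  car <- (1000 * a470 - 2.86 * chl_a - 129.2 * chl_b) / 221
  out <- data.frame(
    chl_a = chl_a, chl_b = chl_b, chl_total = chl_total, carotenoids = car,
    chl_ab_ratio = ifelse(chl_b != 0, chl_a / chl_b, NA_real_),
    chl_car_ratio = ifelse(car != 0, chl_total / car, NA_real_),
    out_of_range = chl_a < 0 | chl_b < 0 | car < 0)
  if (!is.null(cells_per_ml)) {
    # ug/mL -> pg/cell: 1 ug = 1e6 pg
    out$chl_pg_cell <- chl_total * 1e6 / cells_per_ml
    out$car_pg_cell <- car * 1e6 / cells_per_ml
  }
  out
}

#' Relative qPCR expression by the 2^-ddCT method
#'
#' `fold = 2^-((ct_target - ct_ref) - calibrator_dct)` where
#' `calibrator_dct` is the target-minus-reference CT difference of the
#' calibrator sample (its own pre-heat expression).
#'
#' @param ct_target,ct_ref CT values of the gene of interest and the
#'   internal control in the sample of interest.
#' @param calibrator_dct delta-CT of the calibrator sample.
#' @return Fold-change relative to the calibrator.
#' @export
ddct_fold <- function(ct_target, ct_ref, calibrator_dct) {
  stopifnot(all(is.finite(c(ct_target, ct_ref, calibrator_dct))))
  2^-((ct_target - ct_ref) - calibrator_dct)
}

#' Background-corrected ROS (or assay) fold-change
#'
#' Subtracts the ascorbate-quenched background signal, normalizes per cell
#' and per summed cell volume, and reports fold-changes versus a baseline
#' (pre-heat) corrected signal processed the same way.
#'
#' @param signal,ascorbate_signal raw and ascorbate-background
#'   fluorescence of the sample.
#' @param cells_per_ml cell density of the sample.
#' @param cell_volume mean cell volume of the sample (arbitrary units).
#' @param baseline list with the same fields (`signal`,
#'   `ascorbate_signal`, `cells_per_ml`, `cell_volume`) for the baseline
#'   sample.
#' @return data.frame: `corrected`, `per_cell`, `per_volume`,
#'   `fold_per_cell`, `fold_per_volume`, `negative_corrected` flag.
#' @export
ros_fold <- function(signal, ascorbate_signal, cells_per_ml, cell_volume,
                     baseline) {
  corr <- signal - ascorbate_signal
  base_corr <- baseline$signal - baseline$ascorbate_signal
  if (base_corr <= 0) stop("baseline corrected signal must be positive")
  per_cell <- corr / cells_per_ml
  per_vol <- corr / (cells_per_ml * cell_volume)
  base_cell <- base_corr / baseline$cells_per_ml
  base_vol <- base_corr / (baseline$cells_per_ml * baseline$cell_volume)
  data.frame(corrected = corr, per_cell = per_cell, per_volume = per_vol,
             fold_per_cell = per_cell / base_cell,
             fold_per_volume = per_vol / base_vol,
             negative_corrected = corr < 0)
}

#' Welch t-tests with Benjamini-Hochberg correction
#'
#' Two-tailed t-test assuming unequal variance per measurement, with BH
#' adjustment across the whole comparison family. Identical zero-variance
#' groups give p = 1.
#'
#' @param groups_a,groups_b lists of numeric vectors (>= 2 observations
#'   each), one pair per measurement.
#' @param alpha significance cutoff applied to adjusted p values.
#' @return data.frame: `measurement`, `mean_a`, `mean_b`, `p`, `fdr`,
#'   `significant`.
#' @export
welch_bh <- function(groups_a, groups_b, alpha = 0.05) {
  stopifnot(length(groups_a) == length(groups_b))
  nm <- names(groups_a)
  if (is.null(nm)) nm <- as.character(seq_along(groups_a))
  p <- mapply(function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
      stop("each group needs >= 2 observations")
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }, groups_a, groups_b)
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(measurement = nm,
             mean_a = vapply(groups_a, mean, numeric(1)),
             mean_b = vapply(groups_b, mean, numeric(1)),
             p = p, fdr = fdr, significant = fdr < alpha)
}
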