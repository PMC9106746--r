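# FACS DNA-content histogram analysis: peak finding, cell-size-dependent
# background correction, and power-of-two ploidy assignment.

#' Find peaks in a DNA-content histogram
#'
#' Smooths the histogram with a centered moving average and returns local
#' maxima ranked by prominence (height above the higher of the two
#' flanking minima).
#'
#' @param hist_trace a `facs_hist` [kinetic_trace]: `x` = fluorescence bin
#'   centers (raw signal), `y` = cell counts. Bins are typically
#'   log-spaced.
#' @param min_prominence minimum prominence as a fraction of the maximum
#'   smoothed count.
#' @param smooth_window moving-average window in bins.
#' @return data.frame of peaks sorted by position: `position`, `height`,
#'   `prominence`.
#' @export
find_peaks <- function(hist_trace, min_prominence = 0.05,
                       smooth_window = 5L) {
  stopifnot(inherits(hist_trace, "kinetic_trace"))
  y <- as.numeric(stats::filter(hist_trace$y,
                                rep(1 / smooth_window, smooth_window),
                                sides = 2L))
  y[is.na(y)] <- hist_trace$y[is.na(y)]
  n <- length(y)
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) == 0L) stop("no peaks found in histogram")
  # prominence: drop to the valley floor between the peak and the nearest
  # higher ground on each side (edge counts as higher ground at -Inf)
  prom <- vapply(is_max, function(i) {
    higher_l <- which(y[seq_len(i - 1L)] > y[i])
    lo <- if (length(higher_l)) max(higher_l) + 1L else 1L
    left <- min(y[lo:i])
    higher_r <- which(y[(i + 1L):n] > y[i]) + i
    hi <- if (length(higher_r)) min(higher_r) - 1L else n
    right <- min(y[i:hi])
    y[i] - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence * max(y)
  if (!any(keep)) stop("no peaks exceed the prominence threshold")
  out <- data.frame(position = hist_trace$x[is_max[keep]],
                    height = y[is_max[keep]], prominence = prom[keep])
  out[order(out$position), ]
}

#' Subtract cell-size-dependent staining background from peak positions
#'
#' @param raw_peaks raw peak fluorescence positions.
#' @param background background staining level (same units).
#' @return Corrected positions (`raw - background`); an error if the
#'   background exceeds any peak.
#' @export
correct_background <- function(raw_peaks, background) {
  if (background < 0) stop("background must be >= 0")
  corrected <- raw_peaks - background
  if (any(corrected < 0))
    stop("background exceeds peak position(s)")
  corrected
}

#' Assign ploidy labels to corrected peak positions
#'
#' The smallest corrected peak is 1C; every further peak is labeled
#' `2^k C` by the nearest power-of-two ratio to the 1C position, accepted
#' when the ratio to the expected doubling series lies within
#' `[1.7, 2.3] / 2` of it (i.e. observed/expected in \[0.85, 1.15\]);
#' otherwise the peak stays unlabeled.
#'
#' @param corrected corrected peak positions (>= 1 peak).
#' @param max_c largest ploidy class considered.
#' @return data.frame: `position`, `ratio_to_1c`, `label` (e.g. `"2C"`,
#'   `NA` when no doubling class fits), `flagged`.
#' @export
assign_ploidy <- function(corrected, max_c = 16L) {
  if (length(corrected) < 1L) stop("need at least one corrected peak")
  corrected <- sort(corrected)
  base <- corrected[1L]
  classes <- 2^(0:log2(max_c))
  ratio <- corrected / base
  label <- character(length(corrected))
  for (i in seq_along(corrected)) {
    k <- classes[which.min(abs(log(ratio[i] / classes)))]
    # accepted when within the [1.7, 2.3]-per-doubling window, i.e.
    # observed/expected in [0.85, 1.15]
    label[i] <- if (ratio[i] / k >= 0.85 && ratio[i] / k <= 1.15)
      sprintf("%dC", as.integer(k)) else NA_character_
  }
  data.frame(position = corrected, ratio_to_1c = ratio, label = label,
             flagged = is.na(label))
}

#' Cell-size-proportional background estimate
#'
#' Background staining scales with cell volume: `background = kappa *
#' mean_cell_volume`, with `kappa` calibrated on a reference sample
#' (pre-heat) where the background is known.
#'
#' @param mean_cell_volume mean cell volume of the sample.
#' @param kappa background per unit volume (> 0), e.g.
#'   `known_background / reference_volume`.
#' @return Estimated background signal.
#' @export
estimate_background <- function(mean_cell_volume, kappa) {
  if (kappa <= 0) stop("kappa must be positive")
  if (any(mean_cell_volume < 0)) stop("cell volume must be >= 0")
  kappa * mean_cell_volume
}

#' Ploidy population fractions from a histogram and its peaks
#'
#' Splits the histogram at the minima between labeled peaks and sums
#' counts per ploidy class.
#'
#' @param hist_trace a `facs_hist` [kinetic_trace].
#' @param peaks output of [find_peaks()].
#' @param calls output of [assign_ploidy()] on the background-corrected
#'   peak positions (row order matching `peaks`).
#' @return data.frame: `label`, `fraction` (sums to 1 over labeled
#'   classes).
#' @export
ploidy_fractions <- function(hist_trace, peaks, calls) {
  stopifnot(nrow(peaks) == nrow(calls))
  pos <- peaks$position
  bounds <- c(-Inf, vapply(seq_len(length(pos) - 1L), function(i) {
    sel <- hist_trace$x > pos[i] & hist_trace$x < pos[i + 1L]
    if (!any(sel)) return((pos[i] + pos[i + 1L]) / 2)
    hist_trace$x[sel][which.min(hist_trace$y[sel])]
  }, numeric(1)), Inf)
  counts <- vapply(seq_along(pos), function(i)
    sum(hist_trace$y[hist_trace$x >= bounds[i] &
                       hist_trace$x < bounds[i + 1L]]), numeric(1))
  ok <- !calls$flagged
  data.frame(label = calls$label[ok],
             fraction = counts[ok] / sum(counts[ok]))
}
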