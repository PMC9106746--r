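# Windowed transcript-protein fold-change correlation: fold changes vs
# pre-heat, phase windows, per-term Pearson r, Silverman-KDE densities,
# and all-pairs scatter statistics.

#' Default heat/recovery correlation windows
#'
#' Three heat windows (HS1 = heat 0-1 h, HS2 = 2-8 h, HS3 = 16-24 h) and
#' three recovery windows (RE1 = recovery 0-2 h, RE2 = 4-8 h,
#' RE3 = 24-48 h).
#'
#' @return Named list of windows, each with `phase` and `times`.
#' @export
default_windows <- function() {
  list(
    HS1 = list(phase = "heat", times = c(0, 0.5, 1)),
    HS2 = list(phase = "heat", times = c(2, 4, 8)),
    HS3 = list(phase = "heat", times = c(16, 24)),
    RE1 = list(phase = "recovery", times = c(0, 2)),
    RE2 = list(phase = "recovery", times = c(4, 8)),
    RE3 = list(phase = "recovery", times = c(24, 48))
  )
}

#' Log2 fold-changes versus pre-heat
#'
#' For each treatment time point, `log2((mean_t + offset) /
#' (mean_preheat + offset))` of replicate means, per entity. Transcripts
#' use TPM with a 0.01 offset; proteins use normalized intensities
#' (offset 0).
#'
#' @param mat entities x samples numeric matrix (TPM or normalized
#'   intensity; `NA` allowed and ignored in means).
#' @param design matching [tc_design].
#' @param offset pseudocount added to both means.
#' @param treatments treatments to process (default: the heat treatments
#'   present).
#' @return Named list per treatment: `fc` (entities x time points, columns
#'   `phase_timeh`) and `grid` (data.frame of phase, time_h).
#' @export
log2fc_vs_preheat <- function(mat, design, offset = 0, treatments = NULL) {
  design <- design[design$sample_id %in% colnames(mat), , drop = FALSE]
  if (is.null(treatments))
    treatments <- intersect(c("heat35", "heat40"), unique(design$treatment))
  out <- list()
  for (trt in treatments) {
    seq_grp <- group_sequence(design, trt)
    pre <- seq_grp[[1L]]
    if (pre$phase != "pre_heat") stop("no pre_heat group for ", trt)
    mean_pre <- rowMeans(mat[, pre$samples, drop = FALSE], na.rm = TRUE)
    if (offset == 0 && any(!is.nan(mean_pre) & mean_pre == 0))
      stop("zero pre-heat mean without offset for ", trt)
    others <- seq_grp[-1L]
    fc <- vapply(others, function(g) {
      mu <- rowMeans(mat[, g$samples, drop = FALSE], na.rm = TRUE)
      log2((mu + offset) / (mean_pre + offset))
    }, numeric(nrow(mat)))
    fc <- matrix(fc, nrow = nrow(mat),
                 dimnames = list(rownames(mat),
                                 vapply(others, function(g)
                                   sprintf("%s_%gh", g$phase, g$time_h),
                                   character(1))))
    grid <- data.frame(
      phase = vapply(others, `[[`, character(1), "phase"),
      time_h = vapply(others, `[[`, numeric(1), "time_h"))
    out[[trt]] <- list(fc = fc, grid = grid)
  }
  out
}

#' Average fold-changes within phase windows
#'
#' @param fc_obj one treatment's element from [log2fc_vs_preheat()].
#' @param windows window list as from [default_windows()].
#' @return entities x windows matrix of mean log2 fold-changes; windows
#'   with no matching time point are dropped with a warning.
#' @export
window_average <- function(fc_obj, windows = default_windows()) {
  cols <- lapply(windows, function(w)
    which(fc_obj$grid$phase == w$phase & fc_obj$grid$time_h %in% w$times))
  empty <- lengths(cols) == 0L
  if (any(empty)) {
    warning("window(s) with no data dropped: ",
            paste(names(windows)[empty], collapse = ", "))
    cols <- cols[!empty]
  }
  out <- vapply(cols, function(ci)
    rowMeans(fc_obj$fc[, ci, drop = FALSE]), numeric(nrow(fc_obj$fc)))
  matrix(out, nrow = nrow(fc_obj$fc),
         dimnames = list(rownames(fc_obj$fc), names(cols)))
}

#' Per-term transcript-protein window correlations
#'
#' Pairs entities by shared identifier, collects for every (tree-expanded)
#' functional term and window the transcript/protein mean fold-change
#' pairs of its members, and reports the Pearson correlation when at least
#' `min_n` pairs exist.
#'
#' @param transcript_windows,protein_windows entities x windows matrices
#'   from [window_average()] (shared id space; ambiguous protein groups
#'   should be duplicated to singletons upstream).
#' @param onto an [ontology_annotation].
#' @param min_n minimum pairs per term per window.
#' @return data.frame: `term_id`, `window`, `r`, `n`.
#' @export
term_correlations <- function(transcript_windows, protein_windows, onto,
                              min_n = 3L) {
  shared <- intersect(rownames(transcript_windows),
                      rownames(protein_windows))
  wins <- intersect(colnames(transcript_windows), colnames(protein_windows))
  exp_asg <- expand_annotation(onto)
  by_term <- split(
    rep(names(exp_asg), lengths(exp_asg)),
    unlist(exp_asg, use.names = FALSE))
  out <- list()
  for (term in names(by_term)) {
    ids <- intersect(by_term[[term]], shared)
    for (w in wins) {
      x <- transcript_windows[ids, w]
      y <- protein_windows[ids, w]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < min_n) next
      r <- suppressWarnings(stats::cor(x[ok], y[ok]))
      if (is.na(r)) next
      out[[length(out) + 1L]] <- data.frame(term_id = term, window = w,
                                            r = r, n = sum(ok))
    }
  }
  if (length(out) == 0L)
    return(data.frame(term_id = character(0), window = character(0),
                      r = numeric(0), n = integer(0)))
  do.call(rbind, out)
}

#' Kernel density of term correlation coefficients
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth
#' `h = 0.9 min(sd, IQR/1.34) n^(-1/5)`; a zero-spread input falls back to
#' a bandwidth floor of 1e-3 with a warning.
#'
#' @param r numeric vector of correlation coefficients (>= 2 values).
#' @param from,to,n evaluation grid.
#' @return data.frame `grid`, `density`; the bandwidth is attached as
#'   attribute `bw`.
#' @export
correlation_density <- function(r, from = -1, to = 1, n = 512L) {
  r <- r[is.finite(r)]
  if (length(r) < 2L) stop("need at least 2 correlation values")
  spread <- min(stats::sd(r), stats::IQR(r) / 1.34)
  h <- 0.9 * spread * length(r)^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    warning("zero spread; bandwidth floored at 1e-3")
    h <- 1e-3
  }
  d <- stats::density(r, bw = h, kernel = "gaussian", from = from, to = to,
                      n = n)
  structure(data.frame(grid = d$x, density = d$y), bw = h)
}

#' All-pairs window scatter statistics
#'
#' Per window: Pearson correlation over all transcript-protein pairs,
#' ordinary least-squares fit of protein on transcript fold-change, and
#' the functional term with the highest per-term correlation (n >= 3).
#'
#' @param transcript_windows,protein_windows matrices from
#'   [window_average()].
#' @param term_corr optional output of [term_correlations()] used to flag
#'   the top term per window.
#' @return data.frame: `window`, `n`, `r`, `slope`, `intercept`,
#'   `top_term` (`NA` without `term_corr`).
#' @export
global_scatter <- function(transcript_windows, protein_windows,
                           term_corr = NULL) {
  shared <- intersect(rownames(transcript_windows),
                      rownames(protein_windows))
  wins <- intersect(colnames(transcript_windows), colnames(protein_windows))
  out <- list()
  for (w in wins) {
    x <- transcript_windows[shared, w]
    y <- protein_windows[shared, w]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stop("window ", w, " has fewer than 3 pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("degenerate variance in window ", w)
    slope <- stats::cov(x, y) / stats::var(x)
    top <- NA_character_
    if (!is.null(term_corr)) {
      tc <- term_corr[term_corr$window == w & term_corr$n >= 3, ]
      if (nrow(tc)) top <- tc$term_id[which.max(tc$r)]
    }
    out[[length(out) + 1L]] <- data.frame(
      window = w, n = length(x), r = stats::cor(x, y), slope = slope,
      intercept = mean(y) - slope * mean(x), top_term = top)
  }
  do.call(rbind, out)
}
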