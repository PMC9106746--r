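# Count filtering, TPM, the three-criterion DE call, DEG set algebra, and
# surprisal (SVD constraint) decomposition.

#' Filter genes by minimum read support
#'
#' Keeps genes with at least `min_reads` mapped reads in at least
#' `ceiling(min_fraction * n_samples)` samples (default: >= 10 reads in
#' >= 10% of samples).
#'
#' @param em an [expr_matrix].
#' @param min_reads minimum count per sample to count as supported.
#' @param min_fraction minimum fraction of samples with support.
#' @return Filtered [expr_matrix].
#' @export
filter_genes <- function(em, min_reads = 10, min_fraction = 0.10) {
  n_needed <- ceiling(min_fraction * ncol(em$counts))
  keep <- rowSums(em$counts >= min_reads) >= n_needed
  if (!any(keep)) {
    warning("no genes pass the read-support filter")
    empty <- matrix(integer(0), 0L, ncol(em$counts),
                    dimnames = list(character(0), colnames(em$counts)))
    return(expr_matrix(empty, em$gene_length[0]))
  }
  expr_matrix(em$counts[keep, , drop = FALSE], em$gene_length[keep])
}

#' Transcripts per million
#'
#' `TPM_i = 1e6 * r_i / sum_j r_j` per sample, where
#' `r_i = count_i / (length_i / 1000)` is the length-scaled read rate.
#' Every column of the result sums to 1e6.
#'
#' @param em an [expr_matrix].
#' @return Numeric matrix of TPM values, genes x samples.
#' @export
compute_tpm <- function(em) {
  rate <- em$counts / (em$gene_length / 1000)
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(em$counts)[tot == 0], collapse = ", "))
  sweep(rate, 2L, tot, "/") * 1e6
}

de_contrasts <- function(design) {
  trts <- intersect(c("heat35", "heat40"), unique(design$treatment))
  out <- list()
  for (trt in trts) {
    sub <- design[design$treatment == trt & design$phase != "pre_heat", ]
    grp <- unique(sub[c("phase", "time_h")])
    grp <- grp[order(match(grp$phase, PHASES), grp$time_h), ]
    for (i in seq_len(nrow(grp)))
      out[[length(out) + 1L]] <- list(treatment = trt, phase = grp$phase[i],
                                      time_h = grp$time_h[i])
  }
  out
}

#' Differential expression versus pre-heat
#'
#' For each heat treatment and each post-pre-heat time point, fits a
#' negative binomial GLM (edgeR) on the counts of that time point's
#' replicates against the treatment's pre-heat replicates, tests the group
#' coefficient by likelihood ratio, and adjusts p values with
#' Benjamini-Hochberg across genes within the contrast. A gene is called
#' significant when all three criteria hold: `|log2FC| > 1`, `FDR < 0.05`,
#' and the absolute difference of raw mean TPM between the time point and
#' pre-heat is at least `min_tpm_diff`.
#'
#' @param em a filtered [expr_matrix].
#' @param design a [tc_design] covering the samples of `em`.
#' @param lfc_cut,fdr_cut,min_tpm_diff significance rule thresholds.
#' @return data.frame of DEG records: `gene_id`, `treatment`, `phase`,
#'   `time_h`, `log2fc`, `p`, `fdr`, `tpm_ctrl`, `tpm_trt`, `significant`.
#' @export
differential_expression <- function(em, design, lfc_cut = 1, fdr_cut = 0.05,
                                    min_tpm_diff = 1) {
  stopifnot(inherits(em, "expr_matrix"), inherits(design, "tc_design"))
  missing_samp <- setdiff(colnames(em$counts), design$sample_id)
  if (length(missing_samp))
    stop("samples absent from design: ", paste(missing_samp, collapse = ", "))
  tpm <- compute_tpm(em)
  empty <- data.frame(gene_id = character(0), treatment = character(0),
                      phase = character(0), time_h = numeric(0),
                      log2fc = numeric(0), p = numeric(0), fdr = numeric(0),
                      tpm_ctrl = numeric(0), tpm_trt = numeric(0),
                      significant = logical(0))
  res <- list()
  for (ct in de_contrasts(design)) {
    pre <- design$sample_id[design$treatment == ct$treatment &
                              design$phase == "pre_heat"]
    trt <- design$sample_id[design$treatment == ct$treatment &
                              design$phase == ct$phase &
                              design$time_h == ct$time_h]
    pre <- intersect(pre, colnames(em$counts))
    trt <- intersect(trt, colnames(em$counts))
    if (length(pre) < 2L || length(trt) < 2L) {
      warning(sprintf("contrast %s %s %g h skipped: <2 replicates",
                      ct$treatment, ct$phase, ct$time_h))
      next
    }
    group <- factor(rep(c("pre", "trt"), c(length(pre), length(trt))),
                    levels = c("pre", "trt"))
    mm <- stats::model.matrix(~group)
    y <- edgeR::DGEList(em$counts[, c(pre, trt), drop = FALSE], group = group)
    y <- edgeR::calcNormFactors(y)
    y <- edgeR::estimateDisp(y, mm)
    fit <- edgeR::glmFit(y, mm)
    lrt <- edgeR::glmLRT(fit, coef = 2L)
    tab <- lrt$table
    fdr <- stats::p.adjust(tab$PValue, method = "BH")
    tpm_ctrl <- rowMeans(tpm[, pre, drop = FALSE])
    tpm_trt <- rowMeans(tpm[, trt, drop = FALSE])
    res[[length(res) + 1L]] <- data.frame(
      gene_id = rownames(tab), treatment = ct$treatment, phase = ct$phase,
      time_h = ct$time_h, log2fc = tab$logFC, p = tab$PValue, fdr = fdr,
      tpm_ctrl = tpm_ctrl, tpm_trt = tpm_trt,
      significant = abs(tab$logFC) > lfc_cut & fdr < fdr_cut &
        abs(tpm_ctrl - tpm_trt) >= min_tpm_diff,
      row.names = NULL)
  }
  if (length(res) == 0L) return(empty)
  do.call(rbind, res)
}

#' Per-time-point DEG set algebra between two treatments
#'
#' Splits each treatment's significant genes by the sign of the fold
#' change and counts overlapping and treatment-unique genes at every
#' shared time point.
#'
#' @param degs_35,degs_40 DEG tables from [differential_expression()] for
#'   the two treatments.
#' @return data.frame with columns `phase`, `time_h`, `direction`
#'   (`up`/`down`), `overlap`, `unique_35`, `unique_40`.
#' @export
deg_sets <- function(degs_35, degs_40) {
  grid <- unique(rbind(degs_35[c("phase", "time_h")],
                       degs_40[c("phase", "time_h")]))
  grid <- grid[order(match(grid$phase, PHASES), grid$time_h), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(grid))) {
    for (dir in c("up", "down")) {
      pick <- function(d) {
        sig <- d$significant & d$phase == grid$phase[i] &
          d$time_h == grid$time_h[i] &
          (if (dir == "up") d$log2fc > 0 else d$log2fc < 0)
        unique(d$gene_id[sig])
      }
      s35 <- pick(degs_35); s40 <- pick(degs_40)
      out[[length(out) + 1L]] <- data.frame(
        phase = grid$phase[i], time_h = grid$time_h[i], direction = dir,
        overlap = length(intersect(s35, s40)),
        unique_35 = length(setdiff(s35, s40)),
        unique_40 = length(setdiff(s40, s35)))
    }
  }
  do.call(rbind, out)
}

#' Surprisal decomposition of a TPM time course
#'
#' Singular value decomposition of the replicate-averaged `ln(TPM + 1)`
#' matrix (genes x time points) for one treatment. The leading component
#' (alpha = 0) is the baseline expression state; subsequent components are
#' time-dependent constraints with potentials
#' `lambda_alpha(t) = d_alpha * v_alpha(t)` and gene weights
#' `G_i_alpha = u_i_alpha`, ordered by decreasing singular value. The
#' first `n_constraints` post-baseline constraints are retained.
#'
#' @param tpm TPM matrix (genes x samples) from [compute_tpm()].
#' @param design matching [tc_design].
#' @param treatment which treatment's time course to decompose.
#' @param n_constraints number of constraints kept beyond the baseline.
#' @return Object of class `surprisal_decomposition`: `lambda`
#'   ((n_constraints + 1) x time points, row `alpha0` first), `weights`
#'   (genes x (n_constraints + 1)), `var_fraction` per retained component,
#'   `time` (labels), and the full SVD for reconstruction diagnostics.
#' @export
surprisal_analysis <- function(tpm, design, treatment, n_constraints = 3) {
  sub <- design[design$treatment == treatment &
                  design$sample_id %in% colnames(tpm), ]
  grp <- unique(sub[c("phase", "time_h")])
  grp <- grp[order(match(grp$phase, PHASES), grp$time_h), , drop = FALSE]
  if (nrow(grp) < 4L)
    stop("surprisal analysis needs at least 4 time points")
  prof <- vapply(seq_len(nrow(grp)), function(i) {
    ids <- sub$sample_id[sub$phase == grp$phase[i] &
                           sub$time_h == grp$time_h[i]]
    rowMeans(log(tpm[, ids, drop = FALSE] + 1))
  }, numeric(nrow(tpm)))
  colnames(prof) <- paste0(grp$phase, "_", grp$time_h, "h")
  sv <- svd(prof)
  k <- min(n_constraints + 1L, length(sv$d))
  lambda <- t(sv$v[, seq_len(k), drop = FALSE]) * sv$d[seq_len(k)]
  rownames(lambda) <- paste0("alpha", seq_len(k) - 1L)
  colnames(lambda) <- colnames(prof)
  weights <- sv$u[, seq_len(k), drop = FALSE]
  rownames(weights) <- rownames(tpm)
  colnames(weights) <- rownames(lambda)
  structure(list(lambda = lambda, weights = weights,
                 var_fraction = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
                 time = colnames(prof), svd = sv, profile = prof),
            class = "surprisal_decomposition")
}

#' Reconstruction error with the first k components
#'
#' Frobenius norm of the residual when the profile matrix is rebuilt from
#' the baseline plus the first `k` constraints; non-increasing in `k`.
#'
#' @param sd_obj a `surprisal_decomposition`.
#' @param k number of components used (baseline counts as 1).
#' @return Residual Frobenius norm.
#' @export
surprisal_reconstruction_error <- function(sd_obj, k) {
  sv <- sd_obj$svd
  k <- min(k, length(sv$d))
  approx <- sv$u[, seq_len(k), drop = FALSE] %*%
    (sv$d[seq_len(k)] * t(sv$v[, seq_len(k), drop = FALSE]))
  sqrt(sum((sd_obj$profile - approx)^2))
}
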