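# Proteome normalization, replicate-support filtering, kNN + Gaussian
# imputation, and Dunnett many-to-one testing.

# replicate groups of a treatment in phase order: pre_heat, heat times
# ascending, recovery times ascending; adjacency for imputation rule (ii)
# follows this sequence (pre-heat is adjacent to heat 0 h).
group_sequence <- function(design, treatment) {
  sub <- design[design$treatment == treatment, , drop = FALSE]
  grp <- unique(sub[c("phase", "time_h")])
  grp <- grp[order(match(grp$phase, PHASES), grp$time_h), , drop = FALSE]
  lapply(seq_len(nrow(grp)), function(i) {
    list(treatment = treatment, phase = grp$phase[i], time_h = grp$time_h[i],
         samples = sub$sample_id[sub$phase == grp$phase[i] &
                                   sub$time_h == grp$time_h[i]])
  })
}

#' Median-of-ratios normalization
#'
#' DESeq-style size factors computed from complete rows only: the
#' reference for each fully observed protein is its geometric mean across
#' samples; each sample's size factor is the median over those proteins of
#' intensity/reference, and every column is divided by its factor.
#'
#' @param pm a [proteome_matrix].
#' @return List with `matrix` (normalized [proteome_matrix]) and
#'   `size_factors` (named numeric).
#' @export
normalize_median_of_ratios <- function(pm) {
  m <- pm$intensities
  complete <- rowSums(is.na(m)) == 0L
  if (!any(complete))
    stop("no protein observed in all samples; filter the matrix first")
  ref <- exp(rowMeans(log(m[complete, , drop = FALSE])))
  sf <- apply(m[complete, , drop = FALSE] / ref, 2L, stats::median)
  norm <- sweep(m, 2L, sf, "/")
  list(matrix = proteome_matrix(norm, pm$proteotypic),
       size_factors = sf)
}

#' Drop proteins without replicate support
#'
#' Removes proteins for which no biological replicate group (treatment x
#' phase x time point) has more than one observed value -- such proteins
#' cannot support quantitative group statistics.
#'
#' @param pm a [proteome_matrix].
#' @param design a [tc_design] covering the samples of `pm`.
#' @return Filtered [proteome_matrix].
#' @export
filter_replicate_support <- function(pm, design) {
  m <- pm$intensities
  obs <- !is.na(m)
  key <- paste(design$treatment, design$phase, design$time_h, sep = "\r")
  key <- key[match(colnames(m), design$sample_id)]
  n_obs_by_grp <- t(rowsum(t(obs) + 0, key))
  keep <- apply(n_obs_by_grp, 1L, function(v) any(v >= 2))
  proteome_matrix(m[keep, , drop = FALSE], pm$proteotypic[keep])
}

#' Impute missing proteome values
#'
#' Works on log2 intensities. For each protein and replicate group:
#' (i) groups with at least one observed value get missing entries drawn
#' from `Normal(group mean of observed, global sd)`; (ii) wholly missing
#' groups whose adjacent time points (previous/next grid point of the same
#' treatment, pre-heat adjacent to heat 0 h) contain at least one value get
#' a group mean from k-nearest-neighbour proteins (Euclidean distance over
#' shared observed group-mean time profiles, neighbours restricted to
#' proteins observed in the query group), then entries are sampled as in
#' (i); (iii) wholly missing groups with empty adjacent groups are left
#' missing. The global sd is the pooled within-group standard deviation of
#' log2 intensities across all proteins.
#'
#' @param pm a normalized, filtered [proteome_matrix].
#' @param design matching [tc_design].
#' @param k number of nearest neighbours for rule (ii).
#' @param seed RNG seed for the Gaussian draws.
#' @return List with `matrix` (imputed [proteome_matrix]), `report`
#'   (one row per originally missing cell: `protein_id`, `sample_id`,
#'   `treatment`, `phase`, `time_h`, `status` in
#'   `{imputed_group, imputed_knn, left_missing}`, `value`, `neighbors`)
#'   and `global_sd`.
#' @export
impute_proteome <- function(pm, design, k = 3L, seed = 1L) {
  set.seed(seed)
  m <- log2(pm$intensities)
  design <- design[match(colnames(m), design$sample_id), , drop = FALSE]
  trts <- unique(design$treatment)
  seqs <- lapply(stats::setNames(trts, trts),
                 function(trt) group_sequence(design, trt))
  groups <- do.call(c, unname(seqs))
  grp_cols <- lapply(groups, function(g) match(g$samples, colnames(m)))

  # per-protein per-group means of observed values; pooled within-group sd
  grp_means <- sapply(grp_cols, function(cols)
    rowMeans(m[, cols, drop = FALSE], na.rm = TRUE))
  grp_means[is.nan(grp_means)] <- NA_real_
  ss <- 0; dfree <- 0
  for (cols in grp_cols) {
    sub <- m[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    mu <- rowMeans(sub, na.rm = TRUE)
    dev2 <- rowSums((sub - mu)^2, na.rm = TRUE)
    ss <- ss + sum(dev2[n_obs >= 2])
    dfree <- dfree + sum(pmax(n_obs - 1L, 0L))
  }
  global_sd <- if (dfree > 0) sqrt(ss / dfree) else 0
  if (dfree == 0) warning("no replicated observations; global sd set to 0")

  rep_protein <- character(0); rep_sample <- character(0)
  rep_grp <- integer(0); rep_status <- character(0)
  rep_value <- numeric(0); rep_nb <- character(0)
  add_rows <- function(p, cis, gi, status, vals, nb = "") {
    rep_protein <<- c(rep_protein, rep(rownames(m)[p], length(cis)))
    rep_sample <<- c(rep_sample, colnames(m)[cis])
    rep_grp <<- c(rep_grp, rep(gi, length(cis)))
    rep_status <<- c(rep_status, rep(status, length(cis)))
    rep_value <<- c(rep_value, vals)
    rep_nb <<- c(rep_nb, rep(nb, length(cis)))
  }
  out <- m
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    cols <- grp_cols[[gi]]
    sub <- m[, cols, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    # rule (i): partially observed groups
    for (p in which(n_obs > 0 & n_obs < length(cols))) {
      cis <- cols[is.na(m[p, cols])]
      vals <- stats::rnorm(length(cis), grp_means[p, gi], global_sd)
      out[p, cis] <- vals
      add_rows(p, cis, gi, "imputed_group", vals)
    }
    # rules (ii)/(iii): wholly missing groups
    seq_this <- seqs[[g$treatment]]
    pos <- which(vapply(seq_this, function(h)
      h$phase == g$phase && h$time_h == g$time_h, logical(1)))
    adj <- seq_this[c(pos - 1L, pos + 1L)]
    adj <- adj[!vapply(adj, is.null, logical(1))]
    adj_gi <- vapply(adj, function(h) which(vapply(groups, function(q)
      q$treatment == h$treatment && q$phase == h$phase &&
        q$time_h == h$time_h, logical(1)))[1L], integer(1))
    donors <- which(n_obs > 0)
    for (p in which(n_obs == 0L)) {
      has_adjacent <- length(adj_gi) > 0 &&
        any(!is.na(grp_means[p, adj_gi, drop = TRUE]))
      if (!has_adjacent || length(donors) == 0L) {
        add_rows(p, cols, gi, "left_missing", rep(NA_real_, length(cols)))
        next
      }
      diff2 <- (grp_means[donors, , drop = FALSE] -
                  rep(grp_means[p, ], each = length(donors)))^2
      dd <- sqrt(rowMeans(diff2, na.rm = TRUE))
      ok <- is.finite(dd)
      if (!any(ok)) {  # no shared time points: treat as rule (iii)
        add_rows(p, cols, gi, "left_missing", rep(NA_real_, length(cols)))
        next
      }
      cand <- donors[ok]
      kk <- min(k, length(cand))
      if (kk < k)
        warning(sprintf("protein %s group %s %g h: only %d eligible neighbours",
                        rownames(m)[p], g$phase, g$time_h, kk))
      ord <- order(dd[ok], rownames(m)[cand])[seq_len(kk)]
      nb <- cand[ord]
      mu <- mean(grp_means[nb, gi])
      vals <- stats::rnorm(length(cols), mu, global_sd)
      out[p, cols] <- vals
      add_rows(p, cols, gi, "imputed_knn", vals,
               paste(rownames(m)[nb], collapse = ","))
    }
  }
  report <- data.frame(
    protein_id = rep_protein, sample_id = rep_sample,
    treatment = vapply(groups[rep_grp], `[[`, character(1), "treatment"),
    phase = vapply(groups[rep_grp], `[[`, character(1), "phase"),
    time_h = vapply(groups[rep_grp], `[[`, numeric(1), "time_h"),
    status = rep_status, value = rep_value, neighbors = rep_nb)
  if (nrow(report) == 0L)
    report <- data.frame(protein_id = character(0), sample_id = character(0),
                         treatment = character(0), phase = character(0),
                         time_h = numeric(0), status = character(0),
                         value = numeric(0), neighbors = character(0))
  list(matrix = proteome_matrix(2^out, pm$proteotypic), report = report,
       global_sd = global_sd)
}

# Two-sided Dunnett adjusted p for equicorrelated (balanced) many-to-one
# comparisons: P(max_j |T_j| >= t) with T = (Z_j - Z_0)/(sqrt(2) S),
# Z iid N(0,1), S^2 ~ chi^2_df/df. Evaluated by nested quadrature.
dunnett_p_balanced <- function(t, g, df) {
  if (!is.finite(t)) return(0)
  t <- abs(t)
  if (t <= 0) return(1)
  if (g == 1L) return(2 * stats::pt(-t, df))
  if (t > 9) return(min(1, g * 2 * stats::pt(-t, df)))
  inner <- function(s) {
    f <- function(z0)
      stats::dnorm(z0) *
        (stats::pnorm(z0 + sqrt(2) * t * s) -
           stats::pnorm(z0 - sqrt(2) * t * s))^g
    stats::integrate(f, -9, 9, rel.tol = 1e-9)$value
  }
  dens_s <- function(s)
    exp((df / 2) * log(df / 2) - lgamma(df / 2) + (df - 1) * log(s) -
          df * s^2 / 2 + log(2))
  outer_f <- function(s) vapply(s, function(si) dens_s(si) * inner(si),
                                numeric(1))
  acc <- stats::integrate(outer_f, 0, Inf, rel.tol = 1e-8)$value
  max(0, min(1, 1 - acc))
}

# vectorized over t via monotone interpolation on a fine grid
dunnett_padj_vec <- function(tvals, g, df) {
  tvals <- abs(tvals)
  if (g == 1L) return(2 * stats::pt(-tvals, df))
  grid <- seq(0, 9, by = 0.05)
  pg <- vapply(grid, dunnett_p_balanced, numeric(1), g = g, df = df)
  fn <- stats::splinefun(grid, pg, method = "hyman")
  out <- ifelse(tvals > 9, pmin(1, g * 2 * stats::pt(-tvals, df)),
                pmin(1, pmax(0, fn(tvals))))
  out
}

# Monte-Carlo Dunnett for unbalanced replicate counts (seeded upstream)
dunnett_padj_mc <- function(tvals, n_trt, n_ctrl, df, B = 20000L) {
  g <- length(n_trt)
  maxT <- replicate(B, {
    z0 <- stats::rnorm(1L, 0, sqrt(1 / n_ctrl))
    zj <- stats::rnorm(g, 0, sqrt(1 / n_trt))
    s <- sqrt(stats::rchisq(1L, df) / df)
    max(abs(zj - z0) / (s * sqrt(1 / n_trt + 1 / n_ctrl)))
  })
  vapply(abs(tvals), function(t) mean(maxT >= t), numeric(1))
}

#' Dunnett many-to-one test of proteins against pre-heat
#'
#' For every treatment time course, compares the log2 intensity of each
#' time point group to the treatment's pre-heat control with Dunnett's
#' multiple-comparison procedure (multivariate-t single-step adjustment,
#' pooled within-group variance). Proteins quantified by ambiguous
#' (non-proteotypic) peptides or with any missing value in the treatment's
#' samples are excluded.
#'
#' @param pm a [proteome_matrix] (normalized; typically imputed).
#' @param design matching [tc_design].
#' @param alphas significance levels flagged in the output.
#' @param seed RNG seed for the Monte-Carlo fallback used with unbalanced
#'   replicate counts.
#' @return data.frame with one row per protein x treatment x time point:
#'   `protein_id`, `treatment`, `phase`, `time_h`, `log2fc` (group minus
#'   control), `t`, `p_adj`, plus one logical flag column per alpha
#'   (`sig_0.05`, `sig_0.01`).
#' @export
dunnett_test <- function(pm, design, alphas = c(0.05, 0.01), seed = 1L) {
  set.seed(seed)
  m <- log2(pm$intensities)
  design <- design[match(colnames(m), design$sample_id), , drop = FALSE]
  res <- list()
  for (trt in unique(design$treatment)) {
    seq_grp <- group_sequence(design, trt)
    ctrl <- seq_grp[[1L]]
    if (ctrl$phase != "pre_heat" || length(ctrl$samples) < 2L)
      stop("treatment ", trt, " needs >= 2 pre-heat control replicates")
    others <- seq_grp[-1L]
    if (length(others) == 0L) next
    all_samples <- unlist(lapply(seq_grp, `[[`, "samples"))
    keep <- pm$proteotypic & rowSums(is.na(m[, all_samples, drop = FALSE])) == 0L
    if (!any(keep)) next
    sub <- m[keep, all_samples, drop = FALSE]
    grp_id <- rep(seq_along(seq_grp),
                  vapply(seq_grp, function(g) length(g$samples), integer(1)))
    n_by_grp <- tabulate(grp_id)
    df <- length(all_samples) - length(seq_grp)
    if (df < 1L) stop("no residual degrees of freedom for ", trt)
    means <- t(rowsum(t(sub), grp_id) / n_by_grp)
    resid2 <- sub - means[, grp_id, drop = FALSE]
    s2 <- rowSums(resid2^2) / df
    g <- length(others)
    balanced <- length(unique(n_by_grp)) == 1L
    tstat <- (means[, -1L, drop = FALSE] - means[, 1L]) /
      sqrt(outer(s2, 1 / n_by_grp[-1L] + 1 / n_by_grp[1L]))
    tv <- as.vector(tstat)
    p_adj <- if (balanced) dunnett_padj_vec(tv, g, df) else
      dunnett_padj_mc(tv, n_by_grp[-1L], n_by_grp[1L], df)
    est <- as.vector(means[, -1L, drop = FALSE] - means[, 1L])
    block <- data.frame(
      protein_id = rep(rownames(sub), times = g),
      treatment = trt,
      phase = rep(vapply(others, `[[`, character(1), "phase"),
                  each = nrow(sub)),
      time_h = rep(vapply(others, `[[`, numeric(1), "time_h"),
                   each = nrow(sub)),
      log2fc = est, t = tv, p_adj = p_adj)
    for (a in alphas) block[[paste0("sig_", a)]] <- block$p_adj < a
    res[[length(res) + 1L]] <- block
  }
  if (length(res) == 0L)
    return(data.frame(protein_id = character(0), treatment = character(0),
                      phase = character(0), time_h = numeric(0),
                      log2fc = numeric(0), t = numeric(0),
                      p_adj = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
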