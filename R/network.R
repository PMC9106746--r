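# RMT-thresholded correlation network: ANOVA prefilter, spectral
# threshold selection, greedy-modularity modules with signed eigenvectors,
# ANOVA module assignment, and ontology-expanded enrichment.

#' Split ambiguous protein groups into singleton entities
#'
#' Protein groups quantified by shared (non-proteotypic) peptides carry
#' ids like `"p1;p2"`; network and enrichment stages treat each member as
#' its own entity with the group's intensity profile.
#'
#' @param pm a [proteome_matrix].
#' @return A [proteome_matrix] with one row per member protein.
#' @export
duplicate_to_singletons <- function(pm) {
  ids <- rownames(pm$intensities)
  members <- strsplit(ids, ";", fixed = TRUE)
  idx <- rep(seq_along(ids), lengths(members))
  m <- pm$intensities[idx, , drop = FALSE]
  rownames(m) <- unlist(members)
  proteome_matrix(m, pm$proteotypic[idx])
}

# vectorized one-way ANOVA across replicate groups; x: entities x samples
anova_f_p <- function(x, grp) {
  grp <- as.integer(factor(grp))
  n_by <- tabulate(grp)
  k <- length(n_by)
  n <- length(grp)
  means <- t(rowsum(t(x), grp) / n_by)
  grand <- rowMeans(x)
  ss_between <- rowSums(sweep(means, 2L, n_by, function(a, b) b * a^2)) -
    n * grand^2
  ss_within <- rowSums((x - means[, grp, drop = FALSE])^2)
  df1 <- k - 1L
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[ss_within == 0 & ss_between <= 1e-12] <- 1
  data.frame(f = f, p = p)
}

#' ANOVA prefilter of constant profiles
#'
#' Keeps entities whose log2 intensity differs across replicate groups by
#' one-way ANOVA at `p < alpha`; ambiguous protein groups are first
#' duplicated to singletons.
#'
#' @param pm a [proteome_matrix] (complete, e.g. imputed).
#' @param design matching [tc_design].
#' @param alpha ANOVA significance cutoff.
#' @return A [proteome_matrix] restricted to significant entities.
#' @export
anova_prefilter <- function(pm, design, alpha = 0.05) {
  pm <- duplicate_to_singletons(pm)
  m <- log2(pm$intensities)
  if (anyNA(m)) stop("prefilter requires a complete (imputed) matrix")
  design <- design[match(colnames(m), design$sample_id), , drop = FALSE]
  grp <- paste(design$treatment, design$phase, design$time_h, sep = "\r")
  keep <- anova_f_p(m, grp)$p < alpha
  proteome_matrix(pm$intensities[keep, , drop = FALSE], pm$proteotypic[keep])
}

# nearest-neighbour spacing distribution of a thresholded matrix's
# spectrum; unfolding by cubic smoothing spline on the cumulative
# spectral function (few degrees of freedom -- a flexible fit tracks the
# empirical staircase and rigidifies the spacings), bins of width 0.25 on
# [0, 3]
nnsd_distances <- function(ev, bin_width = 0.25, s_max = 3) {
  ev <- sort(ev)
  ev <- ev[c(TRUE, diff(ev) > 1e-8)]   # drop degenerate copies
  n <- length(ev)
  if (n < 10L) return(NULL)
  cdf <- seq_len(n) / n
  fit <- tryCatch(stats::smooth.spline(ev, cdf, df = min(5, n - 2)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  unfolded <- n * stats::predict(fit, ev)$y
  s <- diff(sort(unfolded))
  s <- s[s >= 0]
  if (length(s) < 10L || mean(s) <= 0) return(NULL)
  s <- s / mean(s)
  breaks <- seq(0, s_max, by = bin_width)
  obs <- tabulate(findInterval(s[s < s_max], breaks,
                               rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L) / length(s)
  lo <- breaks[-length(breaks)]; hi <- breaks[-1L]
  exp_poisson <- exp(-lo) - exp(-hi)
  exp_wigner <- exp(-pi * lo^2 / 4) - exp(-pi * hi^2 / 4)
  chisq <- function(e) sum((obs - e)^2 / pmax(e, 1e-12))
  list(d_poisson = chisq(exp_poisson), d_wigner = chisq(exp_wigner),
       spacings = s)
}

#' NNSD statistics of a thresholded correlation matrix
#'
#' Diagnostic companion to [rmt_threshold()]: zeroes sub-threshold
#' entries, unfolds the spectrum, and returns the chi-square distances of
#' the nearest-neighbour spacing distribution to the Poisson and
#' Wigner-Dyson laws.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param threshold absolute-correlation threshold (0 keeps the full
#'   matrix).
#' @return list `d_poisson`, `d_wigner`, `spacings`, `wigner_like`
#'   (`d_wigner < d_poisson`); `NULL` when the spectrum is too degenerate.
#' @export
nnsd_stats <- function(corr, threshold = 0) {
  a <- corr
  a[abs(a) < threshold] <- 0
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  nd <- nnsd_distances(ev)
  if (is.null(nd)) return(NULL)
  nd$wigner_like <- nd$d_wigner < nd$d_poisson
  nd
}

#' Random-matrix-theory correlation threshold
#'
#' Scans candidate absolute-correlation thresholds; at each, entries below
#' the threshold are zeroed, the eigenvalue spectrum is unfolded with a
#' cubic smoothing spline on the cumulative spectral function, and the
#' nearest-neighbour spacing distribution (NNSD) is compared (chi-square
#' distance over bins of width 0.25 on \[0, 3\]) to the Poisson law
#' `exp(-s)` and the Wigner-Dyson surmise `(pi s/2) exp(-pi s^2/4)`. The
#' chosen threshold `rho*` is the smallest at which the NNSD is closer to
#' Poisson than to Wigner -- the point where correlated (GOE-like) noise
#' gives way to modular signal.
#'
#' @param corr symmetric correlation matrix with unit diagonal, at least
#'   50 entities.
#' @param scan candidate thresholds.
#' @return List: `rho_star`, `flag` (`ok`, `no_transition`, `no_signal`),
#'   and `scan` (data.frame of threshold, d_poisson, d_wigner).
#' @export
rmt_threshold <- function(corr, scan = seq(0.50, 0.99, by = 0.01)) {
  if (!isSymmetric(unname(corr), tol = 1e-8))
    stop("correlation matrix must be symmetric")
  if (nrow(corr) < 50L)
    stop("need at least 50 entities for spectral statistics")
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  rows <- list()
  rho_star <- NA_real_
  for (rho in scan) {
    a <- corr
    a[abs(a) < rho] <- 0
    ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
    nd <- nnsd_distances(ev)
    if (is.null(nd)) {
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = rho, d_poisson = NA_real_, d_wigner = NA_real_)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      threshold = rho, d_poisson = nd$d_poisson, d_wigner = nd$d_wigner)
    if (is.na(rho_star) && nd$d_poisson < nd$d_wigner) rho_star <- rho
  }
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$d_poisson)))
    return(list(rho_star = NA_real_, flag = "no_signal", scan = tab))
  if (is.na(rho_star))
    return(list(rho_star = max(scan), flag = "no_transition", scan = tab))
  list(rho_star = rho_star, flag = "ok", scan = tab)
}

#' Build correlation-network modules
#'
#' Thresholds the correlation matrix at `|r| >= rho_star`, detects
#' communities by greedy modularity maximization, discards singletons, and
#' summarizes each module by its eigenvector: the leading principal
#' component of the members' z-scored time profiles, standardized to zero
#' mean and unit variance over time points. Members negatively correlated
#' with the eigenvector carry sign -1 (their contribution was inverted);
#' the global sign is fixed so the mean member correlation is positive.
#'
#' @param corr correlation matrix over entities.
#' @param rho_star absolute-correlation threshold (from [rmt_threshold()]
#'   or user supplied).
#' @param profiles entities x time points matrix of replicate-averaged
#'   log2 intensities (rownames matching `corr`).
#' @return Object of class `network_modules`: list of modules, each with
#'   `module_id`, `members` (named sign vector), `eigenvector`,
#'   `var_explained`; plus the thresholded `graph` (igraph).
#' @export
build_modules <- function(corr, rho_star, profiles) {
  a <- abs(corr) >= rho_star
  diag(a) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  # greedy modularity (Louvain); fixed local seed for deterministic
  # tie-breaking, caller RNG state restored
  rng <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(20240901)
  comm <- igraph::cluster_louvain(gr)
  if (!is.null(rng)) assign(".Random.seed", rng, globalenv())
  memb <- igraph::membership(comm)
  mods <- list()
  for (cid in sort(unique(memb))) {
    ids <- names(memb)[memb == cid]
    if (length(ids) < 2L) next
    prof <- profiles[ids, , drop = FALSE]
    z <- t(scale(t(prof)))
    z[is.na(z)] <- 0
    sv <- svd(z)
    eig <- sv$v[, 1L]
    eig <- (eig - mean(eig)) / stats::sd(eig)
    cors <- apply(prof, 1L, function(r)
      suppressWarnings(stats::cor(r, eig)))
    cors[is.na(cors)] <- 0
    if (mean(cors) < 0) { eig <- -eig; cors <- -cors }
    names(eig) <- colnames(profiles)
    mods[[length(mods) + 1L]] <- list(
      module_id = sprintf("TM%d", length(mods) + 1L),
      members = stats::setNames(ifelse(cors >= 0, 1, -1), ids),
      eigenvector = eig,
      var_explained = sv$d[1L]^2 / sum(sv$d^2))
  }
  if (length(mods) == 0L) warning("thresholded graph has no modules")
  structure(list(modules = mods, graph = gr, rho_star = rho_star),
            class = "network_modules")
}

#' @export
print.network_modules <- function(x, ...) {
  cat("network_modules:", length(x$modules), "modules at |r| >=",
      format(x$rho_star), "\n")
  for (m in x$modules)
    cat(" ", m$module_id, ":", length(m$members), "members,",
        sprintf("%.0f%%", 100 * m$var_explained), "variance\n")
  invisible(x)
}

#' Assign entities to modules by ANOVA against eigenvectors
#'
#' Regresses every entity's time profile on every module eigenvector,
#' takes the regression F-test p value, adjusts all tests together with
#' Benjamini-Hochberg, and assigns each entity to its minimum-FDR module
#' when that FDR is below the cutoff; otherwise the entity stays
#' unassigned.
#'
#' @param profiles entities x time points matrix on the eigenvector grid.
#' @param modules a `network_modules` object (or list of modules).
#' @param fdr_cut assignment FDR cutoff.
#' @return data.frame: `entity_id`, `module_id` (`NA` when unassigned),
#'   `fdr`.
#' @export
assign_by_anova <- function(profiles, modules, fdr_cut = 0.05) {
  mods <- if (inherits(modules, "network_modules")) modules$modules else
    modules
  if (length(mods) == 0L)
    return(data.frame(entity_id = rownames(profiles),
                      module_id = NA_character_, fdr = NA_real_))
  n <- ncol(profiles)
  pmat <- vapply(mods, function(m) {
    r <- suppressWarnings(apply(profiles, 1L, stats::cor, y = m$eigenvector))
    r[is.na(r)] <- 0
    r2 <- pmin(r^2, 1 - 1e-12)
    f <- r2 / (1 - r2) * (n - 2)
    stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }, numeric(nrow(profiles)))
  pmat <- matrix(pmat, nrow = nrow(profiles))
  fdr <- matrix(stats::p.adjust(pmat, method = "BH"), nrow = nrow(pmat))
  best <- apply(fdr, 1L, which.min)
  best_fdr <- fdr[cbind(seq_len(nrow(fdr)), best)]
  assigned <- best_fdr < fdr_cut
  data.frame(
    entity_id = rownames(profiles),
    module_id = ifelse(assigned,
                       vapply(mods, `[[`, character(1), "module_id")[best],
                       NA_character_),
    fdr = best_fdr)
}

#' Hypergeometric term enrichment of a module
#'
#' Annotations are tree-expanded (an entity counts at every ancestor of
#' its assigned terms); for each term the upper-tail hypergeometric
#' probability of observing at least the module's overlap is computed, and
#' p values are Benjamini-Hochberg adjusted across terms within the
#' module.
#'
#' @param members character vector of module entity ids.
#' @param onto an [ontology_annotation].
#' @param universe character vector: all entities that entered the network
#'   stage.
#' @return data.frame: `term_id`, `k` (overlap), `n` (module size), `K`
#'   (term size in universe after expansion), `N` (universe size), `p`,
#'   `fdr`, `enriched` (fdr < 0.05).
#' @export
term_enrichment <- function(members, onto, universe) {
  members <- intersect(members, universe)
  exp_asg <- expand_annotation(onto)
  n <- length(members)
  big_n <- length(universe)
  term_of <- exp_asg[intersect(names(exp_asg), universe)]
  tab_universe <- table(unlist(term_of, use.names = FALSE))
  term_of_mod <- exp_asg[intersect(names(exp_asg), members)]
  tab_module <- table(unlist(term_of_mod, use.names = FALSE))
  terms <- names(tab_universe)
  if (length(terms) == 0L)
    return(data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      fdr = numeric(0), enriched = logical(0)))
  k <- as.integer(tab_module[terms]); k[is.na(k)] <- 0L
  big_k <- as.integer(tab_universe[terms])
  p <- stats::phyper(k - 1L, big_k, big_n - big_k, n, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term_id = terms, k = k, n = n, K = big_k, N = big_n,
                    p = p, fdr = fdr, enriched = fdr < 0.05)
  out[order(out$p), ]
}
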