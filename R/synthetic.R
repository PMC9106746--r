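# Synthetic-data generators emulating the statistical structure of the
# assays: NB counts with planted temporal archetypes, log-normal protein
# intensities with phase-dependent transcript coupling and structured
# missingness, ontology recipes, turbidostat OD traces, instrument
# kinetics, FACS histograms, and pigment absorbances.

default_archetypes <- function() {
  heat_t <- HEAT_TIMES; rec_t <- RECOVERY_TIMES
  prof <- function(heat, rec)
    stats::setNames(c(0, heat, rec),
                    c("pre_heat_0h", sprintf("heat_%gh", heat_t),
                      sprintf("recovery_%gh", rec_t)))
  list(
    heat_early = list(fraction = 0.05, profile = prof(
      c(1, 2, 2, 1.5, 1, 0.5, 0.25, 0.25), c(0.25, 0, 0, 0, 0, 0))),
    heat_late = list(fraction = 0.05, profile = prof(
      c(0, 0.25, 0.5, 1, 1.5, 2, 2, 2), c(2, 1.5, 1, 0.5, 0, 0))),
    heat_down = list(fraction = 0.05, profile = prof(
      -c(0.5, 1, 1.5, 2, 2, 2, 1.5, 1.5), -c(1.5, 1, 0.5, 0.25, 0, 0))),
    recovery_up = list(fraction = 0.05, profile = prof(
      c(0, 0, 0, 0, 0, 0, 0, 0), c(1, 2, 2, 1.5, 0.5, 0)))
  )
}

#' Synthetic multi-omics recipe
#'
#' Bundles every tunable of [simulate_omics()]: counts are negative
#' binomial with variance `mu + phi mu^2`; protein log2 fold-changes
#' follow the transcript fold-changes with phase-dependent coupling
#' (Pearson `rho_heat` across genes during heat windows, `rho_recovery`
#' during recovery); missingness combines a missing-completely-at-random
#' rate with an intensity-dependent (logistic, MNAR) component mimicking
#' label-free quantification dropouts.
#'
#' @param seed RNG seed.
#' @param n_genes,n_proteins numbers of genes and of proteins (a subset
#'   of the genes).
#' @param archetypes named list of temporal archetypes, each with
#'   `fraction` (of genes) and `profile` (named log2FC vector over the
#'   design grid, names `phase_timeh`); genes belong to at most one
#'   archetype, the rest are null.
#' @param treatment_scale multiplier of archetype profiles per heat
#'   treatment (the acute treatment responds more strongly).
#' @param nb_dispersion NB dispersion phi.
#' @param lib_size_range sampled library-size range (reads per sample).
#' @param rho_heat,rho_recovery transcript-protein fold-change coupling
#'   per phase, in \[-1, 1\].
#' @param protein_noise_sd replicate noise of log2 intensities.
#' @param mcar_rate completely-at-random missingness rate, in \[0, 1\].
#' @param mnar_mid,mnar_scale,mnar_max logistic MNAR parameters: missing
#'   probability `mnar_max * plogis((mnar_mid - log2 intensity) /
#'   mnar_scale)`.
#' @param ambiguous_rate fraction of proteins merged into two-member
#'   ambiguous (non-proteotypic) groups.
#' @param n_terms,term_depth,genes_per_term ontology recipe.
#' @return list of class `sim_recipe`.
#' @export
sim_recipe <- function(seed = 1L, n_genes = 2000L, n_proteins = 1000L,
                       archetypes = default_archetypes(),
                       treatment_scale = c(heat35 = 1, heat40 = 1.5),
                       nb_dispersion = 0.1,
                       lib_size_range = c(1e6, 2e6),
                       rho_heat = 0.8, rho_recovery = 0.1,
                       protein_noise_sd = 0.3,
                       mcar_rate = 0.05, mnar_mid = 21, mnar_scale = 1.5,
                       mnar_max = 0.5, ambiguous_rate = 0.05,
                       n_terms = 30L, term_depth = 2L,
                       genes_per_term = 40L) {
  stopifnot(n_proteins <= n_genes,
            abs(rho_heat) <= 1, abs(rho_recovery) <= 1,
            mcar_rate >= 0, mcar_rate <= 1, mnar_max >= 0, mnar_max <= 1,
            nb_dispersion >= 0)
  if (sum(vapply(archetypes, `[[`, numeric(1), "fraction")) > 1)
    stop("archetype fractions exceed 1")
  structure(as.list(environment()), class = "sim_recipe")
}

recipe_fc_profile <- function(recipe, design, treatment) {
  # archetype log2FC per gene x design group for one treatment
  grp <- group_sequence(design, treatment)
  keys <- vapply(grp, function(g) sprintf("%s_%gh", g$phase, g$time_h),
                 character(1))
  scale <- if (treatment %in% names(recipe$treatment_scale))
    recipe$treatment_scale[[treatment]] else 0
  fc <- matrix(0, recipe$n_genes, length(keys),
               dimnames = list(NULL, keys))
  if (scale == 0) return(fc)
  idx <- 1L
  for (an in names(recipe$archetypes)) {
    a <- recipe$archetypes[[an]]
    n_a <- round(a$fraction * recipe$n_genes)
    if (n_a == 0L) next
    missing_keys <- setdiff(keys, names(a$profile))
    if (length(missing_keys))
      stop("archetype ", an, " lacks time point(s): ",
           paste(missing_keys, collapse = ", "))
    rows <- idx:(idx + n_a - 1L)
    fc[rows, ] <- matrix(rep(a$profile[keys] * scale, each = n_a), n_a)
    idx <- idx + n_a
  }
  fc
}

#' Simulate a paired transcriptome-proteome experiment
#'
#' Generates NB read counts around length- and library-scaled means times
#' `2^(archetype log2FC)`, log-normal protein intensities whose group
#' fold-changes track the transcript fold-changes with phase-dependent
#' coupling, structured missingness (MCAR + intensity-dependent MNAR), an
#' ontology over the genes, and truth tables recording every planted
#' effect.
#'
#' @param recipe a [sim_recipe].
#' @param design a [tc_design] (defaults to the full paper grid).
#' @return list: `expression` ([expr_matrix]), `proteome`
#'   ([proteome_matrix]), `ontology` ([ontology_annotation]), `design`,
#'   and `truth` (gene archetypes, per-group transcript/protein log2FC
#'   matrices, pre-masking log2 intensities, missingness mechanism per
#'   masked cell).
#' @export
simulate_omics <- function(recipe, design = default_design()) {
  stopifnot(inherits(recipe, "sim_recipe"), inherits(design, "tc_design"))
  set.seed(recipe$seed)
  ng <- recipe$n_genes
  gene_ids <- sprintf("g%04d", seq_len(ng))
  gene_len <- stats::setNames(round(stats::runif(ng, 500, 5000)), gene_ids)
  base_log2_abund <- stats::rnorm(ng, 3, 1.5)  # relative abundance scale

  # archetype membership (disjoint blocks from the top of the gene list)
  arch <- rep("null", ng)
  idx <- 1L
  for (an in names(recipe$archetypes)) {
    n_a <- round(recipe$archetypes[[an]]$fraction * ng)
    if (n_a == 0L) next
    arch[idx:(idx + n_a - 1L)] <- an
    idx <- idx + n_a
  }

  trts <- unique(design$treatment)
  fc_by_trt <- lapply(stats::setNames(trts, trts), function(trt)
    recipe_fc_profile(recipe, design, trt))

  lib <- stats::runif(nrow(design), recipe$lib_size_range[1L],
                      recipe$lib_size_range[2L])
  names(lib) <- design$sample_id
  counts <- matrix(0L, ng, nrow(design),
                   dimnames = list(gene_ids, design$sample_id))
  for (si in seq_len(nrow(design))) {
    trt <- design$treatment[si]
    key <- sprintf("%s_%gh", design$phase[si], design$time_h[si])
    fc <- fc_by_trt[[trt]][, key]
    w <- 2^(base_log2_abund + fc) * gene_len / 1000
    mu <- lib[si] * w / sum(w)
    counts[, si] <- stats::rnbinom(ng, mu = mu,
                                   size = 1 / max(recipe$nb_dispersion,
                                                  1e-8))
  }

  # proteins: first n_proteins genes (covers archetype and null genes)
  np <- recipe$n_proteins
  prot_genes <- gene_ids[seq_len(np)]
  base_prot <- stats::rnorm(np, 25, 2)
  # Protein fold-changes track transcript fold-changes with per-phase
  # coupling rho; the decoupled component is a gene-level deviation drawn
  # once per phase (protein-specific translation/turnover persists over a
  # phase), scaled to the transcript fold-change spread so the across-gene
  # Pearson correlation per time point is ~rho.
  prot_fc_by_trt <- lapply(stats::setNames(trts, trts), function(trt) {
    tfc <- fc_by_trt[[trt]][seq_len(np), , drop = FALSE]
    pfc <- tfc * 0
    eps <- list(heat = stats::rnorm(np), recovery = stats::rnorm(np))
    for (j in seq_len(ncol(tfc))) {
      key <- colnames(tfc)[j]
      phase <- sub("_[^_]+$", "", key)
      rho <- switch(phase, heat = recipe$rho_heat,
                    recovery = recipe$rho_recovery, 0)
      sd_t <- stats::sd(tfc[, j])
      if (!is.finite(sd_t) || sd_t == 0) sd_t <- 0
      dev <- if (phase %in% names(eps)) eps[[phase]] else 0
      pfc[, j] <- rho * tfc[, j] + sqrt(max(0, 1 - rho^2)) * sd_t * dev
    }
    pfc
  })

  log2_int <- matrix(NA_real_, np, nrow(design),
                     dimnames = list(prot_genes, design$sample_id))
  loading <- stats::rnorm(nrow(design), 0, 0.2)  # per-sample loading bias
  for (si in seq_len(nrow(design))) {
    trt <- design$treatment[si]
    key <- sprintf("%s_%gh", design$phase[si], design$time_h[si])
    log2_int[, si] <- base_prot + prot_fc_by_trt[[trt]][, key] +
      stats::rnorm(np, 0, recipe$protein_noise_sd) + loading[si]
  }

  p_mcar <- recipe$mcar_rate
  p_mnar <- recipe$mnar_max *
    stats::plogis((recipe$mnar_mid - log2_int) / recipe$mnar_scale)
  u <- matrix(stats::runif(length(log2_int)), nrow(log2_int))
  mech <- matrix("observed", np, nrow(design))
  mech[u < p_mnar] <- "mnar"
  mech[u >= p_mnar & u < p_mnar + p_mcar] <- "mcar"
  intensities <- 2^log2_int
  intensities[mech != "observed"] <- NA_real_

  # merge a fraction of proteins into ambiguous two-member groups
  proteotypic <- rep(TRUE, np)
  n_amb <- floor(recipe$ambiguous_rate * np / 2) * 2
  if (n_amb >= 2) {
    amb_idx <- seq(np - n_amb + 1L, np)
    pair_a <- amb_idx[seq(1L, n_amb, by = 2L)]
    pair_b <- amb_idx[seq(2L, n_amb, by = 2L)]
    merged <- intensities[pair_a, , drop = FALSE]
    rownames(merged) <- paste(prot_genes[pair_a], prot_genes[pair_b],
                              sep = ";")
    intensities <- rbind(intensities[-amb_idx, , drop = FALSE], merged)
    proteotypic <- c(rep(TRUE, np - n_amb), rep(FALSE, length(pair_a)))
  }

  onto <- simulate_ontology(recipe, gene_ids)
  truth <- list(
    gene_archetype = data.frame(gene_id = gene_ids, archetype = arch),
    transcript_log2fc = fc_by_trt,
    protein_log2fc = prot_fc_by_trt,
    log2_intensity = log2_int,
    missing_mechanism = mech,
    library_sizes = lib)
  list(expression = expr_matrix(counts, gene_len),
       proteome = proteome_matrix(intensities, proteotypic),
       ontology = onto, design = design, truth = truth)
}

simulate_ontology <- function(recipe, gene_ids) {
  n_parents <- max(1L, ceiling(recipe$n_terms / 5L))
  parents <- sprintf("bin%02d", seq_len(n_parents))
  children <- sprintf("bin%02d.%d", rep(seq_len(n_parents),
                                        length.out = recipe$n_terms),
                      seq_len(recipe$n_terms))
  terms <- rbind(
    data.frame(term_id = parents, name = paste("category", parents),
               parent = NA_character_),
    data.frame(term_id = children, name = paste("subcategory", children),
               parent = parents[rep(seq_len(n_parents),
                                    length.out = recipe$n_terms)]))
  asg <- lapply(children, function(ch)
    sample(gene_ids, min(recipe$genes_per_term, length(gene_ids))))
  assignments <- split(rep(children, lengths(asg)),
                       unlist(asg, use.names = FALSE))
  ontology_annotation(terms, assignments)
}

#' Simulate a turbidostat OD680 sawtooth trace
#'
#' Exponential growth from `target (1 - band)` up to `target (1 + band)`,
#' instantaneous dilution back to the lower bound, repeated for the trace
#' duration, with additive Gaussian noise.
#'
#' @param doubling_time_h culture doubling time (> 0).
#' @param target_od turbidostat target OD680.
#' @param band half-width of the turbidostat band as a fraction of the
#'   target (< 1).
#' @param duration_h trace length in hours.
#' @param noise_sd additive noise sd (OD units).
#' @param dt_h sampling interval in hours.
#' @param seed RNG seed.
#' @return An `od680` [kinetic_trace] with `x` in hours.
#' @export
simulate_od_trace <- function(doubling_time_h, target_od = 0.4,
                              band = 0.08, duration_h = 24,
                              noise_sd = 0, dt_h = 0.01, seed = 1L) {
  if (doubling_time_h <= 0) stop("doubling_time_h must be > 0")
  if (band >= 1 || band <= 0) stop("band must be in (0, 1)")
  set.seed(seed)
  t <- seq(0, duration_h, by = dt_h)
  od <- numeric(length(t))
  od[1L] <- target_od * (1 - band)
  growth <- 2^(dt_h / doubling_time_h)
  hi <- target_od * (1 + band)
  for (i in seq_along(t)[-1L]) {
    nxt <- od[i - 1L] * growth
    od[i] <- if (nxt > hi) target_od * (1 - band) else nxt
  }
  if (noise_sd > 0) od <- od + stats::rnorm(length(od), 0, noise_sd)
  kinetic_trace("od680", t, od,
                meta = list(doubling_time_h = doubling_time_h,
                            target_od = target_od, band = band))
}

#' Simulate instrument kinetic traces
#'
#' Realizes the stated model per instrument kind plus additive Gaussian
#' noise; parameters are echoed in `meta`.
#'
#' Kinds and parameters:
#' * `p700`: `amplitude`, `tau` (s), `offset` -- decay
#'   `A exp(-t/tau) + c` over 5 s (`meta$reduction_start = 0`).
#' * `ecs`: `ecst`, `tau` (s) -- 300 ms dark-interval decay
#'   (`meta$dark_start = 0`).
#' * `fluorescence`: `fo`, `fm`, `fs`, `fm_prime`, `fo_prime` --
#'   piecewise-constant segment levels, 1 s each.
#' * `spectrum77k`: `h686`, `h714`, `w686`, `w714` -- two Gaussian
#'   emission peaks on 650-750 nm.
#'
#' @param kind one of `p700`, `ecs`, `fluorescence`, `spectrum77k`.
#' @param params named list of kind-specific parameters.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return A [kinetic_trace].
#' @export
simulate_kinetics <- function(kind, params, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  add_noise <- function(y) if (noise_sd > 0)
    y + stats::rnorm(length(y), 0, noise_sd) else y
  if (kind == "p700") {
    if (params$tau <= 0) stop("tau must be > 0")
    t <- seq(0, 5, by = 0.01)
    y <- params$amplitude * exp(-t / params$tau) + params$offset
    return(kinetic_trace("p700", t, add_noise(y),
                         meta = c(params, reduction_start = 0)))
  }
  if (kind == "ecs") {
    if (params$tau <= 0) stop("tau must be > 0")
    t <- seq(0, 0.3, by = 0.001)
    y <- params$ecst * exp(-t / params$tau)
    return(kinetic_trace("ecs", t, add_noise(y),
                         meta = c(params, dark_start = 0)))
  }
  if (kind == "fluorescence") {
    lv <- with(params, c(fo, fm, fs, fm_prime, fo_prime))
    t <- seq(0, 5, by = 0.01)[-1L]
    y <- lv[pmin(ceiling(t), 5L)]
    return(kinetic_trace("fluorescence", t, add_noise(y), meta = params))
  }
  if (kind == "spectrum77k") {
    x <- seq(650, 750, by = 0.5)
    y <- params$h686 * exp(-(x - 686)^2 / (2 * params$w686^2)) +
      params$h714 * exp(-(x - 714)^2 / (2 * params$w714^2))
    return(kinetic_trace("spectrum77k", x, add_noise(y), meta = params))
  }
  stop("unknown kinetics kind: ", kind)
}

#' Simulate a FACS DNA-content histogram
#'
#' Draws per-cell signals `background + ploidy * unit_signal` with
#' log-normal spread `cv` and bins them into a log-spaced histogram.
#'
#' @param ploidy_fractions named fractions summing to 1 over ploidies in
#'   `{1, 2, 4, 8, 16}` (names like `"1C"`).
#' @param unit_signal fluorescence per 1C DNA content.
#' @param background cell-size-dependent background staining (>= 0).
#' @param n number of cells.
#' @param cv log-normal coefficient of variation of the per-cell signal.
#' @param n_bins histogram bins (log-spaced).
#' @param seed RNG seed.
#' @return A `facs_hist` [kinetic_trace] (`x` = bin centers on the raw
#'   signal scale, `y` = counts); true per-ploidy modes in
#'   `meta$true_modes`.
#' @export
simulate_facs <- function(ploidy_fractions, unit_signal, background,
                          n = 20000L, cv = 0.08, n_bins = 256L, seed = 1L) {
  if (background < 0) stop("background must be >= 0")
  pl <- as.integer(sub("C$", "", names(ploidy_fractions)))
  if (any(!pl %in% c(1L, 2L, 4L, 8L, 16L)))
    stop("ploidies must be in {1, 2, 4, 8, 16}")
  if (abs(sum(ploidy_fractions) - 1) > 1e-6)
    stop("ploidy fractions must sum to 1")
  set.seed(seed)
  ploidy <- sample(pl, n, replace = TRUE, prob = ploidy_fractions)
  mu <- background + ploidy * unit_signal
  signal <- mu * exp(stats::rnorm(n, 0, max(cv, 1e-12)))
  breaks <- exp(seq(log(min(signal) * 0.99), log(max(signal) * 1.01),
                    length.out = n_bins + 1L))
  counts <- tabulate(findInterval(signal, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  centers <- sqrt(breaks[-1L] * breaks[-(n_bins + 1L)])
  kinetic_trace("facs_hist", centers, counts,
                meta = list(true_modes = background + pl * unit_signal,
                            unit_signal = unit_signal,
                            background = background, cv = cv))
}

#' Absorbances producing given pigment concentrations
#'
#' Inverts the pigment equations (see [pigments()]) so that the forward
#' equations recover the requested chlorophyll a/b and carotenoid
#' concentrations exactly.
#'
#' @param chl_a,chl_b,carotenoids concentrations in ug/mL (>= 0).
#' @return data.frame: `a470`, `a652`, `a665`.
#' @export
simulate_absorbance <- function(chl_a, chl_b, carotenoids = 0) {
  stopifnot(length(chl_a) == length(chl_b),
            length(carotenoids) %in% c(1L, length(chl_a)))
  m <- matrix(c(16.29, -8.54, -13.58, 30.66), 2L, byrow = TRUE)
  ab <- solve(m, rbind(chl_a, chl_b))  # rows: A665, A652
  a470 <- (221 * carotenoids + 2.86 * chl_a + 129.2 * chl_b) / 1000
  data.frame(a470 = a470, a652 = ab[2L, ], a665 = ab[1L, ])
}
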