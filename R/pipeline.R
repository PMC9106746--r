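# Stage-chaining pipeline: simulate -> transcriptome -> proteome ->
# network -> integrate, driven by a config list or YAML file. All numeric
# outputs are a pure function of (inputs, config, seed).

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, reading inputs from
#' files or generating them with the synthetic recipe, and writes TSV
#' result tables plus a run log (package version, seed, parameters) to
#' the output directory. Identical config and seed give byte-identical
#' numeric tables.
#'
#' Config keys: `stages` (subset of `simulate`, `transcriptome`,
#' `proteome`, `network`, `integrate`), `seed`, `out`, `synthetic`
#' (overrides for [sim_recipe()]), `inputs` (`counts`, `lengths`,
#' `design`, `proteome`, `ontology_terms`, `ontology_assignments`),
#' `params` (`rho_star` fallback threshold, `knn_k`, `exclude_imputed`).
#'
#' @param config list or path to a YAML file.
#' @param out output directory (overrides `config$out`).
#' @param seed integer seed (overrides `config$seed`).
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config, out = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- unlist(config$stages)
  if (is.null(stages)) stages <- c("simulate", "transcriptome", "proteome",
                                   "network", "integrate")
  order_all <- c("simulate", "transcriptome", "proteome", "network",
                 "integrate")
  bad <- setdiff(stages, order_all)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- order_all[order_all %in% stages]
  out <- out %||% config$out
  if (is.null(out)) stop("no output directory configured")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  params <- config$params %||% list()

  state <- list()
  log_lines <- c(
    paste("heatomics", as.character(utils::packageVersion("heatomics"))),
    R.version.string,
    paste("seed:", seed),
    paste("stages:", paste(stages, collapse = ", ")),
    paste("config:", paste(deparse(config), collapse = " ")))

  need <- function(field, stage, loader) {
    if (!is.null(state[[field]])) return(state[[field]])
    loader(stage)
  }
  load_design <- function(stage) {
    p <- config$inputs$design
    if (is.null(p)) stop("stage '", stage, "' requires a design (inputs$design)")
    read_design(p)
  }
  load_expression <- function(stage) {
    p <- config$inputs$counts; l <- config$inputs$lengths
    if (is.null(p) || is.null(l))
      stop("stage '", stage,
           "' requires counts and lengths (inputs$counts, inputs$lengths)")
    read_counts(p, l)
  }
  load_proteome <- function(stage) {
    p <- config$inputs$proteome
    if (is.null(p))
      stop("stage '", stage, "' requires a proteome (inputs$proteome)")
    read_proteome(p)
  }
  load_ontology <- function(stage) {
    tp <- config$inputs$ontology_terms
    ap <- config$inputs$ontology_assignments
    if (is.null(tp) || is.null(ap))
      stop("stage '", stage, "' requires an ontology (inputs$ontology_terms,",
           " inputs$ontology_assignments)")
    read_ontology(tp, ap)
  }

  if ("simulate" %in% stages) {
    recipe <- do.call(sim_recipe, c(list(seed = seed),
                                    config$synthetic %||% list()))
    sim <- simulate_omics(recipe)
    state$design <- sim$design
    state$expression <- sim$expression
    state$proteome <- sim$proteome
    state$ontology <- sim$ontology
    write_design(sim$design, file.path(out, "design.tsv"))
    write_counts(sim$expression, file.path(out, "counts.tsv"),
                 file.path(out, "gene_lengths.tsv"))
    write_proteome(sim$proteome, file.path(out, "proteome.tsv"))
    write_ontology(sim$ontology, file.path(out, "ontology_terms.tsv"),
                   file.path(out, "ontology_assignments.tsv"))
    write_tsv(sim$truth$gene_archetype,
              file.path(out, "truth_gene_archetypes.tsv"))
    for (trt in names(sim$truth$transcript_log2fc))
      write_tsv(data.frame(gene_id = rownames(sim$expression$counts),
                           sim$truth$transcript_log2fc[[trt]],
                           check.names = FALSE),
                file.path(out, sprintf("truth_transcript_fc_%s.tsv", trt)))
    log_lines <- c(log_lines, "stage simulate: done")
  }

  if (any(c("transcriptome", "integrate") %in% stages)) {
    state$design <- need("design", stages[1L], load_design)
    state$expression <- need("expression", "transcriptome", load_expression)
    filtered <- filter_genes(state$expression)
    tpm <- compute_tpm(filtered)
    state$tpm <- tpm
    state$filtered <- filtered
  }

  if ("transcriptome" %in% stages) {
    degs <- differential_expression(state$filtered, state$design)
    write_tsv(degs, file.path(out, "deg_table.tsv"))
    state$degs <- degs
    if (all(c("heat35", "heat40") %in% degs$treatment)) {
      sets <- deg_sets(degs[degs$treatment == "heat35", ],
                       degs[degs$treatment == "heat40", ])
      write_tsv(sets, file.path(out, "deg_sets.tsv"))
    }
    for (trt in intersect(c("heat35", "heat40"),
                          unique(state$design$treatment))) {
      sa <- surprisal_analysis(tpm_for_treatment <- state$tpm,
                               state$design, trt)
      write_tsv(data.frame(component = rownames(sa$lambda), sa$lambda,
                           check.names = FALSE),
                file.path(out, sprintf("surprisal_lambda_%s.tsv", trt)))
    }
    log_lines <- c(log_lines, sprintf(
      "stage transcriptome: %d genes after filter, %d DEG records",
      nrow(state$filtered$counts), nrow(degs)))
  }

  if (any(c("proteome", "network", "integrate") %in% stages)) {
    state$design <- need("design", "proteome", load_design)
    state$proteome <- need("proteome", "proteome", load_proteome)
    # normalization/imputation run independently per heat time course
    prot_trts <- intersect(c("heat35", "heat40"),
                           unique(state$design$treatment))
    if (length(prot_trts) == 0L)
      stop("proteome stages need at least one heat treatment in the design")
    state$proteome_by_trt <- list()
    daps <- list()
    for (ti in seq_along(prot_trts)) {
      trt <- prot_trts[ti]
      samp <- state$design$sample_id[state$design$treatment == trt]
      samp <- intersect(colnames(state$proteome$intensities), samp)
      sub_pm <- proteome_matrix(
        state$proteome$intensities[, samp, drop = FALSE],
        state$proteome$proteotypic)
      norm <- normalize_median_of_ratios(sub_pm)
      filt <- filter_replicate_support(norm$matrix, state$design)
      imp <- impute_proteome(filt, state$design,
                             k = params$knn_k %||% 3L,
                             seed = seed + ti)
      state$proteome_by_trt[[trt]] <- imp$matrix
      if ("proteome" %in% stages) {
        write_proteome(imp$matrix,
                       file.path(out, sprintf("proteome_normalized_%s.tsv",
                                              trt)))
        write_tsv(imp$report,
                  file.path(out, sprintf("imputation_report_%s.tsv", trt)))
        write_tsv(data.frame(sample_id = names(norm$size_factors),
                             size_factor = norm$size_factors),
                  file.path(out, sprintf("size_factors_%s.tsv", trt)))
        daps[[trt]] <- dunnett_test(imp$matrix, state$design,
                                    seed = seed + 100L + ti)
        log_lines <- c(log_lines, sprintf(
          "stage proteome (%s): %d proteins kept, global sd %.4f",
          trt, nrow(imp$matrix$intensities), imp$global_sd))
      }
    }
    if ("proteome" %in% stages)
      write_tsv(do.call(rbind, daps), file.path(out, "dap_table.tsv"))
  }

  if ("network" %in% stages) {
    state$ontology <- need("ontology", "network", load_ontology)
    for (trt in names(state$proteome_by_trt)) {
      pm <- anova_prefilter(state$proteome_by_trt[[trt]], state$design)
      prof <- group_profiles(pm, state$design, trt)
      if (nrow(prof) < 3L) next
      corr <- stats::cor(t(prof))
      rho <- if (!is.null(params$rho_star)) params$rho_star else if
        (nrow(corr) >= 50L) rmt_threshold(corr)$rho_star else 0.8
      mods <- build_modules(corr, rho, prof)
      memb <- do.call(rbind, lapply(mods$modules, function(m)
        data.frame(entity_id = names(m$members), module_id = m$module_id,
                   sign = unname(m$members))))
      write_tsv(memb %||% data.frame(),
                file.path(out, sprintf("modules_%s.tsv", trt)))
      eig <- do.call(rbind, lapply(mods$modules, function(m)
        data.frame(module_id = m$module_id, t(m$eigenvector),
                   check.names = FALSE)))
      if (!is.null(eig))
        write_tsv(eig, file.path(out, sprintf("eigenvectors_%s.tsv", trt)))
      universe <- rownames(pm$intensities)
      enr <- do.call(rbind, lapply(mods$modules, function(m) {
        e <- term_enrichment(names(m$members), state$ontology, universe)
        if (nrow(e)) cbind(module_id = m$module_id, e) else NULL
      }))
      if (!is.null(enr))
        write_tsv(enr, file.path(out, sprintf("enrichment_%s.tsv", trt)))
      log_lines <- c(log_lines, sprintf(
        "stage network (%s): rho* = %.4f, %d modules", trt, rho,
        length(mods$modules)))
    }
  }

  if ("integrate" %in% stages) {
    state$ontology <- need("ontology", "integrate", load_ontology)
    t_fc <- log2fc_vs_preheat(state$tpm, state$design, offset = 0.01)
    for (trt in intersect(names(t_fc), names(state$proteome_by_trt))) {
      pm_trt <- state$proteome_by_trt[[trt]]
      pmat <- pm_trt$intensities
      if (isTRUE(params$exclude_imputed)) {
        rep_mask <- !is.na(state$proteome$intensities)
        common <- intersect(rownames(pmat), rownames(rep_mask))
        pmat[common, ][!rep_mask[common, colnames(pmat)]] <- NA
      }
      pmat <- duplicate_to_singletons(
        proteome_matrix(pmat, pm_trt$proteotypic))$intensities
      p_fc <- log2fc_vs_preheat(pmat, state$design, offset = 0,
                                treatments = trt)
      tw <- window_average(t_fc[[trt]])
      pw <- window_average(p_fc[[trt]])
      tc <- term_correlations(tw, pw, state$ontology)
      write_tsv(tc, file.path(out, sprintf("term_correlations_%s.tsv", trt)))
      dens <- do.call(rbind, lapply(unique(tc$window), function(w) {
        r <- tc$r[tc$window == w]
        if (length(r) < 2L) return(NULL)
        cbind(window = w, correlation_density(r))
      }))
      if (!is.null(dens))
        write_tsv(dens, file.path(out, sprintf("densities_%s.tsv", trt)))
      sc <- global_scatter(tw, pw, tc)
      write_tsv(sc, file.path(out, sprintf("scatter_%s.tsv", trt)))
      log_lines <- c(log_lines, sprintf(
        "stage integrate (%s): %d term-window correlations", trt, nrow(tc)))
    }
  }

  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(state)
}

#' Replicate-averaged log2 group profiles of a proteome
#'
#' @param pm a complete [proteome_matrix].
#' @param design matching [tc_design].
#' @param treatment treatment whose group sequence defines the columns.
#' @return entities x groups matrix of mean log2 intensities.
#' @export
group_profiles <- function(pm, design, treatment) {
  m <- log2(pm$intensities)
  design <- design[match(colnames(m), design$sample_id), , drop = FALSE]
  grp <- group_sequence(design, treatment)
  prof <- vapply(grp, function(g)
    rowMeans(m[, g$samples, drop = FALSE], na.rm = TRUE),
    numeric(nrow(m)))
  colnames(prof) <- vapply(grp, function(g)
    sprintf("%s_%gh", g$phase, g$time_h), character(1))
  prof
}

`%||%` <- function(a, b) if (is.null(a)) b else a
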