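#' heatomics: multi-omics analysis of algal heat-stress time courses
#'
#' Analysis tools for paired transcriptome-proteome time courses of
#' *Chlamydomonas reinhardtii* grown in turbidostatic photobioreactors and
#' exposed to moderate (35 degC) or acute (40 degC) heat followed by
#' recovery at 25 degC. The package covers the full desk-side pipeline:
#' differential expression with a three-criterion significance rule,
#' label-free proteome normalization/imputation/Dunnett testing,
#' random-matrix-theory thresholded correlation networks, windowed
#' transcript-protein fold-change correlation, and physiological /
#' spectroscopic parameter calculators, plus a synthetic-data generator
#' emulating the statistical structure of all assays.
#'
#' @keywords internal
"_PACKAGE"

TREATMENTS <- c("ctrl25", "heat35", "heat40")
PHASES <- c("pre_heat", "heat", "recovery")
HEAT_TIMES <- c(0, 0.5, 1, 2, 4, 8, 16, 24)
RECOVERY_TIMES <- c(0, 2, 4, 8, 24, 48)
TRACE_KINDS <- c("od680", "fluorescence", "ecs", "p700", "o2",
                 "spectrum77k", "facs_hist")

#' Time-course experimental design
#'
#' Validates and classes a sample design table mapping every sample to a
#' treatment, a phase of the experiment (pre-heat acclimation, heat, or
#' recovery), a time in hours within the phase, and a biological replicate.
#'
#' @param df data.frame with columns `sample_id`, `treatment` (one of
#'   `ctrl25`, `heat35`, `heat40`), `phase` (one of `pre_heat`, `heat`,
#'   `recovery`), `time_h` (non-negative hours) and `replicate` (positive
#'   integer).
#' @return The validated design with class `tc_design`.
#' @export
tc_design <- function(df) {
  req <- c("sample_id", "treatment", "phase", "time_h", "replicate")
  if (!is.data.frame(df) || nrow(df) == 0L)
    stop("design must be a non-empty data.frame")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("design is missing columns: ", paste(miss, collapse = ", "))
  df <- df[req]
  df$sample_id <- as.character(df$sample_id)
  df$treatment <- as.character(df$treatment)
  df$phase <- as.character(df$phase)
  df$time_h <- as.numeric(df$time_h)
  df$replicate <- as.integer(df$replicate)
  bad_trt <- setdiff(unique(df$treatment), TREATMENTS)
  if (length(bad_trt))
    stop("unknown treatment label(s): ", paste(bad_trt, collapse = ", "))
  bad_ph <- setdiff(unique(df$phase), PHASES)
  if (length(bad_ph))
    stop("unknown phase label(s): ", paste(bad_ph, collapse = ", "))
  if (anyNA(df$time_h) || any(df$time_h < 0))
    stop("time_h must be non-negative and finite")
  if (anyNA(df$replicate) || any(df$replicate < 1L))
    stop("replicate must be a positive integer")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id")
  key <- paste(df$treatment, df$phase, df$time_h, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (treatment, phase, time_h, replicate) tuple")
  for (trt in unique(df$treatment)) {
    if (!any(df$treatment == trt & df$phase == "pre_heat"))
      stop("treatment ", trt, " has no pre_heat entry")
  }
  rownames(df) <- NULL
  class(df) <- c("tc_design", "data.frame")
  df
}

#' Default photobioreactor sampling grid
#'
#' The built-in time grid: one pre-heat sample, heat samples at 0, 0.5, 1,
#' 2, 4, 8, 16 and 24 h after reaching the target temperature, and recovery
#' samples at 0, 2, 4, 8, 24 and 48 h after return to 25 degC -- 15 time
#' points per treatment.
#'
#' @param treatments subset of `c("ctrl25", "heat35", "heat40")`.
#' @param replicates number of biological replicates per time point.
#' @return A [tc_design] data.frame.
#' @export
default_design <- function(treatments = TREATMENTS, replicates = 3L) {
  grid <- rbind(
    data.frame(phase = "pre_heat", time_h = 0),
    data.frame(phase = "heat", time_h = HEAT_TIMES),
    data.frame(phase = "recovery", time_h = RECOVERY_TIMES)
  )
  rows <- do.call(rbind, lapply(treatments, function(trt) {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      data.frame(
        sample_id = sprintf("%s_%s_%gh_r%d", trt, grid$phase, grid$time_h, r),
        treatment = trt, phase = grid$phase, time_h = grid$time_h,
        replicate = r, stringsAsFactors = FALSE
      )
    }))
  }))
  tc_design(rows)
}

#' Gene expression count matrix with gene lengths
#'
#' @param counts integer matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param gene_length named numeric vector of gene lengths in bp covering
#'   every gene in `counts`.
#' @return Object of class `expr_matrix` with elements `counts` and
#'   `gene_length`.
#' @export
expr_matrix <- function(counts, gene_length) {
  counts <- as.matrix(counts)
  # R stores no dimnames for zero-row matrices; only require them when
  # there is something to name
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && nrow(counts) > 0L && is.null(colnames(counts))))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids")
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  missing_len <- setdiff(rownames(counts), names(gene_length))
  if (length(missing_len))
    stop("no gene length for: ", paste(missing_len, collapse = ", "))
  gene_length <- gene_length[rownames(counts)]
  if (any(!is.finite(gene_length)) || any(gene_length <= 0))
    stop("gene lengths must be positive")
  structure(list(counts = counts, gene_length = gene_length),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Label-free proteome intensity matrix
#'
#' Intensities are strictly positive where observed; `NA` encodes a missing
#' (unquantified) cell. Protein groups identified only by shared
#' (non-proteotypic) peptides carry `proteotypic = FALSE`.
#'
#' @param intensities numeric matrix, proteins x samples, `NA` = missing.
#' @param proteotypic logical vector per protein (default all `TRUE`).
#' @return Object of class `proteome_matrix`.
#' @export
proteome_matrix <- function(intensities, proteotypic = NULL) {
  intensities <- as.matrix(intensities)
  if ((nrow(intensities) > 0L && is.null(rownames(intensities))) ||
      (ncol(intensities) > 0L && nrow(intensities) > 0L &&
         is.null(colnames(intensities))))
    stop("intensities must have protein rownames and sample colnames")
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate protein ids")
  obs <- !is.na(intensities)
  if (any(intensities[obs] <= 0))
    stop("observed intensities must be strictly positive")
  if (is.null(proteotypic)) proteotypic <- rep(TRUE, nrow(intensities))
  if (length(proteotypic) != nrow(intensities))
    stop("proteotypic flag length mismatch")
  names(proteotypic) <- rownames(intensities)
  structure(list(intensities = intensities, proteotypic = proteotypic),
            class = "proteome_matrix")
}

#' @export
print.proteome_matrix <- function(x, ...) {
  cat("proteome_matrix:", nrow(x$intensities), "proteins x",
      ncol(x$intensities), "samples;",
      sprintf("%.1f%%", 100 * mean(is.na(x$intensities))), "missing\n")
  invisible(x)
}

#' Missingness mask of a proteome matrix
#' @param pm a [proteome_matrix].
#' @return Logical matrix, `TRUE` where observed.
#' @export
missing_mask <- function(pm) !is.na(pm$intensities)

#' Functional ontology annotation (MapMan-bin style)
#'
#' A term forest (each term has at most one parent) plus entity-to-term
#' assignments. Tree expansion -- counting an entity at every ancestor of
#' its assigned terms -- is done by [expand_annotation()].
#'
#' @param terms data.frame with columns `term_id`, `name`, `parent`
#'   (`NA` for roots).
#' @param assignments named list: entity id -> character vector of term ids.
#' @return Object of class `ontology_annotation`.
#' @export
ontology_annotation <- function(terms, assignments) {
  stopifnot(all(c("term_id", "name", "parent") %in% names(terms)))
  terms$term_id <- as.character(terms$term_id)
  terms$parent <- as.character(terms$parent)
  if (anyDuplicated(terms$term_id)) stop("duplicate term ids")
  known <- terms$term_id
  bad_parent <- setdiff(terms$parent[!is.na(terms$parent)], known)
  if (length(bad_parent))
    stop("parent term(s) not in tree: ", paste(bad_parent, collapse = ", "))
  # forest check: walking up from any term must terminate
  parent_of <- stats::setNames(terms$parent, terms$term_id)
  for (t in known) {
    seen <- character(0)
    cur <- t
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cycle in term tree at ", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  assignments <- lapply(assignments, as.character)
  bad <- setdiff(unique(unlist(assignments)), known)
  if (length(bad))
    stop("assigned term(s) absent from tree: ", paste(bad, collapse = ", "))
  structure(list(terms = terms, assignments = assignments),
            class = "ontology_annotation")
}

#' Expand assignments to all ancestor terms
#'
#' Each entity is counted once at every term on the path from each assigned
#' term up to its root, so enrichment at a parent term sees every entity
#' annotated anywhere below it.
#'
#' @param onto an [ontology_annotation].
#' @return Named list: entity id -> character vector of term ids (expanded,
#'   de-duplicated per entity).
#' @export
expand_annotation <- function(onto) {
  parent_of <- stats::setNames(onto$terms$parent, onto$terms$term_id)
  ancestors <- function(t) {
    out <- character(0)
    cur <- t
    while (!is.na(cur)) {
      out <- c(out, cur)
      cur <- parent_of[[cur]]
    }
    out
  }
  anc_cache <- lapply(stats::setNames(onto$terms$term_id, onto$terms$term_id),
                      ancestors)
  lapply(onto$assignments, function(tt)
    unique(unlist(anc_cache[tt], use.names = FALSE)))
}

#' Instrument kinetic trace
#'
#' @param kind one of `od680`, `fluorescence`, `ecs`, `p700`, `o2`,
#'   `spectrum77k`, `facs_hist`.
#' @param x strictly increasing abscissa (seconds, hours, nm, or
#'   log-fluorescence bin centers depending on `kind`).
#' @param y signal (arbitrary units or counts).
#' @param meta named list of metadata (e.g. actinic light intensity in
#'   umol photons m-2 s-1, simulation parameters).
#' @return Object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(kind, x, y, meta = list()) {
  kind <- match.arg(kind, TRACE_KINDS)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2L) stop("trace needs at least two points")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  structure(list(kind = kind, x = x, y = y, meta = meta),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat("kinetic_trace [", x$kind, "]: ", length(x$x), " points, x in [",
      format(min(x$x)), ", ", format(max(x$x)), "]\n", sep = "")
  invisible(x)
}
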