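# Readers/writers. All tables are TSV with header, UTF-8, '.' decimal;
# proteome missing values are empty cells (MaxQuant-export compatible).

#' Read a count matrix with gene lengths
#'
#' @param path TSV: first column gene ids, remaining columns one integer
#'   count column per sample.
#' @param lengths path to either a two-column TSV (`gene_id`, `length_bp`)
#'   or a GFF3 file; gene length is the union of exon intervals.
#' @return An [expr_matrix].
#' @export
read_counts <- function(path, lengths) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts file needs a gene column plus samples")
  gene_ids <- as.character(df[[1L]])
  m <- as.matrix(df[-1L])
  if (!is.numeric(m)) stop("non-numeric count cell(s) in ", path)
  frac <- which(m != floor(m), arr.ind = TRUE)
  if (nrow(frac)) {
    stop(sprintf("non-integer count %s at gene %s, sample %s",
                 format(m[frac[1L, , drop = FALSE]]),
                 gene_ids[frac[1L, 1L]], colnames(m)[frac[1L, 2L]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  len <- read_gene_lengths(lengths)
  expr_matrix(m, len)
}

#' Read gene lengths from TSV or GFF3
#'
#' For GFF3 input the length of a gene is the number of bases covered by
#' the union of its exons (GFF3 coordinates are 1-based inclusive).
#'
#' @param path file ending in `.gff`/`.gff3` (exon union) or a TSV with
#'   columns `gene_id` and `length_bp`.
#' @return Named numeric vector of lengths in bp.
#' @export
read_gene_lengths <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE))
    return(gene_lengths_from_gff3(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(df)))
    stop("length table needs columns gene_id, length_bp")
  stats::setNames(as.numeric(df$length_bp), as.character(df$gene_id))
}

gene_lengths_from_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  types <- tolower(as.character(gr$type))
  ex <- gr[types == "exon"]
  if (length(ex) == 0L) stop("no exon features in ", path)
  # transcript -> gene map so exon Parent=mRNA resolves to the gene
  tx <- gr[types %in% c("mrna", "transcript")]
  tx2gene <- character(0)
  if (length(tx)) {
    tx_par <- vapply(as.list(tx$Parent), function(p)
      if (length(p)) p[[1L]] else NA_character_, character(1))
    tx2gene <- stats::setNames(tx_par, as.character(tx$ID))
  }
  mc <- S4Vectors::mcols(ex)
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else
    rep(NA_character_, length(ex))
  par <- vapply(as.list(mc$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1))
  fallback <- !is.na(par) & par %in% names(tx2gene)
  gid[is.na(gid) & fallback] <- tx2gene[par[is.na(gid) & fallback]]
  gid[is.na(gid)] <- par[is.na(gid)]
  if (anyNA(gid)) stop("exon without gene_id/Parent attribute in ", path)
  gid <- sub("^gene:", "", gid)
  by_gene <- split(ex, gid)
  vapply(by_gene, function(g)
    sum(BiocGenerics::width(GenomicRanges::reduce(g, ignore.strand = TRUE))),
    numeric(1))
}

#' Write a count matrix (and its length table)
#' @param em an [expr_matrix].
#' @param path output TSV for counts.
#' @param lengths_path optional output TSV for gene lengths.
#' @export
write_counts <- function(em, path, lengths_path = NULL) {
  df <- data.frame(gene_id = rownames(em$counts), em$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(lengths_path)) {
    utils::write.table(
      data.frame(gene_id = names(em$gene_length), length_bp = em$gene_length),
      lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a sample design table
#' @param path TSV with columns `sample_id`, `treatment`, `phase`,
#'   `time_h`, `replicate`.
#' @return A [tc_design].
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty design file: ", path)
  tc_design(df)
}

#' Write a sample design table
#' @param design a [tc_design]; @param path output TSV.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a label-free proteome intensity matrix
#'
#' MaxQuant-style export: a protein id column plus one intensity column per
#' sample; `0` or an empty cell encodes a missing value. An optional
#' logical `proteotypic` column flags groups quantified only by shared
#' peptides.
#'
#' @param path TSV file.
#' @return A [proteome_matrix].
#' @export
read_proteome <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  proteo <- NULL
  if ("proteotypic" %in% names(df)) {
    proteo <- as.logical(df$proteotypic)
    df$proteotypic <- NULL
  }
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "double"
  m[!is.na(m) & m == 0] <- NA_real_
  rownames(m) <- ids
  proteome_matrix(m, proteo)
}

#' Write a proteome matrix (missing cells written empty)
#' @param pm a [proteome_matrix]; @param path output TSV.
#' @export
write_proteome <- function(pm, path) {
  df <- data.frame(protein_id = rownames(pm$intensities), pm$intensities,
                   proteotypic = pm$proteotypic, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an ontology annotation
#' @param terms_path TSV with columns `term_id`, `name`, `parent` (empty =
#'   root).
#' @param assignments_path TSV with columns `entity_id`, `term_id`.
#' @return An [ontology_annotation].
#' @export
read_ontology <- function(terms_path, assignments_path) {
  terms <- utils::read.delim(terms_path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
  asg <- utils::read.delim(assignments_path, stringsAsFactors = FALSE)
  assignments <- split(as.character(asg$term_id), as.character(asg$entity_id))
  ontology_annotation(terms, assignments)
}

#' Write an ontology annotation
#' @param onto an [ontology_annotation].
#' @param terms_path,assignments_path output TSVs.
#' @export
write_ontology <- function(onto, terms_path, assignments_path) {
  utils::write.table(onto$terms, terms_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  asg <- data.frame(
    entity_id = rep(names(onto$assignments),
                    lengths(onto$assignments)),
    term_id = unlist(onto$assignments, use.names = FALSE))
  utils::write.table(asg, assignments_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(terms_path)
}

#' Read an instrument trace from two-column CSV
#' @param path CSV with header `x,y` (or any two columns in that order).
#' @param kind trace kind, see [kinetic_trace()].
#' @param meta optional metadata list.
#' @return A [kinetic_trace].
#' @export
read_trace <- function(path, kind, meta = list()) {
  df <- utils::read.csv(path)
  kinetic_trace(kind, df[[1L]], df[[2L]], meta)
}

#' Write an instrument trace as two-column CSV
#' @param trace a [kinetic_trace]; @param path output CSV.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(x = trace$x, y = trace$y), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
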