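#' @title GO term over-representation
#' @description Classic per-term over-representation of a study gene set
#'   against a background, by exact upper-tail hypergeometric test with
#'   Benjamini-Hochberg FDR across tested terms. Annotations are taken as
#'   given (no DAG propagation to ancestors; pre-propagated annotations are
#'   accepted through the same interface).
#' @name enrichment
NULL

#' Read a gene-to-GO annotation table
#'
#' Two tab-separated columns per line: `gene_id` and `GO:NNNNNNN`.
#' Duplicate pairs are collapsed.
#'
#' @param path path to the TSV (no header).
#' @return data.frame `gene_id`, `go_id`.
#' @export
read_gene2go <- function(path) {
  x <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                         col.names = c("gene_id", "go_id"),
                         stringsAsFactors = FALSE)
  bad <- !grepl("^GO:\\d{7}$", x$go_id)
  if (any(bad)) {
    stop(sprintf("malformed GO id '%s'", x$go_id[which(bad)[1L]]),
         call. = FALSE)
  }
  unique(x)
}

#' Hypergeometric GO term enrichment
#'
#' For each term with at least `min_term_size` annotated background genes,
#' the upper-tail probability of observing at least the study's hit count
#' under a hypergeometric draw of `n = |study|` from `N = |background|`
#' genes of which `K` carry the term, followed by Benjamini-Hochberg
#' adjustment across tested terms.
#'
#' @param study_genes character vector of study gene ids (must be a subset
#'   of the background).
#' @param background_genes character vector of background gene ids; defaults
#'   to all annotated genes.
#' @param annotation data.frame `gene_id`, `go_id` ([read_gene2go()]).
#' @param min_term_size smallest term (background genes) tested (default 3).
#' @return data.frame `term`, `study_count`, `background_count`, `p`,
#'   `fdr`, sorted by `p` then `term`.
#' @export
enrich_go <- function(study_genes, background_genes = NULL, annotation,
                      min_term_size = 3L) {
  stopifnot(all(c("gene_id", "go_id") %in% names(annotation)))
  if (is.null(background_genes)) {
    background_genes <- sort(unique(annotation$gene_id))
  }
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  outside <- setdiff(study_genes, background_genes)
  if (length(outside) > 0L) {
    stop(sprintf("study genes not in background: %s",
                 paste(utils::head(outside, 5L), collapse = ", ")),
         call. = FALSE)
  }
  ann <- annotation[annotation$gene_id %in% background_genes, , drop = FALSE]
  N <- length(background_genes)
  n <- length(study_genes)
  terms <- sort(unique(ann$go_id))
  rows <- list()
  for (term in terms) {
    genes <- unique(ann$gene_id[ann$go_id == term])
    K <- length(genes)
    if (K < min_term_size) next
    x <- length(intersect(genes, study_genes))
    p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      term = term, study_count = x, background_count = K, p = p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(term = character(), study_count = integer(),
                      background_count = integer(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
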