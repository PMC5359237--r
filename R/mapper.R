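#' @title Exhaustive k-mismatch tag alignment
#' @description Deterministic, exhaustive Hamming-distance placement of short
#'   tags on small reference sets (pre-miRNA hairpins, genome windows). Every
#'   placement within the mismatch budget is enumerated, so results are a
#'   total order and reruns are byte-identical. Hairpins are scanned on the
#'   forward strand only (mature miRNAs are annotated on the hairpin sense
#'   strand); genome and contaminant screens consider both strands.
#' @name mapper
NULL

.empty_alignments <- function() {
  out <- data.frame(hairpin_id = character(), start = integer(),
                    end = integer(), n_mismatch = integer(),
                    tail5 = character(), tail3 = character(),
                    stringsAsFactors = FALSE)
  out$mismatch_positions <- list()
  out[, c("hairpin_id", "start", "end", "n_mismatch", "mismatch_positions",
          "tail5", "tail3")]
}

#' Align a tag to references at every offset within a mismatch budget
#'
#' Enumerates all placements of `tag_seq` on each reference (forward strand)
#' with Hamming distance at most `max_mismatch`. `N` never matches.
#'
#' @param tag_seq a single nucleotide string.
#' @param references named character vector of reference sequences.
#' @param max_mismatch maximum Hamming distance (>= 0).
#' @return an alignment table: `hairpin_id`, `start`, `end` (0-based
#'   half-open reference interval), `n_mismatch`, `mismatch_positions`
#'   (list-column of 0-based offsets within the tag), `tail5`, `tail3`
#'   (empty here; filled by the trim-and-remap step). Rows are ordered by
#'   (`n_mismatch`, `hairpin_id`, `start`) ascending.
#' @export
map_tag <- function(tag_seq, references, max_mismatch = 0L) {
  if (length(references) == 0L) {
    stop("empty reference set", call. = FALSE)
  }
  stopifnot(length(tag_seq) == 1L, nzchar(tag_seq), max_mismatch >= 0L)
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    stop("references must be named", call. = FALSE)
  }
  l <- nchar(tag_seq)
  tc <- strsplit(tag_seq, "", fixed = TRUE)[[1]]
  pieces <- vector("list", length(references))
  ids <- sort(names(references))
  for (h in seq_along(ids)) {
    rid <- ids[h]
    ref <- references[[rid]]
    L <- nchar(ref)
    if (L < l) next
    rc <- strsplit(ref, "", fixed = TRUE)[[1]]
    w <- L - l + 1L
    mm <- integer(w)
    for (p in seq_len(l)) {
      mm <- mm + (rc[p:(p + w - 1L)] != tc[p])
    }
    hits <- which(mm <= max_mismatch)
    if (length(hits) == 0L) next
    mp <- lapply(hits, function(s) which(rc[s:(s + l - 1L)] != tc) - 1L)
    piece <- data.frame(hairpin_id = rid, start = hits - 1L,
                        end = hits - 1L + l, n_mismatch = mm[hits],
                        tail5 = "", tail3 = "", stringsAsFactors = FALSE)
    piece$mismatch_positions <- mp
    pieces[[h]] <- piece
  }
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0L) return(.empty_alignments())
  out <- do.call(rbind, pieces)
  out <- out[order(out$n_mismatch, out$hairpin_id, out$start), ]
  rownames(out) <- NULL
  out[, c("hairpin_id", "start", "end", "n_mismatch", "mismatch_positions",
          "tail5", "tail3")]
}

# Total end-drift magnitude of an alignment (tails counted as extensions)
# relative to the nearest annotated mature on its hairpin; large sentinel if
# the hairpin has no annotation.
.drift_magnitude <- function(aln, annotations) {
  vapply(seq_len(nrow(aln)), function(i) {
    ann <- annotations[annotations$hairpin_id == aln$hairpin_id[i], , drop = FALSE]
    if (nrow(ann) == 0L) return(.Machine$integer.max / 2)
    s <- aln$start[i] - nchar(aln$tail5[i])
    e <- aln$end[i] + nchar(aln$tail3[i])
    min(abs(ann$start - s) + abs(e - ann$end))
  }, 0)
}

#' Select the best hits among the alignments of one tag
#'
#' Keeps every alignment achieving the minimum of (mismatch count, total
#' end-drift magnitude relative to the nearest annotated mature miRNA when
#' annotations are supplied, total tail length); within one hairpin ties are
#' broken by the smallest start, so at most one alignment per hairpin
#' survives. If the survivors span more than one hairpin the result carries
#' `attr(, "multi_hairpin") = TRUE` (feeds the "complex" class).
#'
#' @param alignments alignment table of a single tag ([map_tag()] output).
#' @param annotations optional mature annotation table (`mature_id`,
#'   `hairpin_id`, `start`, `end`).
#' @return the surviving alignments, one row per hairpin, ordered by
#'   `hairpin_id`; `multi_hairpin` attribute set accordingly.
#' @export
best_hits <- function(alignments, annotations = NULL) {
  if (nrow(alignments) == 0L) {
    out <- .empty_alignments()
    attr(out, "multi_hairpin") <- FALSE
    return(out)
  }
  key_mm <- alignments$n_mismatch
  key_drift <- if (!is.null(annotations)) {
    .drift_magnitude(alignments, annotations)
  } else {
    rep(0, nrow(alignments))
  }
  key_tail <- nchar(alignments$tail5) + nchar(alignments$tail3)
  keep <- key_mm == min(key_mm)
  keep <- keep & key_drift == min(key_drift[keep])
  keep <- keep & key_tail == min(key_tail[keep])
  surv <- alignments[keep, , drop = FALSE]
  surv <- surv[order(surv$hairpin_id, surv$start), , drop = FALSE]
  surv <- surv[!duplicated(surv$hairpin_id), , drop = FALSE]
  rownames(surv) <- NULL
  attr(surv, "multi_hairpin") <- length(unique(surv$hairpin_id)) > 1L
  surv
}

#' Exact substring membership of tags in a sequence set (both strands)
#'
#' @param seqs character vector of tag sequences.
#' @param subjects named character vector of subject sequences.
#' @return logical vector: `TRUE` where the tag occurs exactly as a substring
#'   of any subject, forward or reverse complement.
#' @keywords internal
matches_exactly <- function(seqs, subjects) {
  if (length(subjects) == 0L || length(seqs) == 0L) {
    return(rep(FALSE, length(seqs)))
  }
  subj <- Biostrings::DNAStringSet(subjects)
  vapply(seqs, function(s) {
    p <- Biostrings::DNAString(s)
    fwd <- sum(Biostrings::vcountPattern(p, subj)) > 0L
    if (fwd) return(TRUE)
    sum(Biostrings::vcountPattern(Biostrings::reverseComplement(p), subj)) > 0L
  }, TRUE, USE.NAMES = FALSE)
}

#' Screen hairpin-unmapped tags against a genome
#'
#' Applies only to tags that failed 0-mismatch hairpin mapping: a tag is
#' filtered out iff it matches the genome exactly (substring, either
#' strand); filtered tags never enter non-templated detection, which lowers
#' the non-templated false positive rate.
#'
#' @param tags a tag table.
#' @param genome named character vector of genome/transcriptome sequences,
#'   or `NULL` (no-op with a warning: all tags retained).
#' @return list with elements `retained` and `filtered` (tag tables).
#' @export
genome_filter <- function(tags, genome = NULL) {
  if (is.null(genome) || length(genome) == 0L) {
    warning("no genome supplied; all ", nrow(tags), " tags retained",
            call. = FALSE)
    return(list(retained = tags, filtered = tags[0, , drop = FALSE]))
  }
  hit <- matches_exactly(tags$seq, genome)
  list(retained = tags[!hit, , drop = FALSE],
       filtered = tags[hit, , drop = FALSE])
}
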