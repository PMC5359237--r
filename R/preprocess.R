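#' @title Read preprocessing
#' @description Turns raw small RNA-seq reads into length-filtered,
#'   contaminant-free, collapsed tags. Adapter location uses a transparent
#'   deterministic rule (best Hamming match over candidate overlaps) rather
#'   than a heuristic local aligner, so results are exactly reproducible.
#'   Every input read is accounted for in exactly one of five partitions:
#'   adapter-rejected, N-rejected, length-rejected, contaminant, survivor.
#' @name preprocess
NULL

#' Preprocessing configuration
#'
#' @param adapter3 3' adapter sequence ("" = none).
#' @param adapter5 5' adapter sequence ("" = none).
#' @param min_len,max_len length bounds kept after trimming (defaults 18-26,
#'   the usual plant small-RNA window).
#' @param min_count minimum total read support per tag (default 1).
#' @param min_adapter_overlap minimum adapter overlap considered (default 6).
#' @param max_adapter_mismatch_rate maximum fraction of mismatching bases in
#'   the adapter overlap (default 0.1).
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(adapter3 = "", adapter5 = "", min_len = 18L,
                              max_len = 26L, min_count = 1L,
                              min_adapter_overlap = 6L,
                              max_adapter_mismatch_rate = 0.1) {
  stopifnot(min_len > 0L, min_len <= max_len, min_count >= 1L,
            min_adapter_overlap >= 1L, max_adapter_mismatch_rate >= 0)
  structure(list(adapter3 = normalize_seq(adapter3),
                 adapter5 = normalize_seq(adapter5),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_count = as.integer(min_count),
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 max_adapter_mismatch_rate = max_adapter_mismatch_rate),
            class = "preprocess_config")
}

.hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Best 3' adapter match: for each start s the adapter prefix of length
# overlap = min(|adapter|, |read| - s + 1) is compared; candidates need
# overlap >= min_overlap and rate <= max_rate; lowest rate, then longest
# overlap, then leftmost start wins. Returns the match start or NA.
.find_adapter3 <- function(seq, adapter, cfg) {
  n <- nchar(seq)
  la <- nchar(adapter)
  starts <- integer()
  rates <- numeric()
  overlaps <- integer()
  for (s in seq_len(n)) {
    o <- min(la, n - s + 1L)
    if (o < cfg$min_adapter_overlap) break
    mm <- .hamming(substr(seq, s, s + o - 1L), substr(adapter, 1L, o))
    rate <- mm / o
    if (rate > cfg$max_adapter_mismatch_rate) next
    starts <- c(starts, s)
    rates <- c(rates, rate)
    overlaps <- c(overlaps, o)
  }
  if (length(starts) == 0L) return(NA_integer_)
  starts[order(rates, -overlaps, starts)[1L]]
}

# Best 5' adapter match: an adapter suffix of length o aligned at the read
# start; longest acceptable overlap wins (lowest rate first).
.find_adapter5 <- function(seq, adapter, cfg) {
  n <- nchar(seq)
  la <- nchar(adapter)
  best_o <- NA_integer_
  best_rate <- Inf
  if (min(la, n) < cfg$min_adapter_overlap) return(best_o)
  for (o in seq(min(la, n), cfg$min_adapter_overlap)) {
    mm <- .hamming(substr(seq, 1L, o), substr(adapter, la - o + 1L, la))
    rate <- mm / o
    if (rate <= cfg$max_adapter_mismatch_rate &&
        (rate < best_rate || (rate == best_rate && is.na(best_o)))) {
      best_rate <- rate
      best_o <- o
    }
  }
  best_o
}

#' Trim 5'/3' adapters from a single read
#'
#' The 3' adapter is located as the best prefix-of-adapter match starting at
#' any read position (overlap >= `min_adapter_overlap`, mismatch rate <=
#' `max_adapter_mismatch_rate`); everything from the match start onward is
#' removed. Symmetrically, a 5' adapter is located as a suffix-of-adapter at
#' the read start. A read with no match passes unchanged; a read whose
#' insert is empty after removal is rejected.
#'
#' @param read_seq a single read sequence.
#' @param config a [preprocess_config()].
#' @return the trimmed insert, or `NA_character_` if rejected.
#' @export
trim_adapters <- function(read_seq, config) {
  stopifnot(length(read_seq) == 1L, nzchar(read_seq))
  seq <- normalize_seq(read_seq)
  if (nzchar(config$adapter3)) {
    s <- .find_adapter3(seq, config$adapter3, config)
    if (!is.na(s)) seq <- substr(seq, 1L, s - 1L)
  }
  if (nzchar(seq) && nzchar(config$adapter5)) {
    o <- .find_adapter5(seq, config$adapter5, config)
    if (!is.na(o)) seq <- substr(seq, o + 1L, nchar(seq))
  }
  if (!nzchar(seq)) NA_character_ else seq
}

#' Collapse reads into unique tags
#'
#' @param reads character vector of trimmed, length-filtered read sequences.
#' @param sample sample name for the count column.
#' @return a tag table (`tag_id`, `seq`, one count column named `sample`);
#'   tag ids are assigned deterministically in descending count then
#'   lexicographic sequence order. The counts sum to `length(reads)`.
#' @export
collapse_reads <- function(reads, sample) {
  if (length(reads) == 0L) {
    out <- data.frame(tag_id = character(), seq = character(),
                      stringsAsFactors = FALSE)
    out[[sample]] <- integer()
    return(out)
  }
  tab <- table(reads)
  seqs <- names(tab)
  counts <- as.integer(tab)
  ord <- order(-counts, seqs)
  out <- data.frame(tag_id = sprintf("t%06d", seq_along(ord)),
                    seq = seqs[ord], stringsAsFactors = FALSE)
  out[[sample]] <- counts[ord]
  out
}

#' Remove tags originating from other non-coding RNAs
#'
#' A tag is removed iff it occurs as an exact substring (forward or reverse
#' complement) of any contaminant sequence (rRNA/tRNA/snoRNA-style
#' references). Exact matching is deliberately conservative.
#'
#' @param tags a tag table.
#' @param contaminants named character vector of contaminant sequences, or
#'   `NULL`/empty (no-op with a warning).
#' @return list with `kept` and `removed` tag tables (a disjoint partition
#'   of the input).
#' @export
filter_contaminants <- function(tags, contaminants = NULL) {
  if (is.null(contaminants) || length(contaminants) == 0L) {
    warning("no contaminant reference supplied; all tags kept", call. = FALSE)
    return(list(kept = tags, removed = tags[0, , drop = FALSE]))
  }
  hit <- matches_exactly(tags$seq, contaminants)
  list(kept = tags[!hit, , drop = FALSE],
       removed = tags[hit, , drop = FALSE])
}

#' Full preprocessing stage: trim, filter, collapse, decontaminate
#'
#' @param reads character vector of raw read sequences.
#' @param sample sample name.
#' @param config a [preprocess_config()].
#' @param contaminants optional named character vector of contaminant
#'   sequences.
#' @return list with `tags` (surviving tag table) and `log`, a data.frame of
#'   the five partition counts (`adapter_rejected`, `n_rejected`,
#'   `length_rejected`, `contaminant`, `survivor`) plus `input`; the five
#'   partitions sum to `input`.
#' @export
preprocess_reads <- function(reads, sample, config = preprocess_config(),
                             contaminants = NULL) {
  n_input <- length(reads)
  trimmed <- vapply(reads, function(r) trim_adapters(r, config), "",
                    USE.NAMES = FALSE)
  adapter_rejected <- sum(is.na(trimmed))
  trimmed <- trimmed[!is.na(trimmed)]
  has_n <- grepl("N", trimmed, fixed = TRUE)
  n_rejected <- sum(has_n)
  trimmed <- trimmed[!has_n]
  len <- nchar(trimmed)
  in_range <- len >= config$min_len & len <= config$max_len
  length_rejected <- sum(!in_range)
  trimmed <- trimmed[in_range]
  tags <- collapse_reads(trimmed, sample)
  if (!is.null(contaminants) && length(contaminants) > 0L) {
    part <- filter_contaminants(tags, contaminants)
  } else {
    part <- list(kept = tags, removed = tags[0, , drop = FALSE])
  }
  contaminant <- if (nrow(part$removed)) sum(part$removed[[sample]]) else 0L
  kept <- part$kept[part$kept[[sample]] >= config$min_count, , drop = FALSE]
  rownames(kept) <- NULL
  survivor <- if (nrow(kept)) sum(kept[[sample]]) else 0L
  low_support <- length(trimmed) - contaminant - survivor
  log <- data.frame(
    input = n_input, adapter_rejected = adapter_rejected,
    n_rejected = n_rejected, length_rejected = length_rejected,
    contaminant = as.integer(contaminant),
    low_support = as.integer(low_support),
    survivor = as.integer(survivor)
  )
  list(tags = kept, log = log)
}

#' Merge per-sample tag tables into one multi-sample tag table
#'
#' Tags are matched by sequence; missing counts are zero. Ids are reassigned
#' in descending total count then lexicographic sequence order.
#'
#' @param tag_sets list of tag tables, one per sample (each with exactly one
#'   count column).
#' @return a tag table with one count column per sample.
#' @export
merge_tag_sets <- function(tag_sets) {
  stopifnot(length(tag_sets) >= 1L)
  samples <- vapply(tag_sets, function(t) setdiff(names(t), c("tag_id", "seq")), "")
  if (anyDuplicated(samples)) stop("duplicate sample names", call. = FALSE)
  seqs <- sort(unique(unlist(lapply(tag_sets, `[[`, "seq"))))
  out <- data.frame(seq = seqs, stringsAsFactors = FALSE)
  for (i in seq_along(tag_sets)) {
    m <- match(seqs, tag_sets[[i]]$seq)
    cnt <- tag_sets[[i]][[samples[i]]][m]
    cnt[is.na(cnt)] <- 0L
    out[[samples[i]]] <- as.integer(cnt)
  }
  total <- rowSums(as.matrix(out[, samples, drop = FALSE]))
  ord <- order(-total, out$seq)
  out <- out[ord, , drop = FALSE]
  out <- cbind(data.frame(tag_id = sprintf("t%06d", seq_len(nrow(out))),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
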