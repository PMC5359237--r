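#' @title isomiR detection engine
#' @description The central two-phase detection procedure. Phase one maps
#'   tags to hairpins with zero mismatches and classifies templated isomiRs
#'   by end drift against the annotated canonical miRNA. Tags that fail are
#'   screened against the genome (exact matches are discarded as likely
#'   templated loci elsewhere), then enter non-templated detection: first
#'   mismatch-tolerant remapping with substitution-class checks, then
#'   recursive end trimming to recover non-templated tails. Every tag ends
#'   in exactly one fate.
#' @name detection
NULL

.tag_fates <- c("exact_canonical", "templated_isomiR", "nontemplated_isomiR",
                "genome_filtered", "unclassifiable")

#' Resolve mature miRNAs to their hairpins of origin
#'
#' Each mature sequence is located on the hairpins by exact substring
#' search. When a mature occurs on several hairpins, identifier affinity
#' (case-insensitive, with the conventional miR/MIR equivalence) selects
#' among them when possible; otherwise every occurrence is annotated.
#'
#' @param hairpins named character vector of hairpin sequences.
#' @param matures named character vector of mature sequences.
#' @return annotation table: `mature_id`, `hairpin_id`, `start`, `end`
#'   (0-based half-open interval on the hairpin), `seq`.
#' @export
resolve_annotations <- function(hairpins, matures) {
  rows <- list()
  for (mid in names(matures)) {
    mseq <- matures[[mid]]
    found <- list()
    for (hid in names(hairpins)) {
      hit <- gregexpr(mseq, hairpins[[hid]], fixed = TRUE)[[1]]
      if (hit[1L] == -1L) next
      for (s in hit) {
        found[[length(found) + 1L]] <- data.frame(
          mature_id = mid, hairpin_id = hid, start = s - 1L,
          end = s - 1L + nchar(mseq), seq = mseq, stringsAsFactors = FALSE)
      }
    }
    if (length(found) == 0L) {
      warning(sprintf("mature '%s' not found on any hairpin", mid),
              call. = FALSE)
      next
    }
    found <- do.call(rbind, found)
    if (nrow(found) > 1L) {
      key <- function(x) gsub("[^a-z0-9]", "", tolower(x))
      aff <- startsWith(key(mid), key(found$hairpin_id)) |
        startsWith(key(found$hairpin_id), key(mid))
      if (any(aff)) found <- found[aff, , drop = FALSE]
    }
    rows[[length(rows) + 1L]] <- found
  }
  if (length(rows) == 0L) {
    return(data.frame(mature_id = character(), hairpin_id = character(),
                      start = integer(), end = integer(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Assemble one record row (internal representation; 0-based half-open).
.make_record <- function(tag_id, seq, hairpin_id, mature_id, start, end,
                         templated, canonical_class, drift5, drift3,
                         drift_cat, substitution_class, mismatch_positions,
                         tail5, tail3, seed_corrupt, complex_group) {
  out <- data.frame(tag_id = tag_id, seq = seq, hairpin_id = hairpin_id,
                    mature_id = mature_id, start = start, end = end,
                    templated = templated, canonical_class = canonical_class,
                    drift5 = drift5, drift3 = drift3,
                    drift_category = drift_cat,
                    substitution_class = substitution_class,
                    tail5 = tail5, tail3 = tail3, seed_corrupt = seed_corrupt,
                    complex_group = complex_group, stringsAsFactors = FALSE)
  out$mismatch_positions <- list(as.integer(mismatch_positions))
  out[, .internal_record_cols]
}

.empty_records <- function() {
  out <- .make_record("x", "A", "h", NA_character_, 0L, 1L, TRUE, "canonical",
                      0L, 0L, "no_drift", "none", integer(), "", "", FALSE,
                      NA_character_)
  out[0, , drop = FALSE]
}

# Non-templated detection for one tag that failed 0-mismatch hairpin
# mapping and survived the genome screen. Returns list(status, rows) where
# rows is a list of per-hairpin record fragments.
.detect_nontemplated_one <- function(tag_seq, hairpins, annotations, config) {
  l <- nchar(tag_seq)
  # Step 1: mismatch-tolerant remapping. The raw mapper budget is the sum of
  # the internal cap and both terminal-run caps; the classifier enforces the
  # per-category caps on the winning placement.
  k1 <- config$max_internal_snps + 2L * config$max_terminal_subs
  aln <- map_tag(tag_seq, hairpins, k1)
  if (nrow(aln) > 0L) {
    bh <- best_hits(aln, annotations)
    frags <- list()
    for (i in seq_len(nrow(bh))) {
      cls <- classify_substitutions(bh$mismatch_positions[[i]], l, config)
      if (!cls$ok) next
      anchor <- .anchor_to_mature(bh$hairpin_id[i], bh$start[i], bh$end[i],
                                  "", "", annotations, config)
      if (is.null(anchor)) next
      frags[[length(frags) + 1L]] <- list(
        hairpin_id = bh$hairpin_id[i], start = bh$start[i], end = bh$end[i],
        anchor = anchor, class = cls$class,
        mismatch_positions = bh$mismatch_positions[[i]],
        tail5 = "", tail3 = "")
    }
    if (length(frags) > 0L) return(list(status = "ok", rows = frags))
  }
  # Step 2: recursive trim-and-remap. Trim pairs (i from 5', j from 3') are
  # enumerated by increasing total, smaller i first (3'-tail explanations
  # preferred); the trimmed core must map with zero mismatches and keep the
  # canonical overlap.
  for (t in seq_len(config$r_max_trim)) {
    for (i in 0:t) {
      j <- t - i
      if (l - t < config$min_len) next
      core <- substr(tag_seq, i + 1L, l - j)
      aln0 <- map_tag(core, hairpins, 0L)
      if (nrow(aln0) == 0L) next
      aln0$tail5 <- substr(tag_seq, 1L, i)
      aln0$tail3 <- substr(tag_seq, l - j + 1L, l)
      bh <- best_hits(aln0, annotations)
      frags <- list()
      for (r in seq_len(nrow(bh))) {
        anchor <- .anchor_to_mature(bh$hairpin_id[r], bh$start[r], bh$end[r],
                                    bh$tail5[r], bh$tail3[r], annotations,
                                    config)
        if (is.null(anchor)) next
        if (anchor$overlap < config$min_overlap) next
        frags[[length(frags) + 1L]] <- list(
          hairpin_id = bh$hairpin_id[r], start = bh$start[r], end = bh$end[r],
          anchor = anchor, class = "none", mismatch_positions = integer(),
          tail5 = bh$tail5[r], tail3 = bh$tail3[r])
      }
      if (length(frags) > 0L) return(list(status = "ok", rows = frags))
    }
  }
  list(status = "unclassifiable", rows = list())
}

#' Run full isomiR detection over a tag table
#'
#' Assigns every tag exactly one fate: `exact_canonical` (the canonical
#' miRNA itself), `templated_isomiR`, `nontemplated_isomiR`,
#' `genome_filtered`, or `unclassifiable`. Tags whose best hits span more
#' than one hairpin become `complex` records sharing a group id, one record
#' per hairpin, but count once in the audit.
#'
#' @param tags tag table (`tag_id`, `seq`, per-sample count columns).
#' @param hairpins named character vector of pre-miRNA sequences.
#' @param annotations annotation table from [resolve_annotations()].
#' @param genome optional named character vector used to screen tags that
#'   fail 0-mismatch hairpin mapping.
#' @param config a [detect_config()].
#' @return list with `records` (one row per (isomiR, hairpin anchor), count
#'   columns appended, `samples` attribute set), `audit` (fate counts; sums
#'   to `nrow(tags)`), and `fates` (per-tag fate table).
#' @export
run_detection <- function(tags, hairpins, annotations, genome = NULL,
                          config = detect_config()) {
  samples <- setdiff(names(tags), c("tag_id", "seq"))
  fates <- character(nrow(tags))
  rec_rows <- list()
  complex_n <- 0L
  genome_known <- !is.null(genome) && length(genome) > 0L
  for (k in seq_len(nrow(tags))) {
    tag_id <- tags$tag_id[k]
    seq <- tags$seq[k]
    aln0 <- map_tag(seq, hairpins, 0L)
    frags <- list()
    templated <- TRUE
    if (nrow(aln0) > 0L) {
      bh <- best_hits(aln0, annotations)
      statuses <- vector("list", nrow(bh))
      for (i in seq_len(nrow(bh))) {
        statuses[[i]] <- classify_templated(bh[i, , drop = FALSE],
                                            annotations, config)
      }
      keep <- vapply(statuses, function(s) s$status != "rejected", TRUE)
      if (!any(keep)) {
        fates[k] <- "unclassifiable"
        next
      }
      bh <- bh[keep, , drop = FALSE]
      statuses <- statuses[keep]
      multi <- nrow(bh) > 1L
      if (!multi && statuses[[1]]$status == "exact_canonical") {
        fates[k] <- "exact_canonical"
        next
      }
      fates[k] <- "templated_isomiR"
      for (i in seq_len(nrow(bh))) {
        frags[[i]] <- list(hairpin_id = bh$hairpin_id[i], start = bh$start[i],
                           end = bh$end[i], anchor = statuses[[i]],
                           class = "none", mismatch_positions = integer(),
                           tail5 = "", tail3 = "")
      }
    } else {
      if (genome_known && matches_exactly(seq, genome)) {
        fates[k] <- "genome_filtered"
        next
      }
      res <- .detect_nontemplated_one(seq, hairpins, annotations, config)
      if (res$status != "ok") {
        fates[k] <- "unclassifiable"
        next
      }
      fates[k] <- "nontemplated_isomiR"
      templated <- FALSE
      frags <- res$rows
    }
    multi <- length(unique(vapply(frags, `[[`, "", "hairpin_id"))) > 1L
    cgroup <- NA_character_
    if (multi) {
      complex_n <- complex_n + 1L
      cgroup <- sprintf("cg%04d", complex_n)
    }
    for (f in frags) {
      a <- f$anchor
      cclass <- if (multi) "complex" else a$canonical_class
      corrupt <- flag_seed_corrupt(seq, a$mature_seq, config)
      rec_rows[[length(rec_rows) + 1L]] <- .make_record(
        tag_id, seq, f$hairpin_id, a$mature_id, f$start, f$end,
        templated, cclass, a$drift5, a$drift3, a$category, f$class,
        f$mismatch_positions, f$tail5, f$tail3, corrupt, cgroup)
    }
  }
  records <- if (length(rec_rows) > 0L) do.call(rbind, rec_rows) else
    .empty_records()
  rownames(records) <- NULL
  m <- match(records$tag_id, tags$tag_id)
  for (s in samples) records[[s]] <- tags[[s]][m]
  attr(records, "samples") <- samples
  audit <- data.frame(fate = .tag_fates,
                      n_tags = vapply(.tag_fates,
                                      function(f) sum(fates == f), 0L),
                      stringsAsFactors = FALSE)
  rownames(audit) <- NULL
  list(records = records,
       audit = audit,
       fates = data.frame(tag_id = tags$tag_id, seq = tags$seq, fate = fates,
                          stringsAsFactors = FALSE))
}
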