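#' @title isomiR taxonomy primitives
#' @description Pure classification functions for the isomiR taxonomy:
#'   signed end-drift against the annotated canonical miRNA, substitution
#'   classes over mismatch patterns, and the seed-corruption flag. These are
#'   composed by [run_detection()].
#' @name isomir_core
NULL

#' Detection configuration
#'
#' @param max_internal_snps maximum internal mismatches in a non-templated
#'   alignment (default 1, the benchmark setting).
#' @param max_terminal_subs maximum length of a terminal mismatch run per
#'   end (default 6).
#' @param r_max_trim maximum total nucleotides trimmed across both ends in
#'   the recursive trim-and-remap step (default 3).
#' @param min_overlap minimum overlap (nt) with the canonical miRNA for the
#'   canonical class (default 16).
#' @param min_len,max_len tag length bounds (defaults 18/26).
#' @param seed_start,seed_end 1-based seed window on the mature 5' end
#'   (defaults 2 and 8).
#' @param seed_corrupt_tolerance maximum seed edits tolerated before an
#'   isomiR is flagged seed-corrupt (default 0).
#' @return a `detect_config` list.
#' @export
detect_config <- function(max_internal_snps = 1L, max_terminal_subs = 6L,
                          r_max_trim = 3L, min_overlap = 16L, min_len = 18L,
                          max_len = 26L, seed_start = 2L, seed_end = 8L,
                          seed_corrupt_tolerance = 0L) {
  stopifnot(max_internal_snps >= 0L, max_terminal_subs >= 0L,
            r_max_trim >= 0L, min_overlap >= 0L, min_len > 0L,
            min_len <= max_len, seed_start >= 1L, seed_start <= seed_end,
            seed_end <= min_len, seed_corrupt_tolerance >= 0L)
  structure(list(max_internal_snps = as.integer(max_internal_snps),
                 max_terminal_subs = as.integer(max_terminal_subs),
                 r_max_trim = as.integer(r_max_trim),
                 min_overlap = as.integer(min_overlap),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 seed_start = as.integer(seed_start),
                 seed_end = as.integer(seed_end),
                 seed_corrupt_tolerance = as.integer(seed_corrupt_tolerance)),
            class = "detect_config")
}

#' Drift category from the signed end drifts
#'
#' Pure function of the sign pair: positive drift is an end addition,
#' negative a deletion; categories `5a`, `3a`, `5d`, `3d`, their four
#' combinations, and `no_drift`.
#'
#' @param drift5,drift3 signed integers (positive = addition).
#' @return one of `"5a" "3a" "5d" "3d" "5a3a" "5a3d" "5d3a" "5d3d"
#'   "no_drift"`.
#' @export
drift_category <- function(drift5, drift3) {
  s5 <- sign(drift5)
  s3 <- sign(drift3)
  if (s5 == 0 && s3 == 0) return("no_drift")
  if (s5 > 0 && s3 == 0) return("5a")
  if (s5 < 0 && s3 == 0) return("5d")
  if (s5 == 0 && s3 > 0) return("3a")
  if (s5 == 0 && s3 < 0) return("3d")
  if (s5 > 0 && s3 > 0) return("5a3a")
  if (s5 > 0 && s3 < 0) return("5a3d")
  if (s5 < 0 && s3 > 0) return("5d3a")
  "5d3d"
}

.drift_categories_templated <- c("5a", "3a", "5d", "3d", "5a3a", "5a3d",
                                 "5d3a", "5d3d")
.drift_categories_all <- c(.drift_categories_templated, "no_drift")
.substitution_classes <- c("none", "MS", "TS", "CV", "5V", "3V", "5V3V")

# Maximal runs of consecutive integers.
.runs <- function(pos) {
  if (length(pos) == 0L) return(list())
  breaks <- c(0L, which(diff(pos) != 1L), length(pos))
  lapply(seq_len(length(breaks) - 1L), function(i) {
    pos[(breaks[i] + 1L):breaks[i + 1L]]
  })
}

#' Classify a mismatch pattern into a substitution class
#'
#' A maximal run of mismatches is 5'-terminal iff it includes core position
#' 0, 3'-terminal iff it includes the last core position; remaining
#' mismatches are internal. Classes: internal only, forming a single run of
#' adjacent positions of length >= 2 -> `TS` (tandem SNPs); internal only
#' otherwise -> `MS` (random SNPs); internal plus any terminal run -> `CV`;
#' 5'-terminal only -> `5V`; 3'-terminal only -> `3V`; both ends terminal
#' only -> `5V3V`; no mismatches -> `none`. Terminal runs longer than
#' `max_terminal_subs` or more than `max_internal_snps` internal mismatches
#' reject the pattern.
#'
#' @param mismatch_positions sorted 0-based mismatch offsets within the
#'   aligned core.
#' @param core_length length of the aligned core.
#' @param config a [detect_config()].
#' @return list with `ok` (logical) and either `class` or `reason`.
#' @export
classify_substitutions <- function(mismatch_positions, core_length, config) {
  pos <- as.integer(mismatch_positions)
  if (is.unsorted(pos, strictly = TRUE) ||
      any(pos < 0L | pos >= core_length)) {
    stop("mismatch positions must be strictly sorted within [0, core_length)",
         call. = FALSE)
  }
  if (length(pos) == 0L) return(list(ok = TRUE, class = "none"))
  runs <- .runs(pos)
  is5 <- vapply(runs, function(r) 0L %in% r, TRUE)
  is3 <- vapply(runs, function(r) (core_length - 1L) %in% r, TRUE)
  five_run <- runs[is5]
  three_run <- runs[is3 & !is5]
  internal <- unlist(runs[!is5 & !is3], use.names = FALSE)
  if (is.null(internal)) internal <- integer()
  if (length(five_run) && length(five_run[[1]]) > config$max_terminal_subs) {
    return(list(ok = FALSE, reason = "5' terminal run exceeds max_terminal_subs"))
  }
  if (length(three_run) && length(three_run[[1]]) > config$max_terminal_subs) {
    return(list(ok = FALSE, reason = "3' terminal run exceeds max_terminal_subs"))
  }
  if (length(internal) > config$max_internal_snps) {
    return(list(ok = FALSE, reason = "internal mismatches exceed max_internal_snps"))
  }
  has5 <- length(five_run) > 0L
  has3 <- length(three_run) > 0L
  hasI <- length(internal) > 0L
  cls <- if (hasI && (has5 || has3)) {
    "CV"
  } else if (hasI) {
    int_runs <- .runs(internal)
    if (length(int_runs) == 1L && length(int_runs[[1]]) >= 2L) "TS" else "MS"
  } else if (has5 && has3) {
    "5V3V"
  } else if (has5) {
    "5V"
  } else {
    "3V"
  }
  list(ok = TRUE, class = cls)
}

# Anchor an aligned interval (tails included as extensions) to the mature
# annotation with maximum overlap on its hairpin; compute drifts and the
# canonical/non-canonical call. Returns NULL if the hairpin has no
# annotation.
.anchor_to_mature <- function(hairpin_id, start, end, tail5, tail3,
                              annotations, config) {
  ann <- annotations[annotations$hairpin_id == hairpin_id, , drop = FALSE]
  if (nrow(ann) == 0L) return(NULL)
  ov <- pmax(0L, pmin(end, ann$end) - pmax(start, ann$start))
  ord <- order(-ov, ann$start, ann$mature_id)
  a <- ann[ord[1L], ]
  overlap <- ov[ord[1L]]
  eff_start <- start - nchar(tail5)
  eff_end <- end + nchar(tail3)
  drift5 <- a$start - eff_start
  drift3 <- eff_end - a$end
  list(mature_id = a$mature_id, mature_start = a$start, mature_end = a$end,
       mature_seq = a$seq, overlap = overlap,
       drift5 = as.integer(drift5), drift3 = as.integer(drift3),
       category = drift_category(drift5, drift3),
       canonical_class = if (overlap >= config$min_overlap) "canonical"
                         else "non_canonical")
}

#' Classify a perfectly mapped (templated) tag against the mature annotation
#'
#' A zero-mismatch, tail-free alignment is compared with the canonical
#' miRNA interval on its hairpin: `drift5 = mature_start - tag_start`,
#' `drift3 = tag_end - mature_end`. Zero drift on both ends is the canonical
#' miRNA itself (`exact_canonical`, excluded from isomiR tables); a hairpin
#' with no annotation rejects the tag.
#'
#' @param alignment a single-row alignment table (zero mismatches, empty
#'   tails).
#' @param annotations mature annotation table (`mature_id`, `hairpin_id`,
#'   `start`, `end`, `seq`).
#' @param config a [detect_config()].
#' @return list with `status` one of `"isomir"`, `"exact_canonical"`,
#'   `"rejected"`; for `"isomir"` also the anchor fields (`mature_id`,
#'   `drift5`, `drift3`, `category`, `canonical_class`, `overlap`).
#' @export
classify_templated <- function(alignment, annotations, config) {
  stopifnot(nrow(alignment) == 1L)
  if (alignment$n_mismatch != 0L || nzchar(alignment$tail5) ||
      nzchar(alignment$tail3)) {
    stop("classify_templated requires a zero-mismatch, tail-free alignment",
         call. = FALSE)
  }
  anchor <- .anchor_to_mature(alignment$hairpin_id, alignment$start,
                              alignment$end, "", "", annotations, config)
  if (is.null(anchor)) {
    return(list(status = "rejected", reason = "hairpin has no mature annotation"))
  }
  if (anchor$drift5 == 0L && anchor$drift3 == 0L) {
    return(c(list(status = "exact_canonical"), anchor))
  }
  c(list(status = "isomir"), anchor)
}

#' Flag an isomiR whose seed region differs from the canonical seed
#'
#' The isomiR's seed window (`seed_start..seed_end`, 1-based on its own 5'
#' end, tails included) is compared with the canonical miRNA's seed window;
#' the flag is raised iff the edit count exceeds
#' `seed_corrupt_tolerance`. A 5' addition or deletion shifts the isomiR
#' frame, so any 5' drift usually corrupts the seed; pure 3' events never
#' touch it.
#'
#' @param isomir_seq full isomiR sequence (tails included).
#' @param mature_seq canonical mature sequence.
#' @param config a [detect_config()].
#' @return logical.
#' @export
flag_seed_corrupt <- function(isomir_seq, mature_seq, config) {
  w1 <- substr(isomir_seq, config$seed_start, config$seed_end)
  w2 <- substr(mature_seq, config$seed_start, config$seed_end)
  if (nchar(w1) != nchar(w2)) return(TRUE)
  .hamming(w1, w2) > config$seed_corrupt_tolerance
}
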