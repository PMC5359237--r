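#' @title Plant miRNA target scoring and degradome evidence
#' @description Complementarity penalty scoring of miRNA/isomiR-transcript
#'   duplexes in the standard plant style: per-position penalties (mismatch
#'   1.0, G:U wobble 0.5, bulged nucleotide 1.0) doubled across query
#'   positions 2-13, at most one bulge per duplex, default cutoff 4.0.
#'   Degradome (PARE) 5'-end profiles grade each predicted cleavage site
#'   into the conventional categories 0-4.
#' @name targets
NULL

#' Target scoring configuration
#'
#' @param mismatch_penalty penalty per mismatching query position (1.0).
#' @param gu_penalty penalty per G:U wobble pair (0.5).
#' @param bulge_penalty penalty per bulged nucleotide (1.0).
#' @param core_start,core_end 1-based query positions whose penalties are
#'   doubled (2 and 13; the cleavage-critical region).
#' @param max_score hit cutoff (4.0).
#' @param max_bulges maximum bulged nucleotides per duplex (1).
#' @return a `target_config` list.
#' @export
target_config <- function(mismatch_penalty = 1.0, gu_penalty = 0.5,
                          bulge_penalty = 1.0, core_start = 2L,
                          core_end = 13L, max_score = 4.0, max_bulges = 1L) {
  structure(list(mismatch_penalty = mismatch_penalty,
                 gu_penalty = gu_penalty, bulge_penalty = bulge_penalty,
                 core_start = as.integer(core_start),
                 core_end = as.integer(core_end), max_score = max_score,
                 max_bulges = as.integer(max_bulges)),
            class = "target_config")
}

# Pair penalty between a query base and a target base (both DNA alphabet,
# read in pairing orientation): Watson-Crick 0, G:U wobble (G~T or T~G)
# gu_penalty, otherwise mismatch_penalty.
.pair_penalty <- function(q, t, cfg) {
  wc <- (q == "A" & t == "T") | (q == "T" & t == "A") |
    (q == "G" & t == "C") | (q == "C" & t == "G")
  gu <- (q == "G" & t == "T") | (q == "T" & t == "G")
  ifelse(wc, 0, ifelse(gu, cfg$gu_penalty, cfg$mismatch_penalty))
}

.pos_weight <- function(i, cfg) {
  ifelse(i >= cfg$core_start & i <= cfg$core_end, 2, 1)
}

.pair_symbol <- function(q, t, cfg) {
  p <- .pair_penalty(q, t, cfg)
  ifelse(p == 0, "|", ifelse(p == cfg$gu_penalty & p != cfg$mismatch_penalty,
                             "o", " "))
}

#' Score a miRNA-target site duplex
#'
#' The query (5'->3') is paired against the site read 3'->5'. Penalties per
#' query position: mismatch 1.0, G:U wobble 0.5, bulged nucleotide 1.0, all
#' doubled at query positions 2-13 (1-based from the query 5' end); a site
#' bulge is weighted by the query position that follows it. Sites one
#' nucleotide shorter (query bulge) or longer (site bulge) than the query
#' are aligned by exhaustively minimizing over the single bulge placement.
#'
#' @param query_seq miRNA/isomiR sequence, 5'->3'.
#' @param site_seq transcript site sequence, 5'->3' (transcript sense).
#' @param config a [target_config()].
#' @return `NULL` if the length difference exceeds the bulge budget;
#'   otherwise list with `score`, `pairing` (three-line diagram), and
#'   `pair_site_index`: for each query position the 1-based position in
#'   `site_seq` it pairs with (`NA` at a query bulge).
#' @export
score_duplex <- function(query_seq, site_seq, config = target_config()) {
  lq <- nchar(query_seq)
  ls <- nchar(site_seq)
  if (abs(ls - lq) > config$max_bulges) return(NULL)
  q <- strsplit(query_seq, "", fixed = TRUE)[[1]]
  s <- rev(strsplit(site_seq, "", fixed = TRUE)[[1]])  # 3'->5' vs query
  w <- .pos_weight(seq_len(lq), config)
  best <- NULL
  consider <- function(cand) {
    if (is.null(best) || cand$score < best$score) best <<- cand
  }
  if (ls == lq) {
    pen <- .pair_penalty(q, s, config)
    consider(list(score = sum(w * pen), qgap = NA_integer_,
                  sgap = NA_integer_))
  } else if (ls == lq - 1L) {
    # one query bulge at position b: query base b is unpaired
    for (b in seq_len(lq)) {
      sm <- append(s, "-", after = b - 1L)
      pen <- .pair_penalty(q, sm, config)
      pen[b] <- config$bulge_penalty
      consider(list(score = sum(w * pen), qgap = b, sgap = NA_integer_))
    }
  } else {
    # one site bulge: site base (3'->5' index c) is unpaired; weighted by
    # the query position at the same offset
    for (cpos in seq_len(ls)) {
      sm <- s[-cpos]
      pen <- .pair_penalty(q, sm, config)
      bw <- .pos_weight(min(cpos, lq), config)
      consider(list(score = sum(w * pen) + bw * config$bulge_penalty,
                    qgap = NA_integer_, sgap = cpos))
    }
  }
  # reconstruct the winning alignment
  qgap <- best$qgap
  sgap <- best$sgap
  if (!is.na(qgap)) {
    s_al <- append(s, "-", after = qgap - 1L)
    q_al <- q
  } else if (!is.na(sgap)) {
    q_al <- append(q, "-", after = sgap - 1L)
    s_al <- s
  } else {
    q_al <- q
    s_al <- s
  }
  n <- length(q_al)
  sym <- character(n)
  for (i in seq_len(n)) {
    sym[i] <- if (q_al[i] == "-" || s_al[i] == "-") " " else
      .pair_symbol(q_al[i], s_al[i], config)
  }
  pairing <- paste(
    paste0("5' ", paste(q_al, collapse = ""), " 3' query"),
    paste0("   ", paste(sym, collapse = "")),
    paste0("3' ", paste(s_al, collapse = ""), " 5' site"),
    sep = "\n")
  # map query positions to 1-based site positions (site in sense orientation)
  pair_site <- rep(NA_integer_, lq)
  si <- 0L
  qi <- 0L
  for (i in seq_len(n)) {
    if (s_al[i] != "-") si <- si + 1L
    if (q_al[i] != "-") {
      qi <- qi + 1L
      if (s_al[i] != "-") pair_site[qi] <- ls - si + 1L
    }
  }
  list(score = best$score, pairing = pairing, pair_site_index = pair_site)
}

# Vectorized window scan of one transcript: minimum duplex penalty for
# every window of length |query| (no bulge), |query| - 1 (one query bulge,
# minimized over the bulge position by prefix/suffix sums) and |query| + 1
# (one site bulge, likewise). Bit-identical to per-window score_duplex().
.scan_transcript <- function(q, tchars, cfg) {
  L <- length(q)
  lt <- length(tchars)
  w <- .pos_weight(seq_len(L), cfg)
  res <- list()
  # penalty row: query position i against transcript chars at window starts
  # s = 1..ns, site offset `off` (reversed-site index arithmetic)
  prow <- function(i, off, ns) .pair_penalty(q[i], tchars[seq_len(ns) + off], cfg)
  if (lt >= L) {                       # no bulge
    ns <- lt - L + 1L
    sc <- numeric(ns)
    for (i in seq_len(L)) sc <- sc + w[i] * prow(i, L - i, ns)
    res$nb <- sc
  }
  if (lt >= L - 1L && L >= 2L) {       # one query bulge (site length L-1)
    ns <- lt - L + 2L
    prefA <- matrix(0, L + 1L, ns)     # prefA[b, ] = sum_{i < b} w A[i, ]
    for (i in seq_len(L - 1L)) {
      prefA[i + 1L, ] <- prefA[i, ] + w[i] * prow(i, L - 1L - i, ns)
    }
    prefA[L + 1L, ] <- prefA[L, ]      # b = L has no i < b beyond L-1 rows... i up to L-1 only
    sufB <- matrix(0, L + 2L, ns)      # sufB[b, ] = sum_{i >= b} w B[i, ]
    for (i in L:2L) {
      sufB[i, ] <- sufB[i + 1L, ] + w[i] * prow(i, L - i, ns)
    }
    best <- rep(Inf, ns)
    for (b in seq_len(L)) {
      cand <- prefA[b, ] + w[b] * cfg$bulge_penalty + sufB[b + 1L, ]
      best <- pmin(best, cand)
    }
    res$qb <- best
  }
  if (lt >= L + 1L) {                  # one site bulge (site length L+1)
    ns <- lt - L
    prefC <- matrix(0, L + 2L, ns)     # prefC[c, ] = sum_{i < c} w C[i, ]
    for (i in seq_len(L)) {
      prefC[i + 1L, ] <- prefC[i, ] + w[i] * prow(i, L + 1L - i, ns)
    }
    prefC[L + 2L, ] <- prefC[L + 1L, ]
    sufD <- matrix(0, L + 2L, ns)      # sufD[c, ] = sum_{i >= c} w D[i, ]
    for (i in L:1L) {
      sufD[i, ] <- sufD[i + 1L, ] + w[i] * prow(i, L - i, ns)
    }
    best <- rep(Inf, ns)
    for (cpos in seq_len(L + 1L)) {
      bw <- .pos_weight(min(cpos, L), cfg)
      cand <- prefC[cpos, ] + bw * cfg$bulge_penalty + sufD[cpos, ]
      best <- pmin(best, cand)
    }
    res$sb <- best
  }
  res
}

#' Predict target sites of a query on a transcript set
#'
#' Every window of each transcript (lengths `|query| - 1` to `|query| + 1`,
#' reverse-complement frame) is scored; hits at or below `max_score` are
#' returned sorted by (score, transcript, position). The window scan uses a
#' prefix/suffix-sum formulation of the single-bulge alignment that is
#' exactly equivalent to calling [score_duplex()] on every window. The
#' cleavage position is the transcript coordinate paired with query
#' position 10 (cleavage occurs opposite query positions 10-11).
#'
#' @param query_id,query_seq query identifier and sequence (5'->3').
#' @param transcripts named character vector of transcript sequences.
#' @param config a [target_config()].
#' @return data.frame `query_id`, `transcript_id`, `start`, `end` (1-based
#'   inclusive site interval), `score`, `cleavage_pos` (1-based), `pairing`.
#' @export
find_targets <- function(query_id, query_seq, transcripts,
                         config = target_config()) {
  if (length(transcripts) == 0L) stop("no transcripts", call. = FALSE)
  lq <- nchar(query_seq)
  q <- strsplit(query_seq, "", fixed = TRUE)[[1]]
  rows <- list()
  emit <- function(tid, tr, s, wlen) {
    site <- substr(tr, s, s + wlen - 1L)
    sc <- score_duplex(query_seq, site, config)
    if (is.null(sc) || sc$score > config$max_score) return(NULL)
    cleave_local <- sc$pair_site_index[10L]
    if (is.na(cleave_local)) cleave_local <- sc$pair_site_index[11L]
    data.frame(query_id = query_id, transcript_id = tid, start = s,
               end = s + wlen - 1L, score = sc$score,
               cleavage_pos = s + cleave_local - 1L,
               pairing = gsub("\n", "\\\\n", sc$pairing),
               stringsAsFactors = FALSE)
  }
  for (tid in sort(names(transcripts))) {
    tr <- transcripts[[tid]]
    tchars <- strsplit(tr, "", fixed = TRUE)[[1]]
    scan <- .scan_transcript(q, tchars, config)
    for (kind in names(scan)) {
      wlen <- switch(kind, nb = lq, qb = lq - 1L, sb = lq + 1L)
      if (config$max_bulges < 1L && kind != "nb") next
      hits <- which(scan[[kind]] <= config$max_score)
      for (s in hits) {
        row <- emit(tid, tr, s, wlen)
        if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query_id = character(), transcript_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      cleavage_pos = integer(), pairing = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$score, out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a degradome 5'-end profile for one transcript
#'
#' PARE tags are matched exactly (forward strand); every occurrence start
#' marks a decay-fragment 5' end and contributes the tag's read count.
#'
#' @param pare_tags tag table of PARE reads (`tag_id`, `seq`, count
#'   column(s)), or a character vector (each read counting 1).
#' @param transcript transcript sequence.
#' @return list with `profile` (integer vector over 1-based transcript
#'   positions) and `unmatched` (number of PARE tags with no match).
#' @export
pare_profile <- function(pare_tags, transcript) {
  if (is.character(pare_tags)) {
    pare_tags <- collapse_reads(pare_tags, "pare")
  }
  counts <- tag_count_matrix(pare_tags)
  total <- if (ncol(counts) > 0L) rowSums(counts) else rep(1L, nrow(pare_tags))
  prof <- integer(nchar(transcript))
  unmatched <- 0L
  for (i in seq_len(nrow(pare_tags))) {
    hit <- gregexpr(pare_tags$seq[i], transcript, fixed = TRUE)[[1]]
    if (hit[1L] == -1L) {
      unmatched <- unmatched + 1L
      next
    }
    prof[hit] <- prof[hit] + as.integer(total[i])
  }
  list(profile = prof, unmatched = unmatched)
}

#' Grade the degradome evidence at a predicted cleavage site
#'
#' With `d(x)` the PARE 5'-end count at transcript position `x` and `c` the
#' predicted cleavage position: category 0 if `d(c) > 1` and is the unique
#' transcript-wide maximum; 1 if `d(c) > 1` and ties the maximum; 2 if
#' `d(c) > 1` and above the median of positive positions; 3 if `d(c) > 1`
#' otherwise; 4 if `d(c) == 1`; `NA` (no evidence) if `d(c) == 0`.
#'
#' @param cleavage_pos 1-based transcript coordinate opposite query
#'   positions 10-11.
#' @param profile degradome profile from [pare_profile()].
#' @return list with `category` (integer or `NA`) and `reads` (`d(c)`).
#' @export
degradome_categorize <- function(cleavage_pos, profile) {
  stopifnot(cleavage_pos >= 1L, cleavage_pos <= length(profile))
  dc <- profile[cleavage_pos]
  if (dc == 0L) return(list(category = NA_integer_, reads = 0L))
  if (dc == 1L) return(list(category = 4L, reads = 1L))
  mx <- max(profile)
  if (dc == mx && sum(profile == mx) == 1L) {
    return(list(category = 0L, reads = dc))
  }
  if (dc == mx) return(list(category = 1L, reads = dc))
  med <- stats::median(profile[profile > 0L])
  if (dc > med) return(list(category = 2L, reads = dc))
  list(category = 3L, reads = dc)
}

#' Target prediction over many queries, with optional degradome grading
#'
#' @param queries named character vector of query sequences.
#' @param transcripts named character vector of transcripts.
#' @param pare_tags optional PARE tag table or character vector of reads.
#' @param config a [target_config()].
#' @return data.frame of hits ([find_targets()] columns plus
#'   `degradome_category` and `pare_reads`).
#' @export
predict_targets <- function(queries, transcripts, pare_tags = NULL,
                            config = target_config()) {
  hits <- list()
  for (qid in names(queries)) {
    h <- find_targets(qid, queries[[qid]], transcripts, config)
    if (nrow(h) > 0L) hits[[length(hits) + 1L]] <- h
  }
  if (length(hits) == 0L) {
    out <- find_targets("q", strrep("A", 21L),
                        c(dummy = strrep("C", 30L)), config)
    out$degradome_category <- integer()
    out$pare_reads <- integer()
    return(out)
  }
  out <- do.call(rbind, hits)
  out$degradome_category <- NA_integer_
  out$pare_reads <- 0L
  if (!is.null(pare_tags)) {
    profs <- lapply(transcripts, function(tr) pare_profile(pare_tags, tr))
    for (i in seq_len(nrow(out))) {
      g <- degradome_categorize(out$cleavage_pos[i],
                                profs[[out$transcript_id[i]]]$profile)
      out$degradome_category[i] <- g$category
      out$pare_reads[i] <- g$reads
    }
  }
  out <- out[order(out$score, out$query_id, out$transcript_id, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
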