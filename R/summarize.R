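#' @title Summary statistics, ratio tables, count export, DE intersection
#' @name summarize_viz
NULL

.stratum_stats <- function(rec) {
  counts <- if (nrow(rec) > 0L) {
    samples <- attr(rec, "samples")
    if (is.null(samples)) samples <- setdiff(names(rec), .internal_record_cols)
    if (length(samples) > 0L)
      rowSums(as.matrix(rec[, samples, drop = FALSE])) else rep(0L, nrow(rec))
  } else {
    numeric()
  }
  complex_groups <- unique(rec$complex_group[!is.na(rec$complex_group)])
  canon <- sum(rec$canonical_class == "canonical")
  noncanon <- sum(rec$canonical_class == "non_canonical")
  hp <- unique(rec$hairpin_id)
  most <- ""
  if (nrow(rec) > 0L) {
    by_hp <- tapply(counts, rec$hairpin_id, sum)
    ord <- order(-by_hp, names(by_hp))
    most <- names(by_hp)[ord[1L]]
  }
  drift <- vapply(.drift_categories_all, function(d) {
    sum(rec$canonical_class == "canonical" & rec$drift_category == d)
  }, 0L)
  subs <- vapply(.substitution_classes, function(s) {
    sum(rec$substitution_class == s)
  }, 0L)
  list(total_isomirs = length(complex_groups) + canon + noncanon,
       complex_count = length(complex_groups),
       canonical_count = canon,
       non_canonical_count = noncanon,
       hairpins_generating = length(hp),
       most_abundant_hairpin = most,
       drift_counts = drift,
       substitution_counts = subs)
}

#' Summary statistics of a detection run
#'
#' Computed separately for the templated and non-templated strata. Within a
#' stratum: `total_isomirs = complex_count + canonical_count +
#' non_canonical_count` (complex tags count once via their group), and the
#' drift-category counts partition the canonical records. The most abundant
#' hairpin maximizes summed isomiR read counts (ties broken by id).
#'
#' @param records record table from [run_detection()].
#' @return named list with elements `templated` and `nontemplated`, each a
#'   list of the summary fields (including named vectors `drift_counts` and
#'   `substitution_counts`).
#' @export
summarize_isomirs <- function(records) {
  samples <- attr(records, "samples")
  split_rec <- function(x) {
    attr(x, "samples") <- samples
    x
  }
  list(templated = .stratum_stats(split_rec(records[records$templated, , drop = FALSE])),
       nontemplated = .stratum_stats(split_rec(records[!records$templated, , drop = FALSE])))
}

#' Flatten summary statistics into a writable TSV data.frame
#' @param stats output of [summarize_isomirs()].
#' @return data.frame with columns `stratum`, `field`, `value`.
#' @export
summary_as_table <- function(stats) {
  one <- function(stratum, s) {
    scalar <- c(total_isomirs = s$total_isomirs, complex = s$complex_count,
                canonical = s$canonical_count,
                non_canonical = s$non_canonical_count,
                hairpins_generating = s$hairpins_generating)
    rows <- data.frame(stratum = stratum,
                       field = c(names(scalar), "most_abundant_hairpin",
                                 paste0("drift_", names(s$drift_counts)),
                                 paste0("subs_", names(s$substitution_counts))),
                       value = c(as.character(scalar),
                                 s$most_abundant_hairpin,
                                 as.character(s$drift_counts),
                                 as.character(s$substitution_counts)),
                       stringsAsFactors = FALSE)
    rows
  }
  rbind(one("templated", stats$templated),
        one("nontemplated", stats$nontemplated))
}

#' Per-mature isomiR abundance-ratio table
#'
#' For every mature miRNA with more than one detected isomiR, the ratio of
#' each isomiR's read count to the mature's total isomiR reads; ratios sum
#' to 1 per mature. Matures with a single isomiR are omitted.
#'
#' @param records record table from [run_detection()].
#' @return data.frame with columns `mature_id`, `tag_id`, `count`, `ratio`.
#' @export
ks_ratio_table <- function(records) {
  samples <- attr(records, "samples")
  if (is.null(samples)) samples <- setdiff(names(records), .internal_record_cols)
  out <- data.frame(mature_id = character(), tag_id = character(),
                    count = numeric(), ratio = numeric(),
                    stringsAsFactors = FALSE)
  rec <- records[!is.na(records$mature_id), , drop = FALSE]
  if (nrow(rec) == 0L) return(out)
  cnt <- if (length(samples) > 0L)
    rowSums(as.matrix(rec[, samples, drop = FALSE])) else rep(0, nrow(rec))
  for (m in sort(unique(rec$mature_id))) {
    sel <- rec$mature_id == m
    if (sum(sel) <= 1L) next
    sub <- data.frame(mature_id = m, tag_id = rec$tag_id[sel],
                      count = cnt[sel], ratio = cnt[sel] / sum(cnt[sel]),
                      stringsAsFactors = FALSE)
    sub <- sub[order(-sub$count, sub$tag_id), , drop = FALSE]
    out <- rbind(out, sub)
  }
  rownames(out) <- NULL
  out
}

#' Export the isomiR count matrix (rows = isomiR tags, columns = samples)
#'
#' Complex tags appear once. Intended as input for external differential
#' expression tools; their result tables are ingested by [intersect_de()].
#'
#' @param records record table from [run_detection()].
#' @param path optional output TSV path.
#' @return data.frame with `id`, `seq`, and one integer column per sample,
#'   ordered by `id`.
#' @export
export_count_matrix <- function(records, path = NULL) {
  samples <- attr(records, "samples")
  if (is.null(samples)) samples <- setdiff(names(records), .internal_record_cols)
  first <- !duplicated(records$tag_id)
  out <- data.frame(id = records$tag_id[first], seq = records$seq[first],
                    stringsAsFactors = FALSE)
  for (s in samples) out[[s]] <- as.integer(records[[s]][first])
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(path)) write_tsv(out, path)
  out
}

#' Intersect the top-k rows of two differential-expression result tables
#'
#' Each table needs columns `id`, `effect`, `adjusted_p`. Rows are ranked by
#' `adjusted_p` ascending then `abs(effect)` descending; ids present in both
#' top-k sets are returned with both tables' statistics side by side.
#'
#' @param table_a,table_b data.frames of DE results (e.g. from two different
#'   DE algorithms run externally).
#' @param k top-list size (default 50).
#' @return data.frame `id`, `effect_a`, `adjusted_p_a`, `effect_b`,
#'   `adjusted_p_b`, ordered by `adjusted_p_a` then `id`.
#' @export
intersect_de <- function(table_a, table_b, k = 50L) {
  need <- c("id", "effect", "adjusted_p")
  for (tb in list(a = table_a, b = table_b)) {
    missing <- setdiff(need, names(tb))
    if (length(missing) > 0L) {
      stop(sprintf("DE table lacks column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  topk <- function(tb) {
    tb <- tb[order(tb$adjusted_p, -abs(tb$effect), tb$id), , drop = FALSE]
    utils::head(tb, k)
  }
  ta <- topk(table_a)
  tb <- topk(table_b)
  common <- intersect(ta$id, tb$id)
  ma <- ta[match(common, ta$id), , drop = FALSE]
  mb <- tb[match(common, tb$id), , drop = FALSE]
  out <- data.frame(id = common, effect_a = ma$effect,
                    adjusted_p_a = ma$adjusted_p, effect_b = mb$effect,
                    adjusted_p_b = mb$adjusted_p, stringsAsFactors = FALSE)
  out <- out[order(out$adjusted_p_a, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
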