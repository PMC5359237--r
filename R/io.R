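#' @title Sequence and table input/output
#' @description Readers and writers for every on-disk format the pipeline
#'   touches: plain FASTA, collapsed FASTA (`>{tag_id}_x{count}`), 4-line
#'   FASTQ, and the classified isomiR table. All sequences are normalized to
#'   an upper-case DNA alphabet internally (U is converted to T on read);
#'   writers can restore U for RNA-facing output. Coordinates are 0-based
#'   half-open in memory and 1-based inclusive in every written file.
#' @name io_formats
NULL

.valid_seq_chars <- "ACGTN"

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Upper-cases and converts U to T. Idempotent.
#'
#' @param seq character vector of nucleotide strings.
#' @return character vector over `{A,C,G,T,N}`.
#' @keywords internal
normalize_seq <- function(seq) {
  toupper(chartr("Uu", "Tt", seq))
}

.check_alphabet <- function(seq, where = "sequence") {
  bad <- grepl(sprintf("[^%s]", .valid_seq_chars), seq)
  if (any(bad)) {
    stop(sprintf("invalid characters in %s: %s", where,
                 paste(utils::head(seq[bad], 3L), collapse = ", ")),
         call. = FALSE)
  }
  invisible(seq)
}

# Locate the file line number of FASTA record `i` (for error messages).
.fasta_record_line <- function(path, i) {
  lines <- readLines(path, warn = FALSE)
  grep("^>", lines)[i]
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file (gzip transparent).
#' @return a data.frame with columns `id` (header token before the first
#'   whitespace), `description` (remainder of the header, possibly empty) and
#'   `seq` (normalized upper-case DNA).
#' @details Malformed records (empty sequence, whitespace-only id) raise an
#'   error naming the offending record and its line number.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">h1 a hairpin", "ACGU"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- normalize_seq(as.character(x))
  empty <- which(nchar(seqs) == 0L | nchar(id) == 0L)
  if (length(empty) > 0L) {
    i <- empty[1L]
    stop(sprintf("empty sequence or id for record '%s' at line %d of %s",
                 id[i], .fasta_record_line(path, i), path), call. = FALSE)
  }
  .check_alphabet(seqs, where = path)
  data.frame(id = id, description = desc, seq = seqs, stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector, or a data.frame with `id` and `seq`
#'   columns (as returned by [read_fasta()]).
#' @param path output path.
#' @param rna if `TRUE`, emit U instead of T (RNA-facing output).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, rna = FALSE) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$seq, seqs$id)
  out <- if (rna) chartr("Tt", "Uu", seqs) else seqs
  Biostrings::writeXStringSet(Biostrings::BStringSet(out), path)
  invisible(path)
}

#' Read a collapsed FASTA file of unique tags
#'
#' Headers must match the collapsed dialect `>{tag_id}_x{count}` with
#' `count >= 1`. Counts are assigned to the named sample.
#'
#' @param path path to a collapsed FASTA file.
#' @param sample sample name the counts belong to.
#' @return a tag table: data.frame with columns `tag_id`, `seq`, and one
#'   integer count column named after `sample`.
#' @export
read_collapsed_fasta <- function(path, sample) {
  stopifnot(is.character(sample), length(sample) == 1L, nzchar(sample))
  fa <- read_fasta(path)
  m <- regmatches(fa$id, regexec("^(.+)_x(\\d+)$", fa$id))
  bad <- which(vapply(m, length, 1L) != 3L)
  if (length(bad) > 0L) {
    stop(sprintf("header '%s' lacks the '_x<count>' suffix (line %d of %s)",
                 fa$id[bad[1L]], .fasta_record_line(path, bad[1L]), path),
         call. = FALSE)
  }
  counts <- as.integer(vapply(m, `[`, "", 3L))
  if (any(counts < 1L)) {
    i <- which(counts < 1L)[1L]
    stop(sprintf("tag '%s' has count %d; counts must be >= 1",
                 fa$id[i], counts[i]), call. = FALSE)
  }
  out <- data.frame(tag_id = vapply(m, `[`, "", 2L), seq = fa$seq,
                    stringsAsFactors = FALSE)
  out[[sample]] <- counts
  out
}

#' Write a tag table as collapsed FASTA
#'
#' @param tags a tag table (`tag_id`, `seq`, count columns). If several count
#'   columns are present they are summed for the header count.
#' @param path output path.
#' @param rna emit U instead of T.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path, rna = FALSE) {
  counts <- tag_count_matrix(tags)
  total <- if (ncol(counts) > 0L) rowSums(counts) else rep(0L, nrow(tags))
  write_fasta(stats::setNames(tags$seq, sprintf("%s_x%d", tags$tag_id, as.integer(total))),
              path, rna = rna)
}

#' Extract the count columns of a tag table as an integer matrix
#'
#' @param tags a tag table.
#' @return integer matrix, one column per sample (possibly zero columns).
#' @keywords internal
tag_count_matrix <- function(tags) {
  fixed <- c("tag_id", "seq")
  cols <- setdiff(names(tags), fixed)
  as.matrix(tags[, cols, drop = FALSE])
}

#' Read a 4-line FASTQ file
#'
#' Strict 4-line records; sequence and quality strings must have equal
#' length. Sequences are normalized to upper-case DNA.
#'
#' @param path path to a FASTQ file (gzip transparent).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(data.frame(id = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("truncated FASTQ: %d lines is not a multiple of 4 in %s",
                 length(lines), path), call. = FALSE)
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  if (any(!startsWith(hdr, "@"))) {
    i <- which(!startsWith(hdr, "@"))[1L]
    stop(sprintf("malformed FASTQ header at line %d of %s", idx[i], path),
         call. = FALSE)
  }
  if (any(!startsWith(plus, "+"))) {
    i <- which(!startsWith(plus, "+"))[1L]
    stop(sprintf("missing '+' separator at line %d of %s", idx[i] + 2L, path),
         call. = FALSE)
  }
  mis <- which(nchar(seqs) != nchar(qual))
  if (length(mis) > 0L) {
    i <- mis[1L]
    stop(sprintf(
      "sequence/quality length mismatch (%d vs %d) at line %d of %s",
      nchar(seqs[i]), nchar(qual[i]), idx[i] + 1L, path), call. = FALSE)
  }
  seqs <- normalize_seq(seqs)
  .check_alphabet(seqs, where = path)
  data.frame(id = sub("\\s.*$", "", substring(hdr, 2L)), seq = seqs,
             qual = qual, stringsAsFactors = FALSE)
}

#' Write reads as 4-line FASTQ
#'
#' @param reads data.frame with `id`, `seq` and optionally `qual` columns
#'   (missing qualities are filled with "I").
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    vapply(nchar(reads$seq), function(n) strrep("I", n), "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(rbind(paste0("@", reads$id), reads$seq, "+", qual), con)
  invisible(path)
}

# Fixed column order of the written isomiR table, before the per-sample
# count columns.
.isomir_table_columns <- c(
  "tag_id", "seq", "hairpin_id", "mature_id", "start_1based",
  "end_1based_inclusive", "templated", "canonical_class", "drift5", "drift3",
  "drift_category", "substitution_class", "mismatch_positions", "tail5",
  "tail3", "seed_corrupt", "complex_group"
)

#' Write classified isomiR records as a TSV table
#'
#' One row per (isomiR, hairpin anchor). Columns, in order: `tag_id`, `seq`,
#' `hairpin_id`, `mature_id`, `start_1based`, `end_1based_inclusive`,
#' `templated`, `canonical_class`, `drift5`, `drift3`, `drift_category`,
#' `substitution_class`, `mismatch_positions` (comma-joined 1-based core
#' offsets), `tail5`, `tail3`, `seed_corrupt`, `complex_group`, then one
#' count column per sample. Tab-separated, header line, no quoting.
#'
#' @param records a record table from [run_detection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_isomir_table <- function(records, path) {
  samples <- attr(records, "samples")
  if (is.null(samples)) samples <- setdiff(names(records), .internal_record_cols)
  out <- data.frame(
    tag_id = records$tag_id,
    seq = records$seq,
    hairpin_id = records$hairpin_id,
    mature_id = ifelse(is.na(records$mature_id), "", records$mature_id),
    start_1based = records$start + 1L,
    end_1based_inclusive = records$end,
    templated = records$templated,
    canonical_class = records$canonical_class,
    drift5 = records$drift5,
    drift3 = records$drift3,
    drift_category = records$drift_category,
    substitution_class = records$substitution_class,
    mismatch_positions = vapply(records$mismatch_positions,
                                function(p) paste(p + 1L, collapse = ","), ""),
    tail5 = records$tail5,
    tail3 = records$tail3,
    seed_corrupt = records$seed_corrupt,
    complex_group = ifelse(is.na(records$complex_group), "",
                           records$complex_group),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (s in samples) out[[s]] <- records[[s]]
  write_tsv(out, path)
}

.internal_record_cols <- c(
  "tag_id", "seq", "hairpin_id", "mature_id", "start", "end", "templated",
  "canonical_class", "drift5", "drift3", "drift_category",
  "substitution_class", "mismatch_positions", "tail5", "tail3",
  "seed_corrupt", "complex_group"
)

#' Read back a written isomiR table into the in-memory record form
#'
#' Exact inverse of [write_isomir_table()] on valid data.
#'
#' @param path path to a TSV written by [write_isomir_table()].
#' @return a record table (0-based half-open coordinates, list-column of
#'   0-based mismatch offsets).
#' @export
read_isomir_table <- function(path) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                         colClasses = "character", check.names = FALSE)
  samples <- setdiff(names(x), .isomir_table_columns)
  rec <- data.frame(
    tag_id = x$tag_id,
    seq = x$seq,
    hairpin_id = x$hairpin_id,
    mature_id = ifelse(x$mature_id == "", NA_character_, x$mature_id),
    start = as.integer(x$start_1based) - 1L,
    end = as.integer(x$end_1based_inclusive),
    templated = as.logical(x$templated),
    canonical_class = x$canonical_class,
    drift5 = as.integer(x$drift5),
    drift3 = as.integer(x$drift3),
    drift_category = x$drift_category,
    substitution_class = x$substitution_class,
    stringsAsFactors = FALSE
  )
  rec$mismatch_positions <- lapply(x$mismatch_positions, function(p) {
    if (p == "") integer() else as.integer(strsplit(p, ",", fixed = TRUE)[[1]]) - 1L
  })
  rec$tail5 <- x$tail5
  rec$tail3 <- x$tail3
  rec$seed_corrupt <- as.logical(x$seed_corrupt)
  rec$complex_group <- ifelse(x$complex_group == "", NA_character_,
                              x$complex_group)
  for (s in samples) rec[[s]] <- as.integer(x[[s]])
  attr(rec, "samples") <- samples
  rec
}

#' Write a data.frame as headered TSV (no quoting)
#' @param x data.frame; fields must not contain tabs.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  has_tab <- vapply(x, function(col) any(grepl("\t", as.character(col), fixed = TRUE)), TRUE)
  if (any(has_tab)) {
    stop(sprintf("fields may not contain tabs (column %s)",
                 names(x)[has_tab][1L]), call. = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV written by [write_tsv()]
#' @param path input path.
#' @param ... passed to [utils::read.delim()].
#' @return data.frame.
#' @export
read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE, ...)
}
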