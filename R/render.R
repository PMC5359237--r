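#' @title Text alignment views of detected isomiRs
#' @description Renders a hairpin, its canonical miRNA(s) and the detected
#'   isomiRs as a fixed-width text block: every base sits at the column of
#'   its hairpin coordinate, matched bases are upper-case, non-templated
#'   tails and substituted bases are lower-case, and a right-margin column
#'   carries the terminal drift ("Mod"), substitution class and read count.
#'   The rendering is parseable; [parse_rendered_alignment()] inverts it.
#' @name alignment_view
NULL

.lower_runs <- function(s) {
  # leading and trailing lower-case run lengths of a string
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  low <- chars %in% letters
  lead <- if (all(low)) length(low) else which(!low)[1L] - 1L
  trail <- if (all(low)) 0L else length(low) - max(which(!low))
  c(lead = lead, trail = trail)
}

#' Render the alignment view of one hairpin
#'
#' @param hairpin_id hairpin identifier.
#' @param hairpins named character vector of hairpin sequences.
#' @param annotations annotation table ([resolve_annotations()]).
#' @param records record table; every row must be anchored to `hairpin_id`.
#' @return a single string (lines separated by `\n`).
#' @export
render_alignment <- function(hairpin_id, hairpins, annotations, records) {
  if (!hairpin_id %in% names(hairpins)) {
    stop(sprintf("unknown hairpin '%s'", hairpin_id), call. = FALSE)
  }
  if (nrow(records) > 0L && any(records$hairpin_id != hairpin_id)) {
    stop("records anchored to a different hairpin", call. = FALSE)
  }
  samples <- attr(records, "samples")
  if (is.null(samples)) samples <- setdiff(names(records), .internal_record_cols)
  hp <- hairpins[[hairpin_id]]
  tails5 <- nchar(records$tail5)
  tails3 <- nchar(records$tail3)
  off <- if (nrow(records)) max(0L, max(tails5 - records$start)) else 0L
  width <- max(nchar(hp),
               if (nrow(records)) max(records$end + tails3) else 0L)
  pad <- function(left, s) {
    body <- paste0(strrep(" ", left), s)
    paste0(body, strrep(" ", off + width - nchar(body)))
  }
  lines <- pad(off, hp)
  ann <- annotations[annotations$hairpin_id == hairpin_id, , drop = FALSE]
  for (i in seq_len(nrow(ann))) {
    lines <- c(lines, pad(off + ann$start[i], ann$seq[i]))
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    core <- substr(r$seq, tails5[i] + 1L, nchar(r$seq) - tails3[i])
    chars <- strsplit(core, "", fixed = TRUE)[[1]]
    mm <- r$mismatch_positions[[1]]
    if (length(mm) > 0L) chars[mm + 1L] <- tolower(chars[mm + 1L])
    body <- paste0(tolower(r$tail5), paste(chars, collapse = ""),
                   tolower(r$tail3))
    cnt <- if (length(samples) > 0L)
      sum(unlist(r[samples])) else 0L
    lines <- c(lines, paste0(
      pad(off + r$start - tails5[i], body),
      sprintf("  Mod=%d,%d class=%s count=%d", r$drift5, r$drift3,
              r$substitution_class, cnt)))
  }
  paste(lines, collapse = "\n")
}

#' Parse a rendered alignment view back into its structure
#'
#' Inverts [render_alignment()] on valid renders: recovers the hairpin, the
#' mature coordinates, and for each isomiR line its coordinates, tails (for
#' class `none`, the lower-case end runs), substituted positions (for
#' substitution classes), class, drifts and count.
#'
#' @param text a string produced by [render_alignment()].
#' @return list with `hairpin` (string), `matures` (data.frame `start`,
#'   `end`, `seq`) and `isomirs` (data.frame `start`, `end`, `seq`, `tail5`,
#'   `tail3`, `substitution_class`, `drift5`, `drift3`, `count`, plus a
#'   list-column `mismatch_positions`).
#' @export
parse_rendered_alignment <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  stopifnot(length(lines) >= 1L)
  lead_ws <- function(s) nchar(s) - nchar(sub("^ *", "", s))
  off <- lead_ws(lines[1L])
  hairpin <- trimws(lines[1L])
  matures <- data.frame(start = integer(), end = integer(),
                        seq = character(), stringsAsFactors = FALSE)
  iso <- list()
  for (ln in lines[-1L]) {
    mpos <- regexpr("Mod=", ln, fixed = TRUE)
    if (mpos == -1L) {
      s <- lead_ws(ln) - off
      seq <- trimws(ln)
      matures <- rbind(matures, data.frame(start = s, end = s + nchar(seq),
                                           seq = seq, stringsAsFactors = FALSE))
      next
    }
    margin <- substring(ln, mpos)
    m <- regmatches(margin, regexec(
      "Mod=(-?\\d+),(-?\\d+) class=(\\S+) count=(\\d+)", margin))[[1]]
    area <- sub(" *$", "", substr(ln, 1L, mpos - 1L))
    ls <- lead_ws(area)
    body <- trimws(area)
    cls <- m[4L]
    runs <- .lower_runs(body)
    if (cls == "none") {
      tail5 <- substr(body, 1L, runs["lead"])
      tail3 <- substr(body, nchar(body) - runs["trail"] + 1L, nchar(body))
      core <- substr(body, runs["lead"] + 1L, nchar(body) - runs["trail"])
      start <- ls - off + runs[["lead"]]
      mm <- integer()
    } else {
      tail5 <- ""
      tail3 <- ""
      core <- body
      start <- ls - off
      chars <- strsplit(body, "", fixed = TRUE)[[1]]
      mm <- which(chars %in% letters) - 1L
    }
    row <- data.frame(start = as.integer(start),
                      end = as.integer(start + nchar(core)),
                      seq = toupper(body), tail5 = toupper(tail5),
                      tail3 = toupper(tail3), substitution_class = cls,
                      drift5 = as.integer(m[2L]), drift3 = as.integer(m[3L]),
                      count = as.integer(m[5L]), stringsAsFactors = FALSE)
    row$mismatch_positions <- list(mm)
    iso[[length(iso) + 1L]] <- row
  }
  isomirs <- if (length(iso) > 0L) do.call(rbind, iso) else {
    out <- data.frame(start = integer(), end = integer(), seq = character(),
                      tail5 = character(), tail3 = character(),
                      substitution_class = character(), drift5 = integer(),
                      drift3 = integer(), count = integer(),
                      stringsAsFactors = FALSE)
    out$mismatch_positions <- list()
    out
  }
  rownames(isomirs) <- NULL
  list(hairpin = hairpin, matures = matures, isomirs = isomirs)
}
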