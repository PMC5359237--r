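#' @title End-to-end pipeline
#' @description Chains every stage in workflow order: per-sample
#'   preprocessing, tag merging, annotation resolution, detection,
#'   summaries, abundance-ratio tables, per-hairpin alignment views, count
#'   export, optional DE-table intersection, optional target prediction
#'   with degradome grading, and optional GO enrichment. Every run writes a
#'   manifest with the resolved configuration, input digests and per-stage
#'   audit counts. Reruns on identical inputs are byte-identical apart from
#'   the manifest timestamps.
#' @name pipeline
NULL

.read_reads_file <- function(path) {
  if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) {
    read_fastq(path)$seq
  } else {
    read_fasta(path)$seq
  }
}

.as_named <- function(fa) stats::setNames(fa$seq, fa$id)

#' Load and validate a pipeline configuration
#'
#' @param config a list, or a path to a YAML file, with fields: `hairpins`,
#'   `mature`, `reads` (named map sample -> FASTQ/FASTA path); optional
#'   `genome`, `contaminants`, `transcripts`, `pare`, `gene2go`, `de_a`,
#'   `de_b`, `de_top_k`; optional sub-lists `preprocess`, `detect`,
#'   `target` overriding [preprocess_config()], [detect_config()] and
#'   [target_config()] fields.
#' @return the resolved configuration list with config objects in place.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (need in c("hairpins", "mature", "reads")) {
    if (is.null(config[[need]])) {
      stop(sprintf("run config lacks required field '%s'", need),
           call. = FALSE)
    }
  }
  paths <- c(config$hairpins, config$mature, unlist(config$reads),
             config$genome, config$contaminants, config$transcripts,
             config$pare, config$gene2go, config$de_a, config$de_b)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(names(config$reads)) || any(!nzchar(names(config$reads)))) {
    stop("'reads' must be a named map of sample -> path", call. = FALSE)
  }
  config$preprocess <- do.call(preprocess_config,
                               as.list(config$preprocess %||% list()))
  config$detect <- do.call(detect_config, as.list(config$detect %||% list()))
  config$target <- do.call(target_config, as.list(config$target %||% list()))
  config$de_top_k <- config$de_top_k %||% 50L
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the complete workflow
#'
#' @param config see [load_run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory stage results (`tags`,
#'   `records`, `audit`, `stats`, and when inputs allow, `targets` and
#'   `enrichment`).
#' @export
run_all <- function(config, out_dir) {
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  config <- load_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  hairpins <- .as_named(read_fasta(config$hairpins))
  matures <- .as_named(read_fasta(config$mature))
  genome <- if (!is.null(config$genome))
    .as_named(read_fasta(config$genome)) else NULL
  contaminants <- if (!is.null(config$contaminants))
    .as_named(read_fasta(config$contaminants)) else NULL

  # preprocessing, one sample at a time
  tag_sets <- list()
  logs <- list()
  for (s in names(config$reads)) {
    reads <- .read_reads_file(config$reads[[s]])
    pp <- preprocess_reads(reads, s, config$preprocess, contaminants)
    tag_sets[[s]] <- pp$tags
    lg <- pp$log
    lg$sample <- s
    logs[[s]] <- lg
    write_collapsed_fasta(pp$tags, p(sprintf("tags_%s.fa", s)))
  }
  write_tsv(do.call(rbind, logs), p("preprocess_log.tsv"))
  tags <- merge_tag_sets(tag_sets)

  # detection
  annotations <- resolve_annotations(hairpins, matures)
  det <- run_detection(tags, hairpins, annotations, genome, config$detect)
  write_isomir_table(det$records, p("isomir_table.tsv"))
  write_tsv(det$audit, p("audit.tsv"))

  # summaries and views
  stats <- summarize_isomirs(det$records)
  write_tsv(summary_as_table(stats), p("summary.tsv"))
  write_tsv(ks_ratio_table(det$records), p("ks_ratios.tsv"))
  export_count_matrix(det$records, p("counts.tsv"))
  dir.create(p("renders"), showWarnings = FALSE)
  for (h in sort(unique(det$records$hairpin_id))) {
    rec <- det$records[det$records$hairpin_id == h, , drop = FALSE]
    attr(rec, "samples") <- attr(det$records, "samples")
    writeLines(render_alignment(h, hairpins, annotations, rec),
               p(file.path("renders", paste0(h, ".txt"))))
  }

  out <- list(tags = tags, records = det$records, audit = det$audit,
              stats = stats)

  # optional DE intersection (externally computed tables)
  if (!is.null(config$de_a) && !is.null(config$de_b)) {
    inter <- intersect_de(read_tsv(config$de_a), read_tsv(config$de_b),
                          k = config$de_top_k)
    write_tsv(inter, p("de_intersection.tsv"))
    out$de_intersection <- inter
  }

  # optional target prediction and degradome grading
  if (!is.null(config$transcripts)) {
    transcripts <- .as_named(read_fasta(config$transcripts))
    first <- !duplicated(det$records$tag_id)
    queries <- stats::setNames(det$records$seq[first],
                               det$records$tag_id[first])
    if (!is.null(out$de_intersection)) {
      queries <- queries[names(queries) %in% out$de_intersection$id]
    }
    pare_tags <- if (!is.null(config$pare)) {
      collapse_reads(.read_reads_file(config$pare), "pare")
    } else {
      NULL
    }
    hits <- predict_targets(queries, transcripts, pare_tags, config$target)
    write_tsv(hits, p("targets.tsv"))
    out$targets <- hits

    # optional GO enrichment of the targeted genes
    if (!is.null(config$gene2go) && nrow(hits) > 0L) {
      ann <- read_gene2go(config$gene2go)
      study <- intersect(unique(hits$transcript_id), unique(ann$gene_id))
      enr <- enrich_go(study, annotation = ann)
      write_tsv(enr, p("enrichment.tsv"))
      out$enrichment <- enr
    }
  }

  manifest <- list(
    tool = "isomirkit",
    version = as.character(utils::packageVersion("isomirkit")),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = lapply(stats::setNames(nm = paths_of(config)), function(f)
      unname(tools::md5sum(f))),
    detect = unclass(config$detect),
    preprocess = unclass(config$preprocess),
    target = unclass(config$target),
    audit = stats::setNames(as.list(det$audit$n_tags), det$audit$fate))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  yaml::write_yaml(list(detect = unclass(config$detect),
                        preprocess = unclass(config$preprocess),
                        target = unclass(config$target)),
                   p("config_echo.yaml"))
  invisible(out)
}

paths_of <- function(config) {
  c(config$hairpins, config$mature, unlist(config$reads), config$genome,
    config$contaminants, config$transcripts, config$pare, config$gene2go,
    config$de_a, config$de_b)
}
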