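#' @title Synthetic fixture generator with exact ground truth
#' @description Generates a fully labelled small RNA-seq study: hairpins
#'   with embedded canonical miRNAs, a genome with the hairpins at recorded
#'   loci, contaminant (ncRNA-style) references, reads planted for every
#'   taxonomy cell (exact canonical, all eight templated drift categories,
#'   all substitution classes, non-templated 5'/3' tails, contaminants,
#'   genomic background, unmappable), transcripts carrying perfect target
#'   sites, degradome (PARE) reads at the predicted cleavage positions, and
#'   a gene-to-GO annotation with one enriched term. Planted classes are
#'   constructed to be unambiguous (tails differ from the templated and
#'   genomic continuations; substitution placements have a unique best
#'   alignment); the guarantees are asserted structurally at generation
#'   time with rejection sampling, so any seed yields a valid bundle.
#' @name simulate
NULL

.sim_classes <- c("exact_canonical", "5a", "3a", "5d", "3d", "5a3a", "5a3d",
                  "5d3a", "5d3d", "MS", "TS", "CV", "5V", "3V", "5V3V",
                  "tail3", "tail5", "contaminant", "genome_background",
                  "unmappable")

#' Simulation configuration
#'
#' @param seed RNG seed; fixes every output byte.
#' @param n_hairpins number of pre-miRNA hairpins (default 20; at least 12).
#' @param hairpin_len hairpin length in nt (default 120).
#' @param mature_len canonical mature length (default 21).
#' @param tags_per_class distinct tags planted per taxonomy class
#'   (default 4).
#' @param reads_per_tag reads per planted tag, split across samples
#'   (default 15).
#' @param samples sample names (default two samples).
#' @param adapter3 3' adapter appended to every read (default a common
#'   Illumina small-RNA adapter).
#' @param tail_t_bias probability that a non-templated tail is poly-T
#'   (uridylation analogue) rather than poly-A (default 0.7).
#' @param flank_len genomic flank between embedded hairpins (default 60).
#' @param classes taxonomy classes to plant (default: all).
#' @return a `sim_config` list.
#' @export
simulate_config <- function(seed = 1L, n_hairpins = 20L, hairpin_len = 120L,
                            mature_len = 21L, tags_per_class = 4L,
                            reads_per_tag = 15L,
                            samples = c("sample1", "sample2"),
                            adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                            tail_t_bias = 0.7, flank_len = 60L,
                            classes = .sim_classes) {
  stopifnot(n_hairpins >= 12L, hairpin_len >= 3L * mature_len,
            mature_len >= 18L, tags_per_class >= 1L, reads_per_tag >= 1L,
            length(samples) >= 1L, all(classes %in% .sim_classes))
  structure(list(seed = as.integer(seed), n_hairpins = as.integer(n_hairpins),
                 hairpin_len = as.integer(hairpin_len),
                 mature_len = as.integer(mature_len),
                 tags_per_class = as.integer(tags_per_class),
                 reads_per_tag = as.integer(reads_per_tag),
                 samples = samples, adapter3 = normalize_seq(adapter3),
                 tail_t_bias = tail_t_bias, flank_len = as.integer(flank_len),
                 classes = classes),
            class = "sim_config")
}

.rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1L)
}

.count_occurrences <- function(needle, haystacks) {
  sum(vapply(haystacks, function(h) {
    hit <- gregexpr(needle, h, fixed = TRUE)[[1]]
    if (hit[1L] == -1L) 0L else length(hit)
  }, 0L))
}

# Does step 1 (mismatch-tolerant remapping + substitution classification)
# accept this tag anywhere? Mirrors the detection engine's acceptance rule.
.step1_accepts <- function(seq, hairpins, annotations, dcfg) {
  k1 <- dcfg$max_internal_snps + 2L * dcfg$max_terminal_subs
  aln <- map_tag(seq, hairpins, k1)
  if (nrow(aln) == 0L) return(FALSE)
  bh <- best_hits(aln, annotations)
  for (i in seq_len(nrow(bh))) {
    cls <- classify_substitutions(bh$mismatch_positions[[i]], nchar(seq), dcfg)
    if (cls$ok) return(TRUE)
  }
  FALSE
}

# First successful trim pair for the recursive trim-and-remap step, or NULL.
.first_trim_success <- function(seq, hairpins, dcfg) {
  l <- nchar(seq)
  for (t in seq_len(dcfg$r_max_trim)) {
    for (i in 0:t) {
      j <- t - i
      if (l - t < dcfg$min_len) next
      core <- substr(seq, i + 1L, l - j)
      aln <- map_tag(core, hairpins, 0L)
      if (nrow(aln) > 0L) return(list(i = i, j = j, aln = aln))
    }
  }
  NULL
}

.sim_truth_row <- function(tag_seq, class, fate, templated, canonical_class,
                           drift5, drift3, drift_cat, sub_class, tail5,
                           tail3, hairpin_id, mature_id) {
  data.frame(seq = tag_seq, class = class, fate = fate,
             templated = templated, canonical_class = canonical_class,
             drift5 = drift5, drift3 = drift3, drift_category = drift_cat,
             substitution_class = sub_class, tail5 = tail5, tail3 = tail3,
             hairpin_id = hairpin_id, mature_id = mature_id,
             stringsAsFactors = FALSE)
}

# Substitution-position templates per class, parameterized by tag index and
# core length L (0-based positions).
.sub_positions <- function(class, idx, L) {
  pick <- function(opts) opts[[(idx - 1L) %% length(opts) + 1L]]
  switch(class,
    MS = pick(list(10L, 9L, 11L, 12L)),
    TS = pick(list(c(9L, 10L), c(10L, 11L), c(8L, 9L), c(11L, 12L))),
    CV = pick(list(c(0L, 10L), c(10L, L - 1L), c(0L, 11L), c(11L, L - 1L))),
    `5V` = pick(list(0L, c(0L, 1L))),
    `3V` = pick(list(L - 1L, c(L - 2L, L - 1L))),
    `5V3V` = pick(list(c(0L, L - 1L), c(0L, 1L, L - 1L))))
}

.drift_pair <- function(class, idx) {
  pick <- function(opts) opts[[(idx - 1L) %% length(opts) + 1L]]
  switch(class,
    `5a` = pick(list(c(1L, 0L), c(2L, 0L), c(3L, 0L))),
    `3a` = pick(list(c(0L, 1L), c(0L, 2L), c(0L, 3L))),
    `5d` = pick(list(c(-1L, 0L), c(-2L, 0L), c(-3L, 0L))),
    `3d` = pick(list(c(0L, -1L), c(0L, -2L), c(0L, -3L))),
    `5a3a` = pick(list(c(1L, 1L), c(1L, 2L), c(2L, 1L))),
    `5a3d` = pick(list(c(1L, -1L), c(2L, -1L), c(1L, -2L))),
    `5d3a` = pick(list(c(-1L, 1L), c(-1L, 2L), c(-2L, 1L))),
    `5d3d` = pick(list(c(-1L, -1L), c(-1L, -2L), c(-2L, -1L))))
}

#' Generate a synthetic fixture bundle with ground-truth labels
#'
#' @param config a [simulate_config()].
#' @param out_dir optional directory; when given, writes `hairpin.fa`,
#'   `mature.fa`, `genome.fa`, `ncrna.fa`, `reads_<sample>.fastq`, `pare.fa`,
#'   `cdna.fa`, `gene2go.tsv` and `truth.tsv`.
#' @return list with `hairpins`, `matures` (named character vectors),
#'   `annotations`, `genome`, `ncrna`, `reads` (named list of per-sample
#'   read vectors), `truth` (per-tag label table), `transcripts`, `pare`
#'   (character vector of PARE reads), `target_truth`, `gene2go`,
#'   `detect` and `preprocess` (the configurations the bundle is built
#'   for), and `config`.
#' @export
simulate_bundle <- function(config = simulate_config(), out_dir = NULL) {
  set.seed(config$seed)
  dcfg <- detect_config(max_internal_snps = 2L)
  pcfg <- preprocess_config(adapter3 = config$adapter3)
  ml <- config$mature_len
  hl <- config$hairpin_len
  nh <- config$n_hairpins

  # hairpin roles: 1-4 mature flush with the 3' end (3' tails cannot be
  # templated), 5-8 flush with the 5' end, the rest centered
  roles <- c(rep("edge3", 4L), rep("edge5", 4L), rep("mid", nh - 8L))
  hp_ids <- sprintf("sim-MIR%03d", seq_len(nh))
  mat_ids <- sprintf("sim-miR%03d", seq_len(nh))

  for (attempt in seq_len(50L)) {
    hairpins <- character(nh)
    mat_start <- integer(nh)
    for (h in seq_len(nh)) {
      hairpins[h] <- .rand_seq(hl)
      mat_start[h] <- switch(roles[h],
        edge3 = hl - ml,
        edge5 = 0L,
        mid = sample(seq(2L * dcfg$r_max_trim, hl - ml - 2L * dcfg$r_max_trim), 1L))
    }
    names(hairpins) <- hp_ids
    matures <- stats::setNames(substr(hairpins, mat_start + 1L,
                                      mat_start + ml), mat_ids)
    ok <- all(vapply(matures, function(m) {
      .count_occurrences(m, hairpins) == 1L
    }, TRUE))
    if (ok) break
  }
  if (!ok) stop("could not generate unique matures", call. = FALSE)
  annotations <- data.frame(mature_id = mat_ids, hairpin_id = hp_ids,
                            start = mat_start, end = mat_start + ml,
                            seq = as.character(matures),
                            stringsAsFactors = FALSE)

  # genome: one chromosome, hairpins embedded between random flanks
  flanks <- vapply(seq_len(nh + 1L), function(i) .rand_seq(config$flank_len), "")
  chrom <- flanks[1L]
  hp_locus <- integer(nh)
  for (h in seq_len(nh)) {
    hp_locus[h] <- nchar(chrom)  # 0-based start of hairpin h on the chromosome
    chrom <- paste0(chrom, hairpins[h], flanks[h + 1L])
  }
  genome <- c(chr1 = chrom)
  ncrna <- stats::setNames(vapply(1:5, function(i) .rand_seq(90L), ""),
                           sprintf("sim-ncRNA%02d", 1:5))

  mid_idx <- which(roles == "mid")
  edge3_idx <- which(roles == "edge3")
  edge5_idx <- which(roles == "edge5")
  classes <- config$classes
  truth <- list()
  planted <- character()
  rr_mid <- 0L

  add_tag <- function(row) {
    truth[[length(truth) + 1L]] <<- row
    planted <<- c(planted, row$seq)
  }

  tag_ok_generic <- function(seq) {
    !(seq %in% planted) && .count_occurrences(seq, ncrna) == 0L
  }

  for (class in classes) {
    for (idx in seq_len(config$tags_per_class)) {
      done <- FALSE
      for (try in seq_len(200L)) {
        if (class %in% c("exact_canonical", .drift_categories_templated,
                         .substitution_classes[-1])) {
          h <- mid_idx[(rr_mid %% length(mid_idx)) + 1L]
          hp <- hairpins[[h]]
          ms <- mat_start[h]
          if (class == "exact_canonical") {
            seq <- matures[[h]]
            d5 <- 0L; d3 <- 0L
          } else if (class %in% .drift_categories_templated) {
            d <- .drift_pair(class, idx)
            d5 <- d[1L]; d3 <- d[2L]
            s <- ms - d5
            e <- ms + ml + d3
            seq <- substr(hp, s + 1L, e)
          } else {
            seq <- matures[[h]]
            d5 <- 0L; d3 <- 0L
          }
          if (class %in% c("exact_canonical", .drift_categories_templated)) {
            # templated: must map 0-mismatch exactly once, at this hairpin
            if (!tag_ok_generic(seq)) { rr_mid <- rr_mid + 1L; next }
            aln <- map_tag(seq, hairpins, 0L)
            if (nrow(aln) != 1L || aln$hairpin_id != hp_ids[h]) {
              rr_mid <- rr_mid + 1L; next
            }
            fate <- if (class == "exact_canonical") "exact_canonical" else
              "templated_isomiR"
            add_tag(.sim_truth_row(seq, class, fate, TRUE, "canonical",
                                   d5, d3,
                                   if (class == "exact_canonical") "no_drift"
                                   else class,
                                   "none", "", "", hp_ids[h], mat_ids[h]))
            rr_mid <- rr_mid + 1L
            done <- TRUE
            break
          }
          # substitution classes: mutate the mature at planted positions
          pos <- .sub_positions(class, idx + try - 1L, ml)
          chars <- strsplit(seq, "", fixed = TRUE)[[1]]
          for (p in pos) chars[p + 1L] <- .mutate_base(chars[p + 1L])
          seq <- paste(chars, collapse = "")
          if (!tag_ok_generic(seq)) { rr_mid <- rr_mid + 1L; next }
          if (nrow(map_tag(seq, hairpins, 0L)) > 0L) { rr_mid <- rr_mid + 1L; next }
          if (matches_exactly(seq, genome)) { rr_mid <- rr_mid + 1L; next }
          k1 <- dcfg$max_internal_snps + 2L * dcfg$max_terminal_subs
          aln <- map_tag(seq, hairpins, k1)
          best_mm <- min(aln$n_mismatch)
          at_min <- aln[aln$n_mismatch == best_mm, , drop = FALSE]
          if (best_mm != length(pos) || nrow(at_min) != 1L ||
              at_min$hairpin_id != hp_ids[h] || at_min$start != ms) {
            rr_mid <- rr_mid + 1L; next
          }
          cls <- classify_substitutions(at_min$mismatch_positions[[1]], ml, dcfg)
          if (!cls$ok || cls$class != class) { rr_mid <- rr_mid + 1L; next }
          add_tag(.sim_truth_row(seq, class, "nontemplated_isomiR", FALSE,
                                 "canonical", 0L, 0L, "no_drift", class,
                                 "", "", hp_ids[h], mat_ids[h]))
          rr_mid <- rr_mid + 1L
          done <- TRUE
          break
        } else if (class %in% c("tail3", "tail5")) {
          pool <- if (class == "tail3") edge3_idx else edge5_idx
          h <- pool[(idx - 1L) %% length(pool) + 1L]
          tail_len <- 2L + (idx + try) %% 2L
          # genomic continuation beyond the hairpin end at this locus
          continuation <- if (class == "tail3") {
            substr(genome[["chr1"]], hp_locus[h] + hl + 1L,
                   hp_locus[h] + hl + 1L)
          } else {
            substr(genome[["chr1"]], hp_locus[h], hp_locus[h])
          }
          pref <- if (stats::runif(1L) < config$tail_t_bias) {
            c("T", "A", "G", "C")
          } else {
            c("A", "T", "G", "C")
          }
          base <- setdiff(pref, continuation)[1L]
          tail <- strrep(base, tail_len)
          seq <- if (class == "tail3") paste0(matures[[h]], tail) else
            paste0(tail, matures[[h]])
          if (!tag_ok_generic(seq)) next
          if (nrow(map_tag(seq, hairpins, 0L)) > 0L) next
          if (matches_exactly(seq, genome)) next
          if (.step1_accepts(seq, hairpins, annotations, dcfg)) next
          ft <- .first_trim_success(seq, hairpins, dcfg)
          want_i <- if (class == "tail5") tail_len else 0L
          want_j <- if (class == "tail3") tail_len else 0L
          if (is.null(ft) || ft$i != want_i || ft$j != want_j ||
              nrow(ft$aln) != 1L || ft$aln$hairpin_id != hp_ids[h]) next
          t5 <- if (class == "tail5") tail else ""
          t3 <- if (class == "tail3") tail else ""
          d5 <- if (class == "tail5") tail_len else 0L
          d3 <- if (class == "tail3") tail_len else 0L
          add_tag(.sim_truth_row(seq, class, "nontemplated_isomiR", FALSE,
                                 "canonical", d5, d3,
                                 if (class == "tail3") "3a" else "5a",
                                 "none", t5, t3, hp_ids[h], mat_ids[h]))
          done <- TRUE
          break
        } else if (class == "contaminant") {
          src <- ncrna[[sample(length(ncrna), 1L)]]
          s <- sample(nchar(src) - ml, 1L)
          seq <- substr(src, s, s + ml - 1L)
          if (seq %in% planted) next
          if (nrow(map_tag(seq, hairpins, 0L)) > 0L) next
          add_tag(.sim_truth_row(seq, class, "contaminant", NA, "", NA_integer_,
                                 NA_integer_, "", "", "", "", "", ""))
          done <- TRUE
          break
        } else if (class == "genome_background") {
          f <- sample(length(flanks), 1L)
          s <- sample(config$flank_len - ml, 1L)
          seq <- substr(flanks[f], s, s + ml - 1L)
          if (!tag_ok_generic(seq)) next
          if (nrow(map_tag(seq, hairpins, 0L)) > 0L) next
          add_tag(.sim_truth_row(seq, class, "genome_filtered", NA, "",
                                 NA_integer_, NA_integer_, "", "", "", "",
                                 "", ""))
          done <- TRUE
          break
        } else {
          seq <- .rand_seq(22L)
          if (!tag_ok_generic(seq)) next
          if (nrow(map_tag(seq, hairpins, 0L)) > 0L) next
          if (matches_exactly(seq, genome)) next
          if (.step1_accepts(seq, hairpins, annotations, dcfg)) next
          if (!is.null(.first_trim_success(seq, hairpins, dcfg))) next
          add_tag(.sim_truth_row(seq, class, "unclassifiable", NA, "",
                                 NA_integer_, NA_integer_, "", "", "", "",
                                 "", ""))
          done <- TRUE
          break
        }
      }
      if (!done) {
        stop(sprintf("could not plant an unambiguous '%s' tag", class),
             call. = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  truth$seed_corrupt <- ifelse(
    truth$mature_id == "", NA,
    mapply(function(s, m) {
      if (m == "") NA else flag_seed_corrupt(s, matures[[m]], dcfg)
    }, truth$seq, truth$mature_id, USE.NAMES = FALSE))

  # reads: counts split across samples, 3' adapter appended
  nsamp <- length(config$samples)
  base_n <- config$reads_per_tag %/% nsamp
  extra <- config$reads_per_tag %% nsamp
  reads <- stats::setNames(vector("list", nsamp), config$samples)
  for (si in seq_len(nsamp)) {
    n_i <- base_n + as.integer(si <= extra)
    reads[[si]] <- unlist(lapply(truth$seq, function(s) {
      rep(paste0(s, config$adapter3), n_i)
    }))
  }

  # transcripts with perfect target sites for four mid-hairpin matures,
  # plus two background transcripts
  target_mats <- mat_ids[mid_idx[1:4]]
  transcripts <- character()
  target_truth <- list()
  pare <- character()
  for (ti in seq_along(target_mats)) {
    mseq <- matures[[target_mats[ti]]]
    site <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(mseq)))
    left <- .rand_seq(100L + 10L * ti)
    tr <- paste0(left, site, .rand_seq(120L))
    tid <- sprintf("sim-tx%02d", ti)
    transcripts[tid] <- tr
    s <- nchar(left) + 1L
    e <- s + ml - 1L
    cleave <- e - 9L  # transcript base paired with query position 10
    target_truth[[ti]] <- data.frame(
      query_id = target_mats[ti], transcript_id = tid, start = s, end = e,
      cleavage_pos = cleave, stringsAsFactors = FALSE)
    # degradome: decay fragments starting at the cleavage site; first two
    # transcripts get a dominant unique peak (category 0), the others share
    # the maximum with one decoy position (category 1)
    frag <- substr(tr, cleave, cleave + 19L)
    pare <- c(pare, rep(frag, 4L + ti))
    if (ti > 2L) {
      decoy_pos <- 10L
      pare <- c(pare, rep(substr(tr, decoy_pos, decoy_pos + 19L), 4L + ti))
    }
  }
  for (bi in 1:2) {
    transcripts[sprintf("sim-tx%02d", length(target_mats) + bi)] <-
      .rand_seq(260L)
  }
  target_truth <- do.call(rbind, target_truth)

  # gene-to-GO annotation: the four target transcripts plus one extra gene
  # share a stress-response-style term; everything gets a root-like term
  genes <- c(names(transcripts), sprintf("sim-g%02d", 7:20))
  gene2go <- rbind(
    data.frame(gene_id = genes, go_id = "GO:0008150",
               stringsAsFactors = FALSE),
    data.frame(gene_id = c(names(transcripts)[1:4], "sim-g07"),
               go_id = "GO:0006950", stringsAsFactors = FALSE),
    data.frame(gene_id = sprintf("sim-g%02d", 8:13), go_id = "GO:0008152",
               stringsAsFactors = FALSE))

  bundle <- list(hairpins = hairpins, matures = matures,
                 annotations = annotations, genome = genome, ncrna = ncrna,
                 reads = reads, truth = truth, transcripts = transcripts,
                 pare = pare, target_truth = target_truth,
                 gene2go = gene2go, detect = dcfg, preprocess = pcfg,
                 config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a simulated bundle to disk
#'
#' @param bundle output of [simulate_bundle()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_fasta(bundle$hairpins, p("hairpin.fa"))
  write_fasta(bundle$matures, p("mature.fa"))
  write_fasta(bundle$genome, p("genome.fa"))
  write_fasta(bundle$ncrna, p("ncrna.fa"))
  for (s in names(bundle$reads)) {
    rd <- bundle$reads[[s]]
    write_fastq(data.frame(id = sprintf("%s_r%06d", s, seq_along(rd)),
                           seq = rd, stringsAsFactors = FALSE),
                p(sprintf("reads_%s.fastq", s)))
  }
  write_fasta(stats::setNames(bundle$pare,
                              sprintf("pare_r%06d", seq_along(bundle$pare))),
              p("pare.fa"))
  write_fasta(bundle$transcripts, p("cdna.fa"))
  utils::write.table(bundle$gene2go, p("gene2go.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(bundle$truth, p("truth.tsv"))
  invisible(out_dir)
}
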