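# Shared fixtures. The default simulated bundle is expensive enough to be
# worth computing once per test run.

.fixture_env <- new.env(parent = emptyenv())

sim_bundle_cached <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- simulate_bundle(simulate_config(seed = 1L))
  }
  .fixture_env$bundle
}

# The bundle run end to end through preprocessing and detection.
sim_detection_cached <- function() {
  if (is.null(.fixture_env$detection)) {
    b <- sim_bundle_cached()
    tag_sets <- lapply(names(b$reads), function(s) {
      preprocess_reads(b$reads[[s]], s, b$preprocess, b$ncrna)$tags
    })
    tags <- merge_tag_sets(tag_sets)
    .fixture_env$detection <- c(
      run_detection(tags, b$hairpins, b$annotations, b$genome, b$detect),
      list(tags = tags))
  }
  .fixture_env$detection
}

# A tiny hand-built hairpin/annotation pair: 60-nt hairpin with a 21-nt
# mature at 0-based position 20.
micro_hairpin <- function() {
  hairpin <- paste0("GATTACAGATTACAGATTAC",                # 0..19
                    "ACGTGGCTTAAGCGTACGATC",               # mature, 20..40
                    "GCTTCCAGATGCAAGTCCA")                 # 41..59
  hairpins <- c(H1 = hairpin)
  ann <- data.frame(mature_id = "m1", hairpin_id = "H1", start = 20L,
                    end = 41L, seq = "ACGTGGCTTAAGCGTACGATC",
                    stringsAsFactors = FALSE)
  list(hairpins = hairpins, annotations = ann,
       mature = "ACGTGGCTTAAGCGTACGATC")
}

make_tags <- function(seqs, counts = rep(1L, length(seqs)),
                      sample = "s1") {
  out <- data.frame(tag_id = sprintf("t%06d", seq_along(seqs)), seq = seqs,
                    stringsAsFactors = FALSE)
  out[[sample]] <- as.integer(counts)
  out
}
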