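cfg <- detect_config(max_internal_snps = 2L)

# hand-built scene: hairpin ends right after the mature, so a 3' tail can
# never be templated; genome continues with "GC" after the hairpin
tail_scene <- function() {
  mature <- "ACGTGGCTTAAGCGTACGATC"
  hairpin <- paste0("GATTACAGATTACAGATTACGGCATCCGAT", mature)   # mature at 30..50
  hairpins <- c(H1 = hairpin)
  ann <- data.frame(mature_id = "m1", hairpin_id = "H1", start = 30L,
                    end = 51L, seq = mature, stringsAsFactors = FALSE)
  genome <- c(chr1 = paste0("TTTTTTTTTT", hairpin, "GCAAACCCAAACCC"))
  list(hairpins = hairpins, annotations = ann, genome = genome,
       mature = mature)
}

test_that("non-templated 3' tails are recovered by trim-and-remap", {
  sc <- tail_scene()
  tagged <- paste0(sc$mature, "TT")
  det <- run_detection(make_tags(tagged), sc$hairpins, sc$annotations,
                       sc$genome, cfg)
  rec <- det$records
  expect_equal(nrow(rec), 1L)
  expect_false(rec$templated)
  expect_equal(rec$tail3, "TT")
  expect_equal(rec$tail5, "")
  expect_equal(rec$drift3, 2L)
  expect_equal(rec$drift_category, "3a")
  expect_equal(rec$substitution_class, "none")
  expect_false(rec$seed_corrupt)
})

test_that("internal substitutions classify in the mismatch-remap step", {
  sc <- tail_scene()
  mut <- sc$mature
  substr(mut, 11, 11) <- setdiff(c("A", "C", "G", "T"), substr(mut, 11, 11))[1]
  det <- run_detection(make_tags(mut), sc$hairpins, sc$annotations,
                       sc$genome, cfg)
  rec <- det$records
  expect_equal(rec$substitution_class, "MS")
  expect_equal(rec$drift_category, "no_drift")
  expect_false(rec$templated)
  expect_equal(rec$mismatch_positions[[1]], 10L)
})

test_that("tags matching the genome never enter non-templated detection", {
  sc <- tail_scene()
  # a pure genomic fragment outside the hairpin
  bg <- substr(sc$genome[["chr1"]], nchar(sc$genome[["chr1"]]) - 20L,
               nchar(sc$genome[["chr1"]]))
  det <- run_detection(make_tags(bg), sc$hairpins, sc$annotations,
                       sc$genome, cfg)
  expect_equal(det$fates$fate, "genome_filtered")
  expect_equal(nrow(det$records), 0L)
})

test_that("tags mapping perfectly to two hairpins become one complex group", {
  mature <- "ACGTGGCTTAAGCGTACGATC"
  h1 <- paste0(strrep("GAT", 10), mature, strrep("CCA", 3))
  h2 <- paste0(strrep("TTG", 4), mature, strrep("AGC", 8))
  hairpins <- c(H1 = h1, H2 = h2)
  ann <- data.frame(mature_id = c("m1", "m2"), hairpin_id = c("H1", "H2"),
                    start = c(30L, 12L), end = c(51L, 33L), seq = mature,
                    stringsAsFactors = FALSE)
  tag <- paste0(mature, substr(h1, 52, 52))
  # only complex if the extension is templated on both hairpins; build it so
  extend <- substr(h1, 52, 52)
  h2 <- paste0(strrep("TTG", 4), mature, extend, strrep("AGC", 8))
  hairpins <- c(H1 = h1, H2 = h2)
  det <- run_detection(make_tags(tag), hairpins, ann, NULL, cfg)
  rec <- det$records
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$hairpin_id, c("H1", "H2"))
  expect_true(all(rec$canonical_class == "complex"))
  expect_equal(length(unique(rec$complex_group)), 1L)
  expect_false(any(is.na(rec$complex_group)))
  # the tag is one fate, counted once
  expect_equal(det$audit$n_tags[det$audit$fate == "templated_isomiR"], 1L)
})

test_that("fates are exhaustive, mutually exclusive, and sum to the input", {
  det <- sim_detection_cached()
  expect_equal(sum(det$audit$n_tags), nrow(det$tags))
  expect_true(all(det$fates$fate %in% c(
    "exact_canonical", "templated_isomiR", "nontemplated_isomiR",
    "genome_filtered", "unclassifiable")))
  # empty input yields empty records and a zeroed audit
  b <- sim_bundle_cached()
  det0 <- run_detection(make_tags(character(), integer()), b$hairpins,
                        b$annotations, b$genome, cfg)
  expect_equal(nrow(det0$records), 0L)
  expect_equal(sum(det0$audit$n_tags), 0L)
})

test_that("templated records never carry tails, mismatches, or zero drift", {
  det <- sim_detection_cached()
  rec <- det$records[det$records$templated, ]
  expect_true(all(rec$substitution_class == "none"))
  expect_true(all(rec$tail5 == "" & rec$tail3 == ""))
  expect_true(all(lengths(rec$mismatch_positions) == 0L))
  expect_true(all(rec$drift_category != "no_drift"))
})
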