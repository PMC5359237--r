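adapter <- "TGGAATTCTC"
cfg <- preprocess_config(adapter3 = adapter)

test_that("3' adapters are removed at the best match, and inserts survive", {
  insert <- "ACGTACGTACGTACGTACGT"
  expect_equal(trim_adapters(paste0(insert, adapter), cfg), insert)
  expect_equal(trim_adapters(insert, cfg), insert)           # no adapter
  expect_true(is.na(trim_adapters(adapter, cfg)))            # empty insert
  # partial adapter at the read end (overlap 7 of 10)
  expect_equal(trim_adapters(paste0(insert, substr(adapter, 1, 7)), cfg),
               insert)
  # below the minimum overlap the read passes unchanged
  short <- paste0(insert, substr(adapter, 1, 4))
  expect_equal(trim_adapters(short, cfg), short)
})

test_that("5' adapter removal takes the longest acceptable adapter suffix", {
  cfg5 <- preprocess_config(adapter3 = "", adapter5 = "GTTCAGAGTT")
  insert <- "ACGTACGTACGTACGTACGT"
  expect_equal(trim_adapters(paste0("GTTCAGAGTT", insert), cfg5), insert)
  expect_equal(trim_adapters(paste0("AGAGTT", insert), cfg5), insert)
})

test_that("adapter trimming is idempotent on its own output", {
  set.seed(42)
  for (i in 1:50) {
    read <- paste0(rand_dna(sample(18:26, 1)), adapter)
    once <- trim_adapters(read, cfg)
    if (is.na(once)) next
    expect_equal(trim_adapters(once, cfg), once)
  }
})

test_that("collapsing counts multiplicities and orders tags deterministically", {
  s <- "ACGTACGTACGTACGTACGT"
  s2 <- "TTTTACGTACGTACGTACGT"
  tags <- collapse_reads(c(s, s, s), "s1")
  expect_equal(nrow(tags), 1L)
  expect_equal(tags$s1, 3L)
  tags <- collapse_reads(c(s, s2, s), "s1")
  expect_equal(tags$seq, c(s, s2))
  expect_equal(tags$s1, c(2L, 1L))
  # conservation
  set.seed(7)
  reads <- replicate(200, rand_dna(20))
  expect_equal(sum(collapse_reads(reads, "s1")$s1), length(reads))
})

test_that("contaminant filtering removes exact substrings on either strand", {
  trna <- c(trna1 = paste0("GGGCCCGTA", "ACGTGGCTTAAGCGTACGATC", "TTAGGCAT"))
  inside <- "ACGTGGCTTAAGCGTACGATC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(inside)))
  near <- paste0("T", substr(inside, 2, nchar(inside)))  # one base off
  tags <- make_tags(c(inside, rc, near))
  part <- filter_contaminants(tags, trna)
  expect_setequal(part$removed$seq, c(inside, rc))
  expect_equal(part$kept$seq, near)
  # kept and removed partition the input
  expect_setequal(c(part$kept$seq, part$removed$seq), tags$seq)
  expect_warning(filter_contaminants(tags, NULL), "no contaminant")
})

test_that("every read lands in exactly one partition and counts sum to input", {
  b <- sim_bundle_cached()
  pp <- preprocess_reads(b$reads$sample1, "sample1", b$preprocess, b$ncrna)
  lg <- pp$log
  expect_equal(lg$adapter_rejected + lg$n_rejected + lg$length_rejected +
                 lg$contaminant + lg$low_support + lg$survivor, lg$input)
  expect_equal(sum(pp$tags$sample1), lg$survivor)
  # reads with N are dropped, short inserts are dropped
  mixed <- c(paste0("ACGTACGTACGTNCGTACGT", adapter),
             paste0("ACGTACG", adapter),
             paste0("ACGTACGTACGTACGTACGT", adapter))
  lg2 <- preprocess_reads(mixed, "s1", cfg)$log
  expect_equal(lg2$n_rejected, 1L)
  expect_equal(lg2$length_rejected, 1L)
  expect_equal(lg2$survivor, 1L)
})

test_that("per-sample tag sets merge by sequence with zero fill", {
  a <- make_tags(c("AAACCCGGGTTTAAACCCGG", "CCCGGGTTTAAACCCGGGTT"),
                 c(5L, 1L), sample = "s1")
  b <- make_tags("AAACCCGGGTTTAAACCCGG", 2L, sample = "s2")
  merged <- merge_tag_sets(list(a, b))
  expect_equal(names(merged), c("tag_id", "seq", "s1", "s2"))
  expect_equal(merged$s2[merged$seq == "CCCGGGTTTAAACCCGGGTT"], 0L)
  expect_equal(sum(merged$s1), 6L)
  expect_equal(sum(merged$s2), 2L)
})
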