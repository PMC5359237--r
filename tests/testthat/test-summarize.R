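# constructed record set: 2 canonical 3a on H1, 1 non-canonical on H2, and
# one complex pair spanning H1/H3
constructed_records <- function() {
  rec <- sim_detection_cached()$records[0, ]
  row <- function(tag, hp, cclass, cat, group, count) {
    r <- data.frame(tag_id = tag, seq = strrep("A", 21), hairpin_id = hp,
                    mature_id = "m1", start = 10L, end = 31L,
                    templated = TRUE, canonical_class = cclass, drift5 = 0L,
                    drift3 = 1L, drift_category = cat,
                    substitution_class = "none", tail5 = "", tail3 = "",
                    seed_corrupt = FALSE, complex_group = group,
                    stringsAsFactors = FALSE)
    r$mismatch_positions <- list(integer())
    r <- r[, names(rec)[seq_len(17)]]
    r$s1 <- count
    r
  }
  out <- rbind(row("t1", "H1", "canonical", "3a", NA, 10L),
               row("t2", "H1", "canonical", "3a", NA, 4L),
               row("t3", "H2", "non_canonical", "3a", NA, 2L),
               row("t4", "H1", "complex", "3a", "cg0001", 1L),
               row("t4", "H3", "complex", "3a", "cg0001", 1L))
  attr(out, "samples") <- "s1"
  out
}

test_that("summary counts reproduce an independent hand tally", {
  stats <- summarize_isomirs(constructed_records())$templated
  # hand count: complex groups 1, canonical 2, non-canonical 1, total 4,
  # hairpins H1+H2+H3
  expect_equal(stats$total_isomirs, 4L)
  expect_equal(stats$complex_count, 1L)
  expect_equal(stats$canonical_count, 2L)
  expect_equal(stats$non_canonical_count, 1L)
  expect_equal(stats$hairpins_generating, 3L)
  expect_equal(stats$most_abundant_hairpin, "H1")   # 10 + 4 + 1 reads
  expect_equal(unname(stats$drift_counts["3a"]), 2L)
  expect_equal(sum(stats$drift_counts), stats$canonical_count)
})

test_that("summary identities hold on simulated detection output", {
  stats <- summarize_isomirs(sim_detection_cached()$records)
  for (s in stats) {
    expect_equal(s$total_isomirs,
                 s$complex_count + s$canonical_count + s$non_canonical_count)
    expect_equal(sum(s$drift_counts), s$canonical_count)
  }
  # empty records give all-zero summaries
  empty <- sim_detection_cached()$records[0, ]
  s0 <- summarize_isomirs(empty)$templated
  expect_equal(s0$total_isomirs, 0L)
  expect_equal(s0$most_abundant_hairpin, "")
})

test_that("abundance ratios sum to one per mature; singletons are omitted", {
  rec <- constructed_records()
  rec$mature_id <- c("mA", "mA", "mB", "mC", "mC")
  rec$s1 <- c(30L, 70L, 5L, 1L, 1L)
  ks <- ks_ratio_table(rec)
  expect_setequal(unique(ks$mature_id), c("mA", "mC"))   # mB has 1 isomiR
  expect_equal(sort(ks$ratio[ks$mature_id == "mA"]), c(0.3, 0.7))
  for (m in unique(ks$mature_id)) {
    expect_equal(sum(ks$ratio[ks$mature_id == m]), 1, tolerance = 1e-9)
  }
  # property on the full simulated output
  ks2 <- ks_ratio_table(sim_detection_cached()$records)
  sums <- tapply(ks2$ratio, ks2$mature_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("count-matrix export is exact and round-trips", {
  det <- sim_detection_cached()
  path <- withr::local_tempfile(fileext = ".tsv")
  cm <- export_count_matrix(det$records, path)
  expect_true(all(c("sample1", "sample2") %in% names(cm)))
  expect_equal(anyDuplicated(cm$id), 0L)
  i <- match(cm$id, det$records$tag_id)
  expect_equal(cm$sample1, det$records$sample1[i])
  back <- read_tsv(path)
  expect_equal(back$id, cm$id)
  expect_equal(back$sample1, cm$sample1)
})

test_that("DE intersection keeps ids in both top-k lists", {
  de <- data.frame(id = sprintf("t%02d", 1:20),
                   effect = seq(2, -2, length.out = 20),
                   adjusted_p = seq(0.001, 0.9, length.out = 20))
  expect_equal(intersect_de(de, de, k = 5)$id, de$id[1:5])
  other <- de
  other$id <- sprintf("u%02d", 1:20)
  expect_equal(nrow(intersect_de(de, other, k = 5)), 0L)
  # k beyond the table size intersects whole tables
  expect_equal(nrow(intersect_de(de, de, k = 100)), 20L)
  expect_error(intersect_de(de[, 1:2], de), "adjusted_p")
})

test_that("alignment views place every base at its hairpin coordinate", {
  b <- sim_bundle_cached()
  det <- sim_detection_cached()
  h <- det$records$hairpin_id[which(!det$records$templated)[1]]
  rec <- det$records[det$records$hairpin_id == h, ]
  attr(rec, "samples") <- attr(det$records, "samples")
  txt <- render_alignment(h, b$hairpins, b$annotations, rec)
  lines <- strsplit(txt, "\n")[[1]]
  expect_equal(trimws(lines[1]), b$hairpins[[h]])
  # column property: each isomiR core base matches the hairpin base at the
  # same column unless rendered lower-case
  off <- nchar(lines[1]) - nchar(sub("^ *", "", lines[1]))
  hp <- b$hairpins[[h]]
  for (ln in lines[-1]) {
    area <- sub(" *$", "", sub("  Mod=.*$", "", ln))
    body <- sub("^ *", "", area)
    left <- nchar(area) - nchar(body) - off
    chars <- strsplit(body, "", fixed = TRUE)[[1]]
    for (j in seq_along(chars)) {
      col <- left + j
      if (chars[j] %in% LETTERS && col >= 1 && col <= nchar(hp)) {
        expect_equal(chars[j], substr(hp, col, col))
      }
    }
  }
})

test_that("rendered views parse back to coordinates, tails and classes", {
  b <- sim_bundle_cached()
  det <- sim_detection_cached()
  for (h in unique(det$records$hairpin_id)) {
    rec <- det$records[det$records$hairpin_id == h, ]
    attr(rec, "samples") <- attr(det$records, "samples")
    parsed <- parse_rendered_alignment(
      render_alignment(h, b$hairpins, b$annotations, rec))
    expect_equal(parsed$hairpin, b$hairpins[[h]])
    expect_equal(parsed$isomirs$start, rec$start)
    expect_equal(parsed$isomirs$end, rec$end)
    expect_equal(parsed$isomirs$tail5, rec$tail5)
    expect_equal(parsed$isomirs$tail3, rec$tail3)
    expect_equal(parsed$isomirs$substitution_class, rec$substitution_class)
    expect_equal(parsed$isomirs$mismatch_positions, rec$mismatch_positions)
    expect_equal(parsed$isomirs$drift5, rec$drift5)
    expect_equal(parsed$isomirs$drift3, rec$drift3)
  }
  # records from a foreign hairpin are a contract violation
  rec <- det$records[1, ]
  expect_error(render_alignment(
    setdiff(unique(det$records$hairpin_id), rec$hairpin_id)[1],
    b$hairpins, b$annotations, rec), "different hairpin")
})
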