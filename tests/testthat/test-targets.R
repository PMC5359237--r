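revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

test_that("duplex penalties match the per-position summation oracle", {
  withr::with_seed(31, q <- rand_dna(21))
  site <- revcomp(q)
  expect_equal(score_duplex(q, site)$score, 0)

  # single mismatch at query position 5 costs 1.0 doubled in the 2-13 core
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  sc <- strsplit(site, "", fixed = TRUE)[[1]]
  # site position pairing query position i is 21 - i + 1 (reverse frame)
  j <- 21 - 5 + 1
  wobble <- switch(qc[5], G = "T", T = "G", "")
  bad <- setdiff(c("A", "C", "G", "T"), c(sc[j], wobble))
  mut <- sc
  mut[j] <- bad[1]
  mut_site <- paste(mut, collapse = "")
  got <- score_duplex(q, mut_site)$score
  expect_equal(got, 2.0)
  expect_equal(got, oracle_duplex_score(q, mut_site))

  # G:U wobble at query position 20 costs 0.5 (outside the doubled core)
  q2 <- q
  substr(q2, 20, 20) <- "G"
  s2 <- strsplit(revcomp(q2), "", fixed = TRUE)[[1]]
  s2[21 - 20 + 1] <- "T"
  s2 <- paste(s2, collapse = "")
  expect_equal(score_duplex(q2, s2)$score, 0.5)
  expect_equal(score_duplex(q2, s2)$score, oracle_duplex_score(q2, s2))
})

test_that("single-bulge alignments minimize over the bulge placement", {
  withr::with_seed(32, q <- rand_dna(21))
  site <- revcomp(q)
  for (pos in c(1, 5, 12, 21)) {
    # query bulge: delete the site base pairing query position pos
    del <- paste0(substr(site, 1, 21 - pos), substr(site, 23 - pos, 21))
    expect_equal(score_duplex(q, del)$score, oracle_duplex_score(q, del))
    # site bulge: insert a base into the site
    ins <- paste0(substr(site, 1, pos), "A", substr(site, pos + 1, 21))
    expect_equal(score_duplex(q, ins)$score, oracle_duplex_score(q, ins))
  }
  # beyond the bulge budget there is no score
  expect_null(score_duplex(q, substr(site, 1, 19)))
})

test_that("adding a mismatch never decreases the penalty", {
  withr::with_seed(33, q <- rand_dna(21))
  site <- revcomp(q)
  sc <- strsplit(site, "", fixed = TRUE)[[1]]
  prev <- 0
  for (j in c(3, 8, 15, 19)) {
    sc[j] <- setdiff(c("A", "C", "G", "T"), sc[j])[1]
    cur <- score_duplex(q, paste(sc, collapse = ""))$score
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("transcript scans find planted sites and match full enumeration", {
  withr::with_seed(34, {
    q <- rand_dna(21)
    left <- rand_dna(130)
    right <- rand_dna(140)
  })
  tr <- c(tx1 = paste0(left, revcomp(q), right))
  hits <- find_targets("q1", q, tr)
  expect_equal(hits$score[1], 0)
  expect_equal(hits$start[1], 131L)
  expect_equal(hits$end[1], 151L)
  # cleavage opposite query positions 10-11
  expect_equal(hits$cleavage_pos[1], 151L - 9L)

  # independent full enumeration over every window and length
  cfg <- target_config()
  expected <- list()
  lt <- nchar(tr[[1]])
  for (wlen in 20:22) {
    for (s in seq_len(lt - wlen + 1)) {
      sc <- oracle_duplex_score(q, substr(tr[[1]], s, s + wlen - 1))
      if (!is.null(sc) && sc <= cfg$max_score) {
        expected[[length(expected) + 1L]] <- c(s, s + wlen - 1, sc)
      }
    }
  }
  expected <- do.call(rbind, expected)
  expected <- expected[order(expected[, 3], expected[, 1], expected[, 2]), ,
                       drop = FALSE]
  expect_equal(nrow(hits), nrow(expected))
  ord <- order(hits$score, hits$start, hits$end)
  expect_equal(hits$start[ord], as.integer(expected[, 1]))
  expect_equal(hits$end[ord], as.integer(expected[, 2]))
  expect_equal(hits$score[ord], expected[, 3])

  # a random transcript with no acceptable window yields no hits
  withr::with_seed(35, noise <- c(tx = rand_dna(300)))
  q_allA <- strrep("A", 21)
  expect_equal(nrow(find_targets("q", q_allA, noise,
                                 target_config(max_score = 0))), 0L)
})

test_that("degradome categories follow the 0-4 evidence ladder", {
  prof <- integer(50)
  prof[20] <- 5L
  expect_equal(degradome_categorize(20L, prof)$category, 0L)  # unique max
  prof[33] <- 5L
  expect_equal(degradome_categorize(20L, prof)$category, 1L)  # tied max
  # constructed profile d = {c: 3, x1: 3, x2: 1} -> tied maximum
  prof2 <- integer(50)
  prof2[c(10, 25)] <- 3L
  prof2[40] <- 1L
  expect_equal(degradome_categorize(10L, prof2)$category, 1L)
  # above the median of positive positions but not the maximum
  prof3 <- integer(50)
  prof3[10] <- 9L
  prof3[c(20, 30, 40)] <- c(3L, 1L, 1L)
  expect_equal(degradome_categorize(20L, prof3)$category, 2L)
  expect_equal(degradome_categorize(30L, prof3)$category, 4L)  # single read
  prof3[30] <- 2L   # > 1 but at/below the median (median of 9,3,2,1 = 2.5)
  expect_equal(degradome_categorize(30L, prof3)$category, 3L)
  expect_true(is.na(degradome_categorize(45L, prof3)$category))
  expect_equal(degradome_categorize(45L, prof3)$reads, 0L)
})

test_that("the category function is total over fuzzed profiles", {
  withr::with_seed(36, {
    for (i in 1:100) {
      prof <- integer(30)
      k <- sample(0:6, 1)
      if (k > 0) prof[sample(30, k)] <- sample(1:8, k, replace = TRUE)
      pos <- sample(30, 1)
      g <- degradome_categorize(pos, prof)
      expect_true(is.na(g$category) || g$category %in% 0:4)
      expect_equal(g$reads, prof[pos])
    }
  })
})

test_that("PARE profiles accumulate exact 5'-end matches only", {
  tr <- paste0(strrep("A", 30), "CCGGTTCCGGAACCGGTTAA", strrep("T", 30))
  tags <- make_tags(c("CCGGTTCCGGAACCGGTTAA", "GGGGGGGGGGGGGGGGGGGG"),
                    counts = c(3L, 2L), sample = "pare")
  pp <- pare_profile(tags, tr)
  expect_equal(pp$profile[31], 3L)
  expect_equal(sum(pp$profile), 3L)
  expect_equal(pp$unmatched, 1L)
})

test_that("degradome grading integrates with prediction on simulated data", {
  b <- sim_bundle_cached()
  queries <- setNames(as.character(b$matures[b$target_truth$query_id]),
                      b$target_truth$query_id)
  hits <- predict_targets(queries, b$transcripts, b$pare)
  perfect <- hits[hits$score == 0, ]
  i <- match(b$target_truth$query_id, perfect$query_id)
  expect_false(any(is.na(i)))
  expect_equal(perfect$transcript_id[i], b$target_truth$transcript_id)
  expect_equal(perfect$start[i], b$target_truth$start)
  expect_equal(perfect$cleavage_pos[i], b$target_truth$cleavage_pos)
  # the first two transcripts carry a unique dominant peak, the rest share
  # the maximum with a decoy
  expect_equal(perfect$degradome_category[i][1:2], c(0L, 0L))
  expect_true(all(perfect$degradome_category[i][3:4] == 1L))
})
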