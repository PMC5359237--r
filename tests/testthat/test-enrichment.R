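make_annotation <- function(n_genes, terms) {
  # terms: named list term -> gene indices
  rows <- lapply(names(terms), function(tm) {
    data.frame(gene_id = sprintf("g%02d", terms[[tm]]), go_id = tm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("upper-tail p matches the exact combinatorial value", {
  # N = 10, K = 5, n = 4, observed 4: C(5,4) C(5,0) / C(10,4) = 5/210
  ann <- make_annotation(10, list("GO:0000001" = 1:5, "GO:0000002" = 1:10))
  study <- sprintf("g%02d", 1:4)
  background <- sprintf("g%02d", 1:10)
  enr <- enrich_go(study, background, ann)
  expect_equal(enr$p[enr$term == "GO:0000001"], 5 / 210)
  # the whole-background term is never enriched
  expect_equal(enr$p[enr$term == "GO:0000002"], 1)
})

test_that("degenerate studies give p = 1 everywhere", {
  ann <- make_annotation(8, list("GO:0000001" = 1:3, "GO:0000002" = 2:7))
  bg <- sprintf("g%02d", 1:8)
  enr <- enrich_go(bg, bg, ann)                  # study == background
  expect_true(all(enr$p == 1))
  enr0 <- enrich_go(sprintf("g%02d", 7:8), bg,
                    make_annotation(8, list("GO:0000001" = 1:3,
                                            "GO:0000002" = 1:8)))
  expect_equal(enr0$p[enr0$term == "GO:0000001"], 1)  # observed 0 -> p = 1
})

test_that("enumeration of all draws reproduces the reported p for small N", {
  # first validate the combinatorial oracle against literal draw enumeration
  for (N in c(6L, 8L, 10L)) {
    for (K in c(2L, N %/% 2L)) {
      for (n in c(2L, N %/% 2L)) {
        for (x in 0:min(K, n)) {
          expect_equal(oracle_hyper_upper(x, K, N, n),
                       oracle_hyper_enum(x, K, N, n), tolerance = 1e-12)
        }
      }
    }
  }
  # then check the package's p against the oracle across N <= 20
  for (N in c(5L, 9L, 14L, 20L)) {
    for (K in unique(c(3L, N %/% 2L, N - 1L))) {
      for (n in unique(c(2L, N %/% 3L + 1L, N - 2L))) {
        if (n < 1L) next
        ann <- make_annotation(N, setNames(list(1:K), "GO:0000001"))
        bg <- sprintf("g%02d", 1:N)
        study <- sprintf("g%02d", sample(N, n))
        enr <- enrich_go(study, bg, ann, min_term_size = 1L)
        x <- sum(study %in% sprintf("g%02d", 1:K))
        expect_equal(enr$p[enr$term == "GO:0000001"],
                     oracle_hyper_upper(x, K, N, n), tolerance = 1e-12)
      }
    }
  }
})

test_that("more study hits never increase the p-value", {
  ps <- vapply(0:6, function(x) oracle_hyper_upper(x, 6L, 15L, 6L), 0)
  ann <- make_annotation(15, setNames(list(1:6), "GO:0000001"))
  bg <- sprintf("g%02d", 1:15)
  got <- vapply(0:6, function(x) {
    study <- sprintf("g%02d", c(seq_len(x), 6L + seq_len(6L - x)))
    enr <- enrich_go(study, bg, ann, min_term_size = 1L)
    enr$p[1]
  }, 0)
  expect_true(all(diff(got) <= 1e-12))
  expect_true(all(diff(ps) <= 0))
})

test_that("FDR equals the hand step-up and dominates p", {
  # validate the helper on a frozen 10-value example first
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.368)
  expect_equal(oracle_bh(p),
               c(0.01, 0.04, 0.084, 0.084, 0.084, 0.1, 0.74 / 7,
                 2.12 / 9, 2.12 / 9, 0.368),
               tolerance = 1e-12)
  # then the package's fdr column must match the step-up on its own p's
  withr::with_seed(81, {
    terms <- setNames(lapply(1:10, function(i) sample(20, sample(3:12, 1))),
                      sprintf("GO:%07d", 1:10))
  })
  ann <- make_annotation(20, terms)
  bg <- sprintf("g%02d", 1:20)
  enr <- enrich_go(sprintf("g%02d", 1:6), bg, ann)
  expect_equal(enr$fdr, oracle_bh(enr$p))
  expect_true(all(enr$fdr >= enr$p - 1e-15))
  expect_true(all(diff(enr$fdr[order(enr$p)]) >= -1e-15))
})

test_that("study genes outside the background are named in the error", {
  ann <- make_annotation(5, list("GO:0000001" = 1:5))
  expect_error(enrich_go(c("g01", "gX"), sprintf("g%02d", 1:5), ann), "gX")
})

test_that("small terms are skipped and the annotation reader validates ids", {
  ann <- make_annotation(10, list("GO:0000001" = 1:2, "GO:0000002" = 1:5))
  enr <- enrich_go(sprintf("g%02d", 1:3), sprintf("g%02d", 1:10), ann,
                   min_term_size = 3L)
  expect_false("GO:0000001" %in% enr$term)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tGO:0006950", "g1\tGO:0006950", "g2\tGO:0008150"), path)
  g2g <- read_gene2go(path)
  expect_equal(nrow(g2g), 2L)   # duplicates collapsed
  writeLines("g1\tGO:abc", path)
  expect_error(read_gene2go(path), "malformed GO id")
})
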