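# Independent oracles, implemented before (and independently of) the code
# paths they check.

# Brute-force double-loop Hamming scan: every placement of `tag` on every
# reference with at most `k` mismatches.
oracle_map_tag <- function(tag, references, k) {
  tc <- strsplit(tag, "", fixed = TRUE)[[1]]
  l <- length(tc)
  rows <- list()
  for (rid in names(references)) {
    rc <- strsplit(references[[rid]], "", fixed = TRUE)[[1]]
    L <- length(rc)
    if (L < l) next
    for (s in 0:(L - l)) {
      pos <- which(rc[(s + 1L):(s + l)] != tc) - 1L
      mm <- length(pos)
      if (mm <= k) {
        row <- data.frame(hairpin_id = rid, start = s, end = s + l,
                          n_mismatch = mm, stringsAsFactors = FALSE)
        row$mismatch_positions <- list(pos)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(hairpin_id = character(), start = integer(),
                      end = integer(), n_mismatch = integer(),
                      stringsAsFactors = FALSE)
    out$mismatch_positions <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$n_mismatch, out$hairpin_id, out$start), ]
  rownames(out) <- NULL
  out
}

# Per-position penalty summation over all <=1-gap alignments of a duplex,
# enumerated explicitly: the query (5'->3') against the reversed site, a
# gap optionally inserted at each position of either strand.
oracle_pair_penalty <- function(q, t) {
  if ((q == "A" && t == "T") || (q == "T" && t == "A") ||
      (q == "G" && t == "C") || (q == "C" && t == "G")) return(0)
  if ((q == "G" && t == "T") || (q == "T" && t == "G")) return(0.5)
  1
}

oracle_duplex_score <- function(query, site, core = c(2L, 13L)) {
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  sc <- rev(strsplit(site, "", fixed = TRUE)[[1]])
  L <- length(qc)
  S <- length(sc)
  wt <- function(i) if (i >= core[1L] && i <= core[2L]) 2 else 1
  straight <- function(qv, sv) {
    # qv, sv equal length; "-" marks a gap
    total <- 0
    qi <- 0L
    for (i in seq_along(qv)) {
      if (qv[i] != "-") qi <- qi + 1L
      if (qv[i] == "-") {
        total <- total + wt(min(qi + 1L, L))      # site bulge: next query pos
      } else if (sv[i] == "-") {
        total <- total + wt(qi)                   # query bulge
      } else {
        total <- total + wt(qi) * oracle_pair_penalty(qv[i], sv[i])
      }
    }
    total
  }
  best <- Inf
  if (S == L) {
    best <- straight(qc, sc)
  } else if (S == L - 1L) {
    for (b in seq_len(L)) {
      sv <- append(sc, "-", after = b - 1L)
      best <- min(best, straight(qc, sv))
    }
  } else if (S == L + 1L) {
    for (b in seq_len(S)) {
      qv <- append(qc, "-", after = b - 1L)
      best <- min(best, straight(qv, sc))
    }
  } else {
    return(NULL)
  }
  best
}

# Exact upper-tail hypergeometric probability by combinatorial summation.
oracle_hyper_upper <- function(x, K, N, n) {
  js <- x:min(K, n)
  js <- js[js >= max(0L, n - (N - K))]
  if (length(js) == 0L) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Exact upper-tail hypergeometric probability by enumerating every draw of
# n items from N (feasible for small N).
oracle_hyper_enum <- function(x, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # items 1..K carry the label
  mean(hits >= x)
}

# Benjamini-Hochberg step-up, written as the textbook procedure.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (r in n:1) {
    prev <- min(prev, p[o[r]] * n / r)
    adj[o[r]] <- prev
  }
  adj
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
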