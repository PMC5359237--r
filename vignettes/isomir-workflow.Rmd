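---
title: "Detecting and classifying plant isomiRs with isomirkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying plant isomiRs with isomirkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomirkit)
```

## The problem

Mature plant miRNAs are excised from stem-loop precursors (pre-miRNAs) by
Dicer-Like enzymes. Cleavage is imprecise, and matured small RNAs are
further edited and tailed post-transcriptionally, so a sequencing library
contains a cloud of variants around each canonical miRNA — *isomiRs*.
isomirkit detects these variants from small RNA-seq reads and classifies
each one along four axes:

* **templated vs non-templated** — a templated isomiR matches the hairpin
  exactly (its length variation is encoded in the precursor); a
  non-templated isomiR carries nucleotides absent from the hairpin at its
  aligned position, either terminal tails (uridylation/adenylation by
  nucleotidyl transferases) or substitutions;
* **canonical vs non-canonical vs complex** — canonical isomiRs overlap the
  annotated mature miRNA by at least `min_overlap` nucleotides;
  non-canonical isomiRs map elsewhere on the hairpin (loop, star-arm
  flank); complex isomiRs have equally good placements on more than one
  hairpin;
* **end drift** — the signed offsets of the isomiR's 5' and 3' ends
  relative to the canonical ends give nine categories (`5a`, `3a`, `5d`,
  `3d`, their four combinations and `no_drift`), with positive drift an
  extension and negative a truncation;
* **substitution class** — `MS` (internal random SNPs), `TS` (internal
  tandem, i.e. adjacent, SNPs), `CV` (internal plus terminal), `5V`/`3V`
  (terminal-only at one end) and `5V3V` (terminal at both ends).

Because 5' drift shifts the seed region (positions `seed_start` to
`seed_end` of the molecule's own 5' end, default 2-8) that dominates target
recognition, every anchored record also carries a *seed-corrupt* flag: the
isomiR's seed window is compared with the canonical seed window and flagged
when the edit count exceeds `seed_corrupt_tolerance` (default 0). The exact
rule behind published "seed corrupt" flags is not standardized; this
edit-count rule is this package's documented choice, and both the window
and the tolerance are configurable.

## The detection procedure

The pipeline follows the standard isomiR workflow:

1. **Preprocessing** (`preprocess_reads()`). 3'/5' adapters are located by
   the best Hamming match over candidate overlaps (overlap at least
   `min_adapter_overlap` = 6, mismatch rate at most
   `max_adapter_mismatch_rate` = 0.1; lowest rate, then longest overlap,
   then leftmost position wins). A transparent deterministic rule was
   preferred over a heuristic local aligner so that every trimming decision
   is exactly reproducible. Reads containing `N` are dropped (mismatch
   semantics with `N` are ambiguous), survivors are length-filtered to
   `[min_len, max_len]` = [18, 26] nt — the usual plant small-RNA window —
   and collapsed into unique tags with per-sample counts. Tags occurring as
   exact substrings (either strand) of the contaminant reference
   (rRNA/tRNA/snoRNA-style sequences) are removed; exact matching is
   deliberately conservative, since mismatch-tolerant contaminant screens
   risk eating genuine isomiRs. Every read is accounted for in exactly one
   partition and the run log proves it.

2. **Templated detection** (`map_tag()`, `classify_templated()`). Tags are
   aligned to the hairpins exhaustively at every offset with zero
   mismatches, forward strand only (matures are annotated on the hairpin
   sense strand). The aligner enumerates all placements and orders them
   totally, so reruns are byte-identical; a brute-force double-loop scan
   serves as its oracle in the test suite. Among a tag's placements,
   `best_hits()` keeps those minimizing (mismatch count, end-drift
   magnitude to the nearest annotated mature, total tail length), breaking
   ties within one hairpin by the smallest start. This tie order is a
   design choice — published descriptions say only "best hits". Survivors
   spanning several hairpins become *complex* records sharing a group id
   and counting once in every total. Drift is measured against the mature
   with maximal overlap; a zero-drift perfect match is the canonical miRNA
   itself and is excluded from isomiR tables.

3. **Genome screen** (`genome_filter()`). Tags that fail 0-mismatch hairpin
   mapping but match the genome exactly (substring, either strand) are set
   aside: they are more parsimoniously explained as fragments of other
   loci than as non-templated isomiRs, and removing them lowers the
   non-templated false-positive rate. Without a genome the screen is a
   logged no-op.

4. **Non-templated detection** (`run_detection()` step 1). Remaining tags
   are remapped allowing mismatches. The raw mapper budget is
   `max_internal_snps + 2 * max_terminal_subs`, reconciling the per-category
   caps (defaults: 1 internal SNP, 6 terminal substitutions per end — the
   published benchmark settings) with a single mapping pass; the
   substitution classifier then enforces the caps on the winning placement
   and assigns `MS`/`TS`/`CV`/`5V`/`3V`/`5V3V`. Best hits are selected
   before classification. A both-ends terminal pattern is reported as its
   own class `5V3V` rather than folded into `CV`. Note that `TS` requires
   at least two internal mismatches, so it is unreachable at the default
   internal cap of 1; studies interested in tandem SNPs should raise
   `max_internal_snps` to 2, as the bundled simulator configuration does.

5. **Recursive trim-and-remap** (step 2). Tags still unplaced are trimmed
   one nucleotide at a time — trim pairs (i from 5', j from 3') enumerated
   by increasing total up to `r_max_trim` = 3, preferring 3'-side trims at
   equal totals, since 3' tailing is the dominant biological mechanism —
   and the core is remapped requiring zero mismatches. The first success
   wins; trimmed letters become the non-templated tail (rendered
   lower-case), and drift counts tails as additions. Cores shorter than
   `min_len` or overlapping the mature by less than `min_overlap` fall
   through. Substitutions and tails are never stacked: a tag needing both
   is reported `unclassifiable` rather than guessed, which avoids a
   combinatorial explosion of explanations. One consequence of running the
   mismatch step before the trim step (the published order) is that a
   short tail over a templated continuation at an interior mature is
   indistinguishable from a terminal substitution run; tails are only
   provably tails where the placement cannot be extended (e.g. matures
   flush with a hairpin end).

Every tag ends in exactly one fate — `exact_canonical`,
`templated_isomiR`, `nontemplated_isomiR`, `genome_filtered`,
`unclassifiable` — and the audit table sums to the tag count.

## Downstream stages

`summarize_isomirs()` reproduces the standard summary: totals obey
`total = complex + canonical + non_canonical` and the drift categories
partition the canonical records within each stratum — arithmetic identities
that hold by construction and are asserted on every run. The most abundant
hairpin maximizes summed isomiR read counts (an alternative reading —
distinct isomiR count — exists; read counts were chosen because the
quantity describes abundance). `ks_ratio_table()` gives, for every mature
with more than one isomiR, each isomiR's share of the mature's isomiR
reads (read counts, not distinct-variant counts). `render_alignment()`
draws hairpin, mature and isomiRs in fixed-width columns with
non-templated bases lower-cased, and is exactly invertible by
`parse_rendered_alignment()`. `export_count_matrix()` feeds external
differential-expression tools; their result tables come back through
`intersect_de()`, which intersects top-k lists (rank by adjusted p, then
absolute effect). DE model fitting itself is deliberately out of scope.

**Target prediction** (`find_targets()`) scores miRNA-transcript duplexes
with the de-facto plant penalty scheme: mismatch 1.0, G:U wobble 0.5,
bulged nucleotide 1.0, all doubled across query positions 2-13, at most
one bulge, cutoff 4.0 — all config-exposed, since the wrapped tools this
stage replaces never printed their constants in one place. The transcript
scan is a prefix/suffix-sum formulation of the single-bulge alignment,
kept exactly equivalent to scoring every window independently (the test
suite enforces this by full enumeration). A site bulge is weighted by the
query position that follows it; ties between bulge placements resolve to
the bulge-free or leftmost alignment. **Degradome evidence**
(`degradome_categorize()`): PARE reads mark decay-fragment 5' ends by
exact forward-strand matching; the count at the position opposite query
positions 10-11 is graded on the conventional ladder — unique maximum (0),
tied maximum (1), above the median of occupied positions (2), more than
one read otherwise (3), a single read (4), no read (none).

**GO enrichment** (`enrich_go()`) is classic per-term over-representation:
exact upper-tail hypergeometric p (via `phyper`) with Benjamini-Hochberg
FDR (via `p.adjust`), terms smaller than `min_term_size` = 3 skipped, the
background defaulting to all annotated genes. Graph-decorrelation
algorithms (elim/weight-style) are out of scope; pre-propagated
annotations pass through the same interface.

## The simulator, and what passing tests do and do not show

`simulate_bundle()` generates the entire study the tests run on: 20
hairpins of 120 nt with 21-nt matures (4 flush with the 3' end, 4 with the
5' end, the rest centered), a genome embedding every hairpin between 60-nt
flanks, 5 contaminant sequences, and — per taxonomy class — 4 distinct
tags at 15 reads each, split over two samples with a 21-nt 3' adapter
appended, for 1,200 reads over 20 classes covering every drift category,
every substitution class, 5'/3' tails (poly-T with probability 0.7, the
uridylation analogue, else poly-A), contaminant fragments, genomic
background and unmappable sequence. Transcripts carry perfect
reverse-complement sites for four matures; PARE reads are planted at the
implied cleavage positions; a gene-to-GO table carries one genuinely
enriched term.

Every planted read is constructed to be *unambiguous* and the guarantees
are asserted structurally at generation time with rejection sampling
(matures occur exactly once across hairpins; substituted tags have a
unique best placement with the planted pattern; tails differ from the
genomic continuation, sit at hairpin-edge matures, and defeat the
mismatch-remap step; unmappable tags defeat every step), so any seed
yields a valid bundle. On this data the pipeline attains per-cell
precision and recall of 1.0 — which validates the logic, not the biology.
Real libraries contain sequencing errors, quality artefacts, repetitive
hairpin families, A-to-I edits and genuinely ambiguous reads the simulator
deliberately omits; on real data the `unclassifiable` and `complex`
buckets, and the tail/terminal-substitution conflation noted above, carry
the corresponding uncertainty.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open internally and 1-based inclusive in
every written file. Sequences are upper-case DNA internally (U is
normalized to T on read; writers can restore U). Ratio tables sum to 1
within 1e-9 per mature. Empty inputs yield empty, well-formed outputs
(header-only tables, zeroed audits). All orderings are total — (mismatch,
hairpin, position) for alignments, (count, sequence) for tag ids, (score,
transcript, position) for target hits, (p, term) for enrichment — so
identical inputs give byte-identical outputs; the only timestamps live in
the run manifest.

## Problem sizes

The bundled test and acceptance runs use the simulator's defaults: 20
hairpins, 1,200 reads, 500 randomized mapper-oracle instances, all 63
single-substitution plus all single-bulge 21-nt duplex variants,
hypergeometric checks across background sizes up to 20, and two complete
pipeline executions for the determinism check — sizes chosen so the whole
validation reads as a single short run while still exercising every code
path.

## A worked example

```{r example, eval = FALSE}
library(isomirkit)

bundle <- simulate_bundle(simulate_config(seed = 1), out_dir = "bundle")
cfg <- list(
  hairpins = "bundle/hairpin.fa", mature = "bundle/mature.fa",
  reads = list(sample1 = "bundle/reads_sample1.fastq",
               sample2 = "bundle/reads_sample2.fastq"),
  genome = "bundle/genome.fa", contaminants = "bundle/ncrna.fa",
  transcripts = "bundle/cdna.fa", pare = "bundle/pare.fa",
  gene2go = "bundle/gene2go.tsv",
  preprocess = list(adapter3 = "TGGAATTCTCGGGTGCCAAGG"),
  detect = list(max_internal_snps = 2))
res <- run_all(cfg, "results")
res$stats$templated$total_isomirs
```

## Known limitations

Indel alignment inside the mapped core is not modelled (the taxonomy uses
end-trimming and substitutions only); hairpin secondary structure is never
folded; de-novo miRNA discovery, quality-aware trimming, thermodynamic
duplex scoring and genome-wide degradome peak discovery are out of scope;
and DE models are consumed, never fitted.
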