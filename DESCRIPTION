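Package: isomirkit
Title: Detection, Classification and Functional Annotation of Plant isomiRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained workflow for profiling microRNA variants
    (isomiRs) from plant small RNA-seq libraries. Reads are adapter-trimmed,
    collapsed into unique tags, cleared of rRNA/tRNA/snoRNA contaminants and
    aligned exhaustively to pre-miRNA hairpins. Tags are classified into the
    full isomiR taxonomy: templated versus non-templated, canonical versus
    non-canonical versus complex (multi-hairpin), signed 5'/3' end-drift
    categories, internal and terminal substitution classes (MS, TS, CV, 5V,
    3V, 5V3V), recovered non-templated tails, and seed-corruption flags.
    Downstream stages provide summary statistics, per-miRNA abundance-ratio
    tables, text alignment views, count-matrix export, intersection of
    externally computed differential-expression results, plant-style miRNA
    target scoring with degradome (PARE) cleavage-evidence categories, and
    hypergeometric GO term over-representation. A deterministic simulator
    generates fully labelled synthetic fixture bundles for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
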