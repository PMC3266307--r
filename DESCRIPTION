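Package: probemap
Title: Scoring and Selection of Microarray Probe Sets for One-to-One
    Gene Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores Affymetrix-style expression microarray probe sets for
    specificity (cross-hybridization), splice-isoform coverage, and
    robustness to 3'-biased target degradation, then selects one optimal
    probe set per gene to obtain an unambiguous gene to probe-set mapping.
    Includes a seeded ungapped local aligner with Karlin-Altschul bit
    scores calibrated to BLASTN-equivalent alignment tiers, an ingest path
    for precomputed BLAST tabular hits, and a synthetic fixture generator
    with analytically known ground-truth scores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
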