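Package: aprtools
Title: Sequence and Structure Analysis of Protein Aggregation Prone Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing aggregation prone regions (APRs) in protein
    sequences and structures. Provides randomized and scrambled sequence null
    datasets with composition chi-square comparisons, gate-keeper residue
    profiling and normalized aggregation propensities, APR conservation
    scoring in homologue alignments, order/disorder contingency analysis
    with odds ratios, a Shrake-Rupley solvent accessible surface area engine
    with segment burial and solvent-isolatedness metrics, a decoy-residue
    permutation null for catalytic-residue/APR structural proximity, a
    synthetic-data generator with known ground truth for every stage, and a
    rule engine ranking APRs as protein-solubility mutation targets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
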