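Package: poolgwas
Title: Pooled-DNA GWAS Analysis for Immune Thrombocytopenia Susceptibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for a two-stage pooled-DNA genome-wide
    association study of immune thrombocytopenia (ITP). Stage one estimates
    relative allele frequencies (RAF) from two-channel pooled-array
    fluorescence intensities, applies array quality control, and tests
    case-control allele-frequency differences with a combined Z-test whose
    denominator carries both binomial pool-sampling variance and
    replicate-array error. Hits are prioritized with odds ratios, false
    positive report probabilities (FPRP), and window-based SNP-to-gene
    mapping, and the resulting gene set is tested for KEGG-style pathway
    over-representation with an exact hypergeometric tail and
    Benjamini-Hochberg adjustment. Stage two reproduces the validation-cohort
    statistics: Hardy-Weinberg tests, 2x3 genotype association, allelic odds
    ratios with Haldane-Anscombe correction, glucocorticoid-response
    classification and association, and per-timepoint platelet-trajectory
    comparison. A seeded synthetic-data generator with known ground truth
    stands in for the raw array deposit so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
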