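Package: spectralcounts
Title: Differential Abundance and Pathway-Frequency Prioritization for
    Label-Free Spectral-Count Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for prioritizing proteins from label-free
    shotgun proteomics spectral counts in two-condition designs (for example
    patient-derived versus healthy brain organoids). Implements two-peptide
    protein inference, a detection-based variation filter, a calibrated
    generalized-log (arsinh) variance-stabilizing transform, differential
    abundance with a reproducibility-optimized test statistic (bootstrap
    top-list overlap optimization, permutation p-values and permutation FDR),
    absolute gene-set enrichment analysis with gene-label permutation nulls
    and leading-edge extraction, a protein frequency statistic across enriched
    pathway components with nearest-rank percentile selection, fold-change and
    spectral-count filter cascades, and disease-library over-representation.
    A negative-binomial simulator with planted differential proteins and
    planted gene sets makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
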