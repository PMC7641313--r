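Package: ImputeBenchMS
Title: Benchmarking Missing-Value Imputation for Quantitative Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarks missing-value imputation methods on bottom-up
    proteomics quantification matrices. Extracts a complete submatrix from
    a feature-by-sample intensity table, injects artificial missing values
    (uniform or left-censored), runs a suite of imputation algorithms
    (single-value, left-censored, neighbour-, regression- and
    covariance-based), and scores every result with four classic criteria
    (NRMSE, NRMSE-based sum of ranks, original-vs-imputed correlation,
    Procrustes superposition of PCA sample scores) and four
    proteomics-specific co-expression criteria (within-charge-state,
    within-protein, within-complex and within-PPI-cluster average pairwise
    correlation). Scores are normalized and methods ranked per criterion
    family. The chosen imputation can be propagated into two-group
    differential-expression analysis with a replicate-subsampling
    simulation. A synthetic-data generator with hierarchical correlation
    structure (charge states within peptides within proteins within
    complexes) makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    MASS,
    rpart,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Preprocessing, Software
RoxygenNote: 7.3.3
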