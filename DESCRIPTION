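Package: indirectRI
Title: Pediatric Reference Intervals by Direct and Indirect Sampling
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Establishes pediatric reference intervals (RIs) from routine
    laboratory-information-system (LIS) records by indirect sampling and
    compares them against a direct healthy-reference sample. Implements the
    full workflow: record cleaning (earliest-record deduplication, age
    filtering, decision-tree age/sex partitioning, Box-Cox normalization with
    maximum-likelihood lambda, Tukey-fence outlier removal, and a radical
    multi-analyte exclusion strategy), affine between-analyzer transference
    with map composition, partitioning of potential healthy individuals by a
    three-component univariate Gaussian mixture fitted by EM and by a 3x1
    batch self-organizing map with PCA initialization, nonparametric
    percentile reference limits with rank-based 90% confidence intervals, and
    bias-ratio assessment of indirect against direct limits. A synthetic-data
    generator emulates correlated creatinine/urea/uric-acid populations with
    pathological contamination and repeat visits, providing ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
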