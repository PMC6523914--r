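Package: dmrscan
Title: Differentially Methylated Region Detection with Kernel Distance
    and Binomial Scan Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects differentially methylated regions (DMRs) from
    bisulfite-sequencing count data using two complementary region-level
    tests: a nonparametric kernel distance statistic with a tri-weight
    kernel that down-weights site pairs by genomic distance, and a
    likelihood-based binomial spatial scan statistic over moving windows
    of variable size.  Both tests operate on covariate-adjusted
    methylation counts from a pooled logistic regression, use permutation
    of subject group labels for inference, and for the scan statistic a
    design-effect correction for read clustering within CpG sites.  A
    Gaussian-copula beta-binomial simulator with distance-decaying
    inter-site correlation generates synthetic datasets for calibration
    (type-I error) and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
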