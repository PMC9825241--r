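Package: vasca
Title: Variable-Selection ANOVA Simultaneous Component Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: ANOVA simultaneous component analysis (ASCA+) for designed
    multivariate experiments, with permutation-based significance testing and
    a variable-selection extension (VASCA) that embeds step-up variable
    selection inside the permutation loop. Includes least-squares
    factorization of a data matrix by a sum/deviation-coded design, SSQ and
    F-ratio test statistics, per-variable permutation p-values with
    Benjamini-Hochberg correction as a false-discovery-rate baseline, a
    leverage/SPE (ASCA-genes style) baseline, PCA visualization of effect
    matrices with bootstrap significance intervals for loadings, and a
    simulation suite with a correlated-background generator for Type-I-error
    and power benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
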