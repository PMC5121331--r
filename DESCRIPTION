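Package: clonedd
Title: Clonal Division Destiny Analysis for Lymphocyte Family Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the concordance of division destiny (the generation at
    which an activated lymphocyte returns to quiescence) within clonal families
    measured by multiplex division-tracking flow cytometry. Implements a
    beta-binomial correlated family-tree model with full-tree enumeration,
    binomial sampling of observed subtrees, clonal range distributions and
    maximum-likelihood estimation of the within-family correlation; a
    tree-concatenation algebra in which quiescent-cell generation counts of a
    summed tree are the convolution of the inputs, with linear mean and maximum
    division-destiny statistics; a test of independent additivity of
    costimulatory signals based on convolution of empirical distribution
    functions, percentile-bootstrap bands and a delta-method chi-squared
    statistic with pseudo-inverse covariance; a synthetic clone-table generator
    emulating the assay (binomial recovery, quiescence misclassification,
    harvest-time truncation); and desk-scale extrapolation of clonal
    contributions to in vivo responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
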