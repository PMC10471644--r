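Package: benthicpufa
Title: PUFA Content of Littoral Macroinvertebrate Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links environmental drivers of boreal lakes to the polyunsaturated
    fatty acid (PUFA) content of their littoral macroinvertebrate communities.
    Provides quartile-based ordinal classification (classes 1-5) of taxon-specific
    arachidonic acid (ARA), eicosapentaenoic acid (EPA) and docosahexaenoic acid
    (DHA) mass fractions; community-level PUFA response variables (abundance- and
    content-weighted indices, counts and percentages of PUFA-rich taxa); one-way
    permutational analysis of variance with pseudo-F, Monte-Carlo p-values and
    components-of-variation effect sizes; a hierarchical Bayesian analysis of
    covariance with nested site-in-lake intercepts, zero-sum categorical effects,
    adaptive random-walk Metropolis sampling, convergence diagnostics and
    DIC-based covariate selection; and a synthetic lake-survey generator with
    known parameters for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
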