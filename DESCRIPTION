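Package: AEpatterns
Title: Adverse-Event Pattern Extraction and Patient-Level Safety Profiles
    by Hierarchical Poisson Matrix Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts treatment-specific adverse-event (AE) co-occurrence
    patterns from patient-level AE records pooled across clinical studies,
    and estimates patient-level safety profiles that predict which AE types
    are likely to occur next. The model is a hierarchical Poisson
    nonnegative matrix factorization: per-period count matrices over
    name-by-severity AE types are decomposed into simplex-constrained
    patterns and nonnegative patient loadings, with Gaussian random-walk
    smoothing across adjacent severity grades, mechanism-of-action sharing
    of treatment patterns, and study-level background patterns identified
    from baseline periods. Estimation is joint MAP by box-constrained
    L-BFGS with analytic gradients. Includes a synthetic-data generator
    emulating a multi-study oncology design, fast fixed-pattern profile
    estimation for new patients, and report utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
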