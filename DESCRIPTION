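Package: sharkCPUE
Title: Delta-GLMM Standardization of Pelagic Shark Longline CPUE
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for standardizing catch-per-unit-effort (CPUE) of
    pelagic sharks taken by longline fleets, using the fisheries delta
    method: a binomial mixed model for the probability of a non-zero
    catch and a gamma mixed model for the magnitude of positive catches,
    each with a per-vessel random intercept integrated by Laplace
    approximation. Includes a synthetic logbook generator with known
    ground truth and a contamination process, record-cleaning filters
    with auditable rejection reports, spatial stratification of sets
    into analysis areas and tRFMO reporting regions, forward BIC
    selection of fixed effects, construction of standardized annual
    abundance indices as the product of back-transformed submodel
    predictions with delta-method error propagation, post-hoc anomaly
    flagging of inter-annual jumps, and descriptive effort and landings
    composition summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    lme4,
    glmmTMB,
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
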