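Package: ncpt
Title: Census-Reweighted Norming and Simulation for Web-Based Cognitive Test Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for processing score tables from the NeuroCognitive
    Performance Test (NCPT), a self-administered web-based battery of brief
    cognitive subtests. Implements the release pipeline end to end:
    session-level inclusion filters (24-hour pause, interleaved tests, slow
    trail making, first-assessment selection), Safe-Harbor age top-coding,
    a census-reweighted rank-based inverse normal transformation that
    re-expresses scores relative to a reference demographic composition,
    the Grand Index battery composite (mean 100, SD 15), normative tables
    over age by education by gender bins, and a technical-validation stage
    (demographics-corrected residual scores, subtest correlation matrices,
    positive-manifold check). A synthetic-cohort generator with a latent
    general-ability factor model and trial-level subtest simulators makes
    every stage testable without the released data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
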