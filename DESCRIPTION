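Package: brcalike
Title: BRCA1-Like Copy-Number Classification and Treatment-Benefit Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for homologous-recombination-deficiency biomarker analysis in
    early-stage triple-negative breast cancer from shallow whole-genome
    sequencing. Implements per-bin read counting on a 20 kb autosomal grid,
    blacklist and mappability filtering, loess GC-bias correction, through-origin
    mappability scaling and log2 copy-number profiles; a nearest shrunken
    centroid BRCA1-like classifier with posterior probability scores and a fixed
    decision threshold; percentile-matched dichotomization for cross-platform
    biomarker concordance; Cox proportional-hazards treatment-by-marker
    interaction analysis with Kaplan-Meier, reverse Kaplan-Meier follow-up and
    Schoenfeld diagnostics; and a synthetic-data generator producing bin grids,
    biased read counts, class-specific copy-number profiles, paired biomarker
    scores and randomized two-arm survival cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
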