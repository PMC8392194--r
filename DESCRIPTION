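Package: chromoscan
Title: Chromoanagenesis Detection from Gene-Level Copy-Number Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects chromoanagenesis (chromothripsis and related catastrophic
    chromosomal events) in tumor samples from gene-level thresholded somatic
    copy-number calls. Segments each chromosomal arm into constant-state runs
    ("oscillations"), summarises their per-arm distribution into two features,
    and classifies samples with a small deterministic CART decision tree.
    Downstream, it provides cancer-type-specific per-gene Fisher exact scans of
    copy-number alteration frequency between chromoanagenesis and
    non-chromoanagenesis samples, merging of significant genes into regions,
    single-gene focality calls, differential mutation-class burden scans from
    MAF input, and pairwise mutual-exclusivity screening with
    Benjamini-Hochberg q-values. A seeded synthetic-cohort generator emulating
    arm-concentrated oscillation bursts and class-linked driver mutations makes
    the whole pipeline testable without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
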