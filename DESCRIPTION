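Package: ibp
Title: Individual Behavioral Profiling for Preclinical Treatment-Response Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Control-anchored individual behavioral profiling (IBP) of animals
    in stress and trauma models. Per-parameter cutoffs are estimated from a
    control population (mean plus or minus a multiple of the control standard
    deviation), each animal is flagged on each behavioral parameter in its
    pathological direction, and a k-of-m rule classifies trauma-exposed
    animals as affected or unaffected and treated animals as treatment
    responders or non-responders. Ships the two built-in seven-parameter
    profiles used in water-associated zero maze, elevated plus maze, open
    field and social recognition testing, the derived behavioral indices
    (anxiety index, social preference index), densitometry and
    percent-of-baseline normalizations, Fisher exact tests on classification
    proportions, a Shapiro-Wilk-gated ANOVA/Kruskal-Wallis group comparison
    layer with Bonferroni or Dunn post hoc tests, and a synthetic cohort
    generator with ground-truth labels for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
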