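Package: cpnquant
Title: Quantification of Callosal Projection Neurons from Retrograde Tracer Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of interhemispheric (callosal)
    cortico-cortical connectivity from retrograde tracer injections in
    primate cortex. Provides per-case counting of labeled neurons with
    injected-area exclusion, homotopic versus heterotopic decomposition of
    callosal projection neurons (CPNs), areal percentage distributions,
    laterality indices, supragranular/infragranular laminar classification
    of connections as feedforward, lateral, or feedback, and group-level
    statistics (Pearson correlations, negative-binomial rate-ratio
    regression with Benjamini-Hochberg adjustment, region summaries).
    Includes a synthetic bilateral-labeling generator with known ground
    truth for end-to-end validation, and report builders producing
    case-by-area connectivity tables and laterality matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
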