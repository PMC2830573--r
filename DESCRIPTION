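Package: bilexnet
Title: Oscillatory Semantic Network Simulator for Bilingual Word Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a two-layer neural-mass model of semantic memory and
    bilingual lexical access. Object features live in topographically
    organized maps of Wilson-Cowan oscillators bound by gamma-band
    synchrony; words live in a lexical sheet of first-order sigmoidal units
    paired with inhibitory interneurons that implement competition between
    translation-equivalent words. A decision gate releases inhibition on
    the lexical sheet only while every feature map carries exactly one
    activation bubble. Three-phase Hebbian training (object learning, L1
    word-object association, L2 acquisition with competitive synapses)
    reproduces classic bilingual phenomena: L1 mediation at low L2
    proficiency, autonomous L2 retrieval after prolonged training,
    word-production conflict, and its resolution by top-down bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
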