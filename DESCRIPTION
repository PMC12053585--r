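Package: bookmorph
Title: Morphological Exposure and Affix Detectability in Book Lexicons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the derivational morphology that readers encounter
    in large book lexicons. Cross-references a word-frequency lexicon with
    etymological morphological annotations, computes complexity, frequency
    and book-dispersion statistics, selects a common-affix inventory, and
    runs a rule-based orthographic affix-stripping algorithm that
    classifies words as detectability hits, misses, or pseudo-affix false
    alarms. Includes a synthetic lexicon generator with gold morphological
    tags for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
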