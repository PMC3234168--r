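Package: lexdens
Title: Lexicon-Density Classification of Combat-Exposure Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An information-retrieval pipeline for recognising first-person
    narratives of combat exposure in noisy web text such as military blog
    posts.  Raw documents are tokenized, normalized (case folding,
    de-hyphenation, collapse of expressive letter elongation), stop-filtered
    and Porter-stemmed; corpus-level TF*IDF weights rank candidate domain
    terms; a category-structured lexicon (physical exposure vs. emotional
    reaction, each with two subcategories) is compiled into a gazetteer
    matcher; documents are scored by annotation density (lexicon hits over
    word count) and classified as combat-exposure-relevant by a transductive
    batch-median threshold.  Includes a seeded synthetic-corpus generator
    with controllable term density and spelling noise, an evaluation module
    (confusion matrix, precision, recall, F-score), and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
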