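Package: bionorm
Title: Biomedical Entity Normalization by Sieve Candidate Generation and CNN Ranking
Version: 0.1.0
Authors@R:
    person("bionorm", "developers", email = "bionorm@example.org", role = c("aut", "cre"))
Description: Maps disease and disorder mentions in biomedical text to concepts
    in a reference terminology. Candidates are generated by a three-tier rule
    cascade (exact match, exact match after morphological transformation, and
    word-overlap partial match) over a TSV lexicon and a training-mention map,
    with optional NIL (unlinkable) handling. Candidates are then ranked by a
    small convolutional network that encodes the mention and each candidate
    with narrow filters and 1-max pooling, combines the encodings through a
    learned bilinear similarity and word-overlap morphological features, and
    scores each pair with a two-class softmax trained pairwise. Includes
    PubTator corpus I/O, Schwartz-Hearst abbreviation detection, a Porter
    stemmer, cross-validated model selection, corpus-level evaluation, a
    command-line interface, and a deterministic synthetic-fixture generator
    for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
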