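Package: polarnet
Title: Polarity Estimation and Echo-Chamber Analytics on Retweet Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-user political polarity on a directed, weighted
    retweet network by combining profile-text embeddings with network
    structure through a Siamese triplet objective, seeded by weak
    supervision from profile hashtags and media-outlet endorsements.
    Quantifies echo chambers with a decile-generalised random-walk
    controversy matrix (with an exact small-graph oracle), and produces
    partisan influence, audience-polarity and user-role analytics.
    Includes a synthetic polarized-corpus generator with known ground
    truth so the full pipeline is testable without any platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    Matrix,
    pROC,
    stats,
    stringi,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
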