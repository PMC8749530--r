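Package: patsim
Title: Multiple-Disease Patient Similarity Learning with Joint Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring similarity between patients carrying multiple
    chronic diseases from longitudinal visit records. Generates seeded synthetic
    cohorts with diabetes, cerebrovascular and ischemic heart disease comorbidity
    structure; embeds visit documents (demographic tokens, diagnosis and
    prescription codes) with a distributed-memory paragraph-vector model or a
    deterministic hashing projection; stacks visit embeddings into zero-padded
    patient matrices; derives rule-based 14-bit feature labels and 4-of-7
    category-match similarity labels; balances multi-label disease prevalence
    with MLSMOTE; trains a weight-shared (Siamese) one-dimensional convolutional
    encoder with self-attention jointly under binary cross-entropy and
    contrastive losses; and compares against Euclidean, cosine, Mahalanobis and
    localized supervised metric learning baselines under a shared evaluation
    harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
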