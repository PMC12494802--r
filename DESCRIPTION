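Package: grnembed
Title: Embedding and Comparative Evaluation of Transcription Factor-Gene
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for embedding directed transcription factor-target gene
    regulatory networks and comparing embedding models. Provides a reader and
    writer for TRRUST-layout interaction tables, a synthetic network generator
    with planted modules and heavy-tailed regulator out-degree, a two-layer
    graph convolutional autoencoder with an inner-product edge decoder, an
    adversarial generator/discriminator pair trained on autoencoder embeddings,
    an exact statevector simulator for angle-encoded quantum node features
    (RY/RZ rotations, CNOT entangling chain, Pauli-Z readout), and an
    evaluation battery covering link prediction (AUC, average precision),
    embedding quality (silhouette, neighborhood preservation), centrality
    correlations, and distribution divergences (KL, Jensen-Shannon,
    Wasserstein, maximum mean discrepancy).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
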