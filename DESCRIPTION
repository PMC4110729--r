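Package: switchscape
Title: Attractor Landscapes of Multistable Switches in Noisy Boolean Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact Markov-chain analysis of synchronous Boolean gene regulatory
    networks under per-gene flip noise. Enumerates attractors and basins,
    builds the noisy state-transition matrix, and computes mean first passage
    times (MFPT) between attractors by solving absorbing-chain linear systems.
    Generates random Boolean networks tuned to the critical regime via the
    sensitivity formula s = 2 q p (1 - p), embeds two-gene multistable switch
    motifs (bistable and mutual-inhibition switches with zero, one or two
    positive feedback loops) by truth-table replacement and rewiring, and runs
    Monte-Carlo ensembles that classify attractor pairs into directional and
    well-separated transitions, the landscape features that shape cellular
    differentiation lineage trees. Includes alternative epigenetic-barrier
    measures (transitory single-bit-flip transition probabilities and
    attractor Hamming distance) and their correlation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
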