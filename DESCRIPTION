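Package: misonet
Title: MISO State-Space Effective Connectivity Networks for Intracranial EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates time-varying directed (effective) connectivity networks
    from multichannel intracranial EEG by fitting, for every channel and
    sliding 10-second epoch, a linear time-invariant multi-input single-output
    (MISO) state-space model with all other channels as inputs. Euclidean
    norms of the input-matrix columns define a non-symmetric influence matrix
    that is pruned at a pooled 95th-percentile threshold into a sparse
    directed graph. Degree and betweenness centrality of the pruned graphs,
    summarised by seizure-onset-zone (SOZ), peri-SOZ and non-SOZ channel
    groups, are scanned for preictal network-state transitions with a
    one-standard-deviation exceedance rule. Includes a seeded synthetic iEEG
    generator with planted piecewise-stationary vector-autoregressive ground
    truth, canonical-band spectral power summaries, and Kruskal-Wallis/Dunn
    group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
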