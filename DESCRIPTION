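Package: mintools
Title: Molecular Interaction Network Analysis with a Vertex-Centric Superstep Engine
Version: 0.1.0
Authors@R: person("M.", "Neri", email = "mneri@example.org", role = c("aut", "cre"))
Description: Tools for analysing molecular interaction networks (MINs):
    reading PSI-MI TAB (MITAB) and plain edge-list interaction files,
    whole-network and per-interactor statistics (density, degrees, harmonic
    closeness), k-hop and weighted max-product-threshold neighborhoods,
    connected components and closest-component queries, and Kleinberg
    dispersion. Graph traversals run on a bulk-synchronous vertex-centric
    (Pregel-style) superstep engine with interchangeable serial and
    partitioned multicore executors bound to the same observable contract.
    Includes a seeded preferential-attachment generator of synthetic MINs
    and independent brute-force oracles for every traversal, plus a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
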