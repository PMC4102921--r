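Package: topocomm
Title: Topology-Based Detection of Strong- and Weak-Sense Network Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic, parameter-free community detection for undirected
    networks driven purely by topology. Communities are defined in a strong
    sense (more internal than external edges) or a weak sense (internal edges
    exceed the edges to any single other community). Detection seeds strong
    communities from node neighbourhoods, grows weak communities around them,
    and iteratively reassigns nodes to the community holding most of their
    neighbours until convergence. Nodes bridging communities are classified
    into two overlap types using neighbour counts, hub members and shortest
    paths. Includes planted-partition and LFR-style benchmark generators with
    planted ground truth, partition metrics (normalized mutual information,
    Newman modularity), readers for edge-list, GML and Pajek files, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
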