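Package: tosnet
Title: Outside Competitive Dynamics and Total-Support Ranking on
    Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the competition between a leader node inside a
    heterogeneous signaling network (state pinned at +1) and a virtual
    opponent outside the network (state pinned at -1) that is temporarily
    attached to one normal node at a time. Normal nodes update by a
    distributed consensus protocol; their steady states are obtained
    either by iteration or by a closed-form linear solve on the anchored
    subsystem. Summing the perturbed node's steady value over all
    attachment points yields the total-support score, a dynamic
    centrality whose top-ranked nodes are candidate driver genes and
    drug targets. The package also parses KEGG KGML pathway files into
    mixed directed/undirected networks (with group-node expansion),
    computes the structural centralities used for validation (closeness
    variant, reachability, hierarchical closeness, degree, betweenness),
    generates directed Barabasi-Albert ensembles, and reproduces the
    total-support-versus-centrality correlation experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
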