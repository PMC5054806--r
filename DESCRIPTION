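Package: sprecon
Title: Network Reconstruction from All Shortest Paths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Enumerates every shortest path (not just one) between node
    pairs of directed or undirected, optionally weighted interaction
    networks, and uses them to extract subnetworks: shortest-path trees
    from a single source, shortest-path clusters connecting a selected
    node set, and attachment of an isolated node to the nearest members
    of a target set. Reads and writes Cytoscape SIF networks and edge
    weight tables (negative weights supported via Bellman-Ford), reports
    the results-panel statistics (paths grouped by size, average path
    length, unique and expected path counts, connectivity flag), and
    ships a command-line front end plus a seeded random-network
    generator for reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    optparse,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
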