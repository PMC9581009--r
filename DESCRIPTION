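Package: goscatter
Title: Semantic Similarity Scatterplots of Redundancy-Reduced GO Term Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes lists of enriched Gene Ontology (GO) terms by grouping
    semantically similar terms with information-content-weighted Lin similarity,
    selecting one representative term per group with a rule-based contest, and
    plotting the representatives in a two-dimensional semantic space computed by
    multidimensional scaling. Parses ontologies in OBO format and annotation
    corpora in GAF format, resolves obsolete and alternative term identifiers
    against the loaded ontology version, reads four tab-delimited enrichment
    result dialects, and writes fully scriptable figure, table, and log output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    ggrepel,
    igraph,
    RColorBrewer,
    grDevices,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
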