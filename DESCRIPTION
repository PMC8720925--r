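Package: pvnet
Title: Pharmacovigilance Signal Detection and Drug-Gene Interaction
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two complementary analyses of drug safety data:
    disproportionality signal detection in spontaneous adverse-event
    report databases (FAERS-dialect tables, case deduplication, suspect
    drug role filtering, MedDRA-style preferred-term to system-organ-class
    mapping, reporting odds ratios with Wald confidence intervals), and
    drug-gene interaction network analysis (PSI-MITAB interactome
    ingestion, one-hop seed-gene neighbourhood expansion, a from-scratch
    MCODE molecular-complex detection implementation, and hypergeometric
    over-representation analysis against GMT pathway and disease-gene
    collections with Benjamini-Hochberg adjustment). A synthetic-data
    module generates spontaneous reports with injected drug-event
    associations of known odds ratio, planted-partition interactomes and
    aligned gene-set collections, so every pipeline stage can be verified
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
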