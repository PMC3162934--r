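Package: sms54
Title: Sigma-54 Promoter Discovery and Enhancer-Binding-Protein Survey by
    Similar Motif Scoring
Version: 0.1.0
Authors@R:
    person("FG", "Bioinformatics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for bacterial Sigma-54 (RpoN)
    regulation. Implements the frequency-sum Similar Motif Search (SMS)
    score for position-frequency matrices over DNA and protein alphabets,
    genome scanning for bipartite -24/-12 promoter elements with signed
    promoter-to-gene distance conventions, rule-based identification and
    classification of Sigma-54 enhancer-binding proteins (GAFTGA integrity
    and domain-architecture typing), taxonomic presence/absence summaries,
    operon/divergon construction, cross-phylum conserved-function-tendency
    extraction from genomic context, and a deterministic synthetic-genome
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
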