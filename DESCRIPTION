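Package: phosmoca
Title: Comparative Evolutionary Conservation Analysis of Phosphorylation
    Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the evolutionary conservation of protein
    phosphorylation motifs across a panel of eukaryotic genomes. Matches
    PROSITE-like positional motif patterns around human phosphosites,
    projects sites through ortholog-cluster multiple sequence alignments,
    computes per-genome conservation rates and a motif-level conservation
    index (CI), and derives downstream summaries: known-versus-potential
    site comparison, CI-rank binning by motif structure, kinase
    group/family substrate tabulations, hypergeometric term enrichment,
    and a permutation statistic for motif-sharing interaction networks.
    Includes a synthetic ortholog-family simulator with planted
    conservation probabilities for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
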