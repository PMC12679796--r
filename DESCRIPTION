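Package: taphos
Title: Post-Mapping Authentication of Ancient Metagenomic Alignments
Version: 0.1.0
Authors@R:
    person("Taphos", "Developers", email = "taphos@example.org", role = c("aut", "cre"))
Description: Tools for authenticating taxonomic assignments in ancient
    environmental DNA experiments after competitive mapping and
    lowest-common-ancestor (LCA) read assignment. Streams a read-name-sorted
    BAM/SAM file synchronized with an ngsLCA-style assignment file to (a)
    shrink alignment files down to phylogenetically informative content, (b)
    compute per-taxonomic-node authentication statistics (k-mer duplicity via
    HyperLogLog sketches, DUST read complexity, terminal C-to-T / G-to-A
    deamination frequencies, average nucleotide identity, GC content), and
    (c) produce downstream artifacts: multi-sample abundance matrices,
    per-taxon read extractions, deamination plots, read-length and mismatch
    plots, and damage-coloured Krona XML. A deterministic synthetic fixture
    generator produces toy taxonomies, references and damaged reads so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Rsamtools,
    jsonlite,
    xml2,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
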