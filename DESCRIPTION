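Package: organvar
Title: Intraspecific Organellar Genome Variation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-based discovery and annotation of SNPs and InDel blocks in
    population samples of plastomes and multichromosomal plant mitogenomes, with
    mutation-spectrum and hotspot statistics, haplotype collapsing, indel-block
    distances, randomized minimum-spanning-tree haplotype networks, bootstrapped
    neighbour-joining trees with Jukes-Cantor/HKY model selection, and
    plastome-versus-mitogenome tree comparison. Includes a synthetic
    organellar-population simulator that plants mutations with known truth tables
    and emits the true alignment, so every stage of the pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
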