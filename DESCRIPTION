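Package: epitriad
Title: Mining Epistatic Maternal and Fetal SNP-Sets in Case-Parent Triads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nominates sets of child and maternal single nucleotide
    polymorphisms (SNPs) that may act epistatically on disease risk in
    case-parent triad studies. Implements a transmission-based fitness score
    that contrasts affected children with their complement siblings and, for
    maternal loci, mothers with fathers under a mating-symmetry assumption;
    an island-model evolutionary search over SNP-sets of fixed size; permutation
    tests for epistasis and for maternal-fetal interaction based on
    pseudo-family reassembly; SNP- and SNP-pair-level graphical scores with
    network export; and a simulator of triad cohorts with Mendelian
    transmission and user-specified joint (super-multiplicative) risk effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
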