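Package: ykmer
Title: Sex-Linked Region Discovery from Sex-Specific k-mers
Version: 0.1.0
Authors@R:
    person("P2R", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genus-wide discovery of sex-linked (Y-specific) genomic regions
    in dioecious species from whole-genome short-read data of one male and
    one female per species. Implements calibrated sex-specific k-mer
    subtraction with genome-specific error cutoffs, cross-species survival
    curves and genus-conserved k-mer sets, k-mer length calibration from SNP
    spacing with a sliding-window miss-probability bound, localization of
    conserved k-mers onto contigs with density tracks and phased-haplotype
    scaffold selection, copy-number inference from read depth normalized to
    a diploid baseline, and Nei-Gojobori synonymous/nonsynonymous
    substitution-rate summaries with relative clade-depth statistics. A
    built-in simulator generates a synthetic dioecious genus (genomes, reads
    and ground truth) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
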