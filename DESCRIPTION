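Package: scaffval
Title: Optical-Map Validation of Hi-C Scaffolded Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects structural inconsistencies between optical genome maps
    (nicking-enzyme label maps) and Hi-C scaffolded assemblies. Performs
    in-silico digestion of scaffold sequences, aligns label maps by dynamic
    programming with a sizing-error model, clusters alignment breakpoints
    into conflicts, classifies them relative to Hi-C gap junctions, estimates
    implied gap sizes, corroborates junctions with spanning long-read
    alignments, cuts confirmed misjoins, and reports before/after assembly
    contiguity statistics. Includes a fully ground-truthed simulator (genome,
    contigs, misjoined scaffolds, noisy label maps, read alignments) for
    end-to-end validation of the method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
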