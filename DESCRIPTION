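Package: codonharmony
Title: Codon Harmonization and Codon-Usage Diagnostics for Recombinant
    Gene Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A workbench for designing recombinant coding sequences whose
    host-codon usage landscape mimics the native gene's, and for diagnosing
    any coding sequence.  Implements full optimization plus three
    harmonization engines (a 5-point deoptimization rule, a no-tolerance
    rule, and a full-tolerance stochastic rule driven by a likelihood-for-
    selection distribution), region-wise application to multi-species
    chimeric genes, %MinMax codon-optimality profiles with a random
    reverse-translation null model, CAI, effective number of codons,
    average relative codon usage, GC content, rare-codon annotation, and
    5'-mRNA ribosome-binding-site occlusion analysis with a base-pair
    maximization folder and Vienna dot-bracket import.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
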