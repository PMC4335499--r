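Package: pabscan
Title: Deep Mutational Scanning Meets Natural Sequence Variation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline combining deep mutational scanning (DMS)
    enrichment scores with natural sequence variation from homologue
    alignments, built around the RRM-domain inter-species complementation
    design. Computes wild-type-normalized enrichment scores from pre- and
    post-selection variant counts with read-count filters and a
    synonymous-variance quality check; catalogues natural single amino
    acid substitutions from a multiple sequence alignment mapped to
    reference residue numbering; classifies substitutions as non-, mildly
    or strongly deleterious with a synonymous-null contamination
    estimator; scores product-rule epistasis for double mutants
    partitioned by co-occurrence in individual homologues; calls and
    categorizes two-hybrid contact-site hits; applies probability-cutoff
    ancestral-state calls; and ships a seeded growth-selection simulator
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
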