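Package: nbsmapr
Title: Mapping Photoaffinity-Labeled Proteolytic Fragments onto Nucleotide-Binding Consensus Motifs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers candidate ATP-binding regions of large membrane proteins
    from photoaffinity-crosslinking experiments. Provides PROSITE-style
    consensus-motif scanning with overlapping hits, in-silico trypsin
    digestion with average peptide masses, assignment of Edman-sequenced
    gel fragments to protein coordinates, an elimination/refinement
    inference that combines label flags, fragment parentage, membrane
    topology and mutagenesis exclusions into binding-region calls, and
    competition-binding IC50 estimation by one-site nonlinear regression.
    Includes a synthetic-data generator emulating limited proteolysis,
    noisy gel masses, ambiguous N-terminal reads and competition curves,
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
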