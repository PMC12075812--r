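Package: kiseq
Title: Repair-Outcome Analysis of CRISPR Knock-In from Long-Read Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies long amplicon reads from CRISPR-mediated endogenous
    tagging experiments into donor-independent and donor-dependent repair
    outcome categories (wild type, deletions, insertions, perfect HDR, blunt
    ligation, asymmetric HDR, imperfect and concatenated integrations),
    computes microhomology lengths at genome-donor junctions, per-position
    deletion profiles, and the bi-allelic dual-color tagging probability
    model. Includes a ground-truth-labelled synthetic HiFi-read generator
    covering all outcome categories under blunt (Cas9-like) and staggered
    (Cas12a-like) cut geometry, so the whole pipeline is testable without
    sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    methods,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
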