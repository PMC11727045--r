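Package: indelssr
Title: Genome-Wide InDel-SSR Marker Development and Marker-Trait Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers composite InDel-SSR loci (insertion/deletion variants
    co-located with microsatellites within a flanking window) from a reference
    genome and InDel calls, designs and screens PCR primer pairs for them,
    predicts electrophoretic band matrices by in-silico PCR, and carries the
    resulting band data through the standard marker-genetics workflow:
    per-marker allele statistics (Na, Ne, Ho, He, PIC, Shannon I), Nei
    genetic distances with UPGMA clustering, principal component analysis,
    Evanno delta-K model choice, allele-sharing kinship, and marker-trait
    association under fixed-effect (GLM) and kinship mixed models (MLM) with
    candidate-gene window lookup. A synthetic-data module generates genomes,
    structured cohorts, band matrices and phenotypes with known ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
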