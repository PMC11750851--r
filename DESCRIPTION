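Package: kaspanel
Title: SNP Marker Panels, KASP Assay Design and Cultivar DNA Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for engineering SNP marker panels for cultivar
    identification from reduced-representation sequencing variants. Filters
    multi-sample VCF genotypes to KASP-suitable candidates (depth, minor
    allele frequency, call-rate, site quality, biallelism, flank cleanliness
    and flank uniqueness against a reference genome), computes per-locus and
    population-level genetic indices (observed/expected heterozygosity,
    polymorphic information content, effective allele number, nucleotide
    diversity, inbreeding coefficient), finds minimum marker combinations
    that distinguish all cultivars by greedy set cover with an exact solver
    for small instances, designs tailed allele-specific (KASP) primer
    candidates under melting-temperature, GC and product-size constraints,
    and renders colour-coded DNA fingerprint tables. Includes a
    structured-population genotype simulator (Balding-Nichols model with
    inbreeding, missingness, duplicate cultivar groups and per-locus depth
    and quality) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
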