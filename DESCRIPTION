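Package: lapaint
Title: Site-Based Local Ancestry Inference via Compact Population Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Local ancestry inference for admixed haplotypes using a
    site-based copying model. A labeled reference panel is collapsed into a
    compact population graph holding, per site, the unique
    (allele, population) pairs observed in the panel; a query haplotype is
    painted by the minimum-penalty threading path through this graph, where
    mismatches cost 1, switching populations between adjacent sites costs a
    recombination-scaled penalty in [1, 2], and switching templates within a
    population is free. Includes VCF/genetic-map input, a compact-panel VCF
    serialization, an exhaustive-enumeration oracle for the dynamic program,
    a synthetic admixture simulator with ground-truth ancestry tracts, and
    accuracy / ancestry-dosage r-squared evaluation with minor-allele
    marker filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
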