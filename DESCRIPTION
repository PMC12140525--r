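Package: rohmap
Title: Runs-of-Homozygosity Detection, Burden Association and Homozygosity
    Mapping for Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) from SNP-array-style
    genotypes with a sliding-window caller, computes per-individual
    homozygosity metrics (S_ROH, N_ROH, AV_ROH, F_ROH) and consanguinity
    classification, fits case-control and age-at-onset burden models, and
    performs homozygosity mapping through consensus ROH pools,
    case-control enrichment tests, family segregation analysis and rare
    homozygous variant prioritization. Includes a synthetic cohort
    generator with planted ground-truth segments for validating every
    stage, PLINK binary I/O, quality-control filters (call rate,
    Hardy-Weinberg, minor allele frequency, LD pruning, KING kinship,
    principal components), and a reproducible staged pipeline runner.
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
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
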