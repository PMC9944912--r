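Package: nsvatlas
Title: Non-Synonymous Variant Panels and F-Statistic Outlier Scans for
    Population Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing panels of non-synonymous
    variants (NSVs) in species with annotated genome assemblies. Classifies
    coding SNVs (synonymous, missense, nonsense) directly from a genome
    FASTA, GFF3 gene models and a VCF; applies a multi-criteria filter
    cascade (pseudogene heuristic, nonsense removal, flanking-region
    cleanliness, tri-allelic exclusion, Hardy-Weinberg screening,
    candidate-gene targeting, per-gene MAF maximisation) with a fully
    auditable ledger; computes panel-level population-genetic summaries
    (allele frequencies, unbiased expected heterozygosity, F_IS, exact
    Hardy-Weinberg tests, Weir-Cockerham F_ST, hierarchical F-statistics);
    and detects F_ST outliers with an FDIST-style scan against a simulated
    island-model neutral null, in flat and hierarchical (e.g. wild versus
    farm) modes. A synthetic-data module generates annotated toy genomes
    with spiked variants and structured genotype panels with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
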