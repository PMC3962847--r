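Package: microcore
Title: Core Microbiome Delineation and Diversity Analysis for Amplicon Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of 16S rRNA amplicon surveys from operational
    taxonomic unit (OTU) count tables: reading and writing mothur-style shared,
    constaxonomy, newick and sample-metadata files; even-depth down-sampling and
    replicate-averaged tables; alpha diversity (observed richness, bias-corrected
    Chao1, ACE, Shannon diversity and evenness, Faith's phylogenetic diversity,
    analytic rarefaction); Bray-Curtis, Morisita-Horn and Sorensen dissimilarities
    with shared-OTU (Venn) accounting; rank correlation of diversity against
    environmental gradients with exact permutation p-values at small n; and
    delineation of a "core microbiome" as the OTU set present in every sample
    above abundance thresholds and evenly distributed across samples by a
    cross-sample Shannon evenness statistic. Includes a synthetic community
    generator with planted core OTUs and a contamination gradient for end-to-end
    validation, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vegan,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante
Config/testthat/edition: 3
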