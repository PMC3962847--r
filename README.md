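# microcore

Downstream analysis of 16S rRNA amplicon surveys from OTU count tables, built
around the delineation of a **core microbiome**: the set of OTUs that is not
merely present in every sample, but present *abundantly* and *evenly*.

The package targets microbial ecologists working with small multi-sample
surveys (the motivating setting is five soil communities along a heavy-metal
contamination gradient) who need the standard downstream toolkit — even-depth
rarefaction, nonparametric richness estimation, community dissimilarities,
rank correlations with environmental variables — plus a principled, testable
definition of the shared community core.

## The core statistic

For each OTU, treat the **samples as categories and its reads as
individuals**, and compute the cross-sample Shannon evenness

```
E = (-Σ_j p_j ln p_j) / ln S,     p_j = reads of the OTU in sample j / its total reads
```

over the `S` samples. `E = 1` means the OTU's reads are spread perfectly
evenly across samples; small `E` means concentration in one sample. An OTU
belongs to the core microbiome when, simultaneously:

1. it has **≥ 3 reads** in every sample (OTUs with two or fewer reads in any
   sample are eliminated — rare reads can land in a sample by chance, e.g.
   through a mis-read multiplex identifier),
2. its relative abundance is **> 0.1 %** in every sample, and
3. its cross-sample evenness satisfies **E > 0.9**.

The two abundance conditions are deliberately applied as separate filters:
at a depth of 1,500 reads per sample, 0.1 % is 1.5 reads and the thresholds
genuinely differ.

Around this sit the standard stages, each exposed as a plain function:
mothur-dialect `.shared`/constaxonomy/newick/TSV readers and writers;
without-replacement (multivariate hypergeometric) down-sampling and
replicate-averaged tables; observed richness, bias-corrected Chao1, ACE,
Shannon diversity/evenness, Faith's rooted phylogenetic diversity and
analytic rarefaction; Bray-Curtis, Morisita-Horn and Sørensen
dissimilarities with shared-OTU (Venn) accounting; and Spearman rank
correlation with exact permutation p-values at small n. A synthetic
community generator with planted ground truth validates the whole chain,
and `run_pipeline()` drives an end-to-end, bit-reproducible analysis from
one configuration.

## Worked example

```r
library(microcore)

## the core statistic on one OTU's per-sample counts
otu_evenness(c(13, 26, 24, 36, 41))
#> [1] 0.9596902

## a synthetic five-sample survey with a planted core and a
## contamination gradient that suppresses richness
ds <- simulate_communities(sim_config(seed = 42))
ds
#> Synthetic community survey: 5 samples x 459 observed OTUs (600 simulated, 20 planted core)
#> contamination gradient: 0.1, 0.3, 0.55, 0.75, 0.92
#> true richness: 537, 418, 256, 158, 66

## normalize depth, then delineate the core
tab <- downsample(ds$table, depth = min(rowSums(ds$table)), seed = 43)
report <- delineate_core(tab, core_criteria(), taxonomy = ds$taxonomy)
summary(report)
#> OTUs tested:               448
#> pass read-count filter:    33
#> pass frequency filter:     33
#> pass evenness filter:      19
#> core (all three):          17
#> near-misses:               16

## rank correlation of a diversity measure against a metal gradient
env <- read_env(system.file("extdata", "soil_env.tsv", package = "microcore"))
alpha <- read.delim(system.file("extdata", "alpha_printed.tsv", package = "microcore"))
spearman_cor(env$Zn_ba, alpha$shannon_003)
#> Spearman rank correlation: env$Zn_ba vs alpha$shannon_003
#> rho = -1.0000, p = 0.01667 (exact-permutation, n = 5)
```

Reading the output: 17 of the 20 planted core OTUs are recovered (the three
misses sit just under an abundance or evenness threshold after read-sampling
noise); the `rho = -1` says the bioavailable-zinc ranking is exactly the
reverse of the species-level Shannon diversity ranking across the five
reference soils, with the exact two-sided permutation p-value `2/5! = 0.0167`.

The `inst/extdata/` folder ships small transcribed reference tables for the
five-soil study system (per-sample metal concentrations, sequencing
statistics, per-OTU core count tables, tabulated diversity summaries) that
the examples, tests and acceptance script use as fixed inputs.

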