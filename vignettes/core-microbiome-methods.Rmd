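---
title: "Delineating a core microbiome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating a core microbiome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcore)
```

# The problem

Amplicon surveys of bacterial communities routinely ask which taxa are
*shared* across a set of samples. Plain presence/absence answers the
question badly at typical sequencing depths: a single stray read — a
mis-assigned multiplex identifier, a low-level cross-contamination — makes
an OTU "present", and deeply sequenced samples accumulate such phantom
presences faster than shallow ones. `microcore` implements a stricter,
quantitative notion of the shared core of a community set, together with
the standard downstream stages needed to get from an OTU count table to
that answer.

# The core-membership model

Write `c_ij` for the reads of OTU `i` in sample `j`, `N_j` for the total of
sample `j`, and `S` for the number of samples. OTU `i` is assigned to the
core microbiome iff all three of the following hold:

* **read floor** — `c_ij >= 3` for every `j`;
* **frequency floor** — `c_ij / N_j > 0.001` for every `j`;
* **evenness** — `E_i > 0.9`, where `E_i` is the Shannon evenness of the
  vector `(c_i1, ..., c_iS)`:
  `E_i = (-sum_j p_ij log p_ij) / log(S)` with `p_ij = c_ij / sum_j c_ij`,
  i.e. the samples are treated as categories and the OTU's reads as
  individuals.

Assumptions worth making explicit. The statistic compares *read counts*
across samples, so it is only meaningful after depth normalization or on
tables whose depths are comparable; the pipeline therefore down-samples to
a common depth first. The evenness denominator is `log(S)`, so `E` is
log-base invariant; the package uses natural logarithms throughout, which
also makes the per-sample Shannon `H'` values come out in nats. Evenness is
invariant to permuting samples and to rescaling all counts by a common
factor, properties the test suite asserts.

## Threshold choices

* The read floor is **3** ("more than two reads"), and the frequency floor
  **0.1%** is kept as a *separate* filter even though the two coincide at a
  depth of ~2,000–3,000 reads. At a depth of 1,500, 0.1% is 1.5 reads and
  the read floor is the binding constraint; in deep samples the frequency
  floor binds instead. Applying both is the strictest consistent reading,
  and costs nothing when they coincide.
* Both inequalities on frequency and evenness are **strict** (`> 0.001`,
  `> 0.9`). Because a verdict that flips on the fourth decimal of `E` is
  fragile, `delineate_core()` warns about OTUs passing the abundance
  filters whose evenness lies within 0.005 of the threshold.
* For replicate-averaged (real-valued) tables the same thresholds are
  applied to the *mean* counts. This is an interpretation, not a fact about
  reads, and the report carries an `averaged` flag saying so.

# Depth normalization

`downsample()` draws exactly `depth` reads per sample **without
replacement** (multivariate hypergeometric), which is the correct model for
subsampling physical reads; multinomial (with-replacement) sampling would
inflate the variance of rare-OTU counts. `averaged_shared()` repeats the
draw (default five replicates) and averages entry-wise; means of
constant-sum draws preserve the per-sample total exactly. Averaged counts
are kept fractional — rounding would silently destroy the conservation
property and is left to consumers that genuinely need integers.

Seed policy: one master seed; replicate `r` uses a sub-seed drawn from a
stream seeded by the master, so the replicate *set* is reproducible and
adding replicates does not shift earlier ones across machines with the same
RNG. All derived seeds stay below 2^31.

# Alpha diversity

Per down-sampled replicate and sample the package computes observed
richness, bias-corrected Chao1, ACE, Shannon `H'` and evenness, and
optionally Faith's PD; `alpha_summary()` reports the mean over replicates.

* **Chao1** uses the bias-corrected form `S_obs + F1(F1-1)/(2(F2+1))`,
  defined even when no doubletons occur. Its 95% interval is the standard
  log-normal interval on `S_chao1 - S_obs` with the bias-corrected variance
  formula. (Published variants of the variance differ slightly between
  implementations; the cross-check against `vegan::estimateR` is therefore
  exact on the point estimate and ~1% on the standard error.)
* **ACE** uses the conventional rare/abundant split at 10 reads. When every
  rare read is a singleton the coverage estimate is zero and ACE is
  undefined; the estimate then falls back to Chao1 and the output flags the
  fallback rather than returning `NaN`. The ACE interval is a normal
  approximation using the standard error from `vegan::estimateR` (available
  at the conventional cutoff only; other cutoffs return `NA` with a note).
* **Shannon CI** uses the first-order estimator variance
  `(sum p log^2 p - H^2)/N`. Whether tabulated subsample CIs of this kind
  are analytic or empirical is generally ambiguous; both are implemented
  (`ci_method = "analytic"` / `"empirical"`) and analytic is the default.
* **Interval aggregation** across replicates is the mean of the
  per-replicate analytic bounds — matching the convention "each value is a
  mean of five subsample values" — rather than an interval of the replicate
  means; the latter is the `"empirical"` option.
* **Faith's PD is rooted**: the spanning subtree includes the stem edges up
  to the root, so a single present leaf contributes its full root-to-tip
  path. Rooted and unrooted PD differ exactly in those stem edges, and the
  choice matters for near-singleton samples; rooted is the convention of
  the phylogenetic-diversity tooling this package mirrors.
* **Rarefaction** is analytic
  (`E[S_n] = sum_i (1 - C(N - N_i, n)/C(N, n))`, evaluated via
  `vegan::rarefy`'s stable log-binomial implementation) and is verified in
  the tests both against exhaustive enumeration at tiny sizes and against a
  10,000-draw Monte-Carlo oracle.

# Community comparison

`bray_curtis()` implements the abundance-based form
`sum|x-y| / sum(x+y)`. Survey literature occasionally labels Bray-Curtis
"incidence-based"; the incidence-based relative (Sørensen) is provided as a
separate, explicitly named metric so that either reading is available
without ambiguity. `morisita_horn()` is scale-invariant and dominated by
abundant OTUs — the pairing of the two metrics separates "the abundant
subcommunities agree" from "the full abundance profiles agree".
`dist_matrix()` delegates to `vegan::vegdist`, and the tests assert the
scalar formulas and the matrix route agree pairwise.

The shared-OTU (Venn) accounting partitions OTUs by their exact support
subset at a configurable presence threshold (default: one read — the core
analysis applies its own, stronger filters). OTUs below the threshold
everywhere land in an explicit `"(none)"` cell so cell counts always sum to
the OTU total.

# Environmental correlation

With five samples, the t- and S-statistic approximations behind most
Spearman implementations are unreliable, and tabulated values like
"p = 0" for a perfect anticorrelation cannot be taken literally: at n = 5
the smallest achievable two-sided exact p-value is `2/5! ≈ 0.017`.
`spearman_cor()` therefore enumerates all `n!` rank permutations for
`n <= 8` (at most 40,320) and reports `P(|rho_perm| >= |rho_obs|)`; beyond
`n = 8` it switches to the t approximation. Ties get mid-ranks. No
multiplicity correction is applied by default — the number of tests is
recorded instead — with Holm adjustment behind a flag.

# The synthetic generator

`simulate_communities()` plants known structure so that every stage has a
ground truth to recover:

* a log-normal species-abundance distribution (default
  `meanlog = 0, sdlog = 1.5` — a long-tailed SAD of the kind amplicon
  surveys of soil show, with a few hundred effective OTUs at these depths);
* **presence via tolerance thresholds**: non-core OTU `i` draws
  `t_i ~ U(0, 1)` and is present in sample `j` iff
  `t_i > z_j`, where `z` is the per-sample contamination. True per-sample
  richness is thereby controlled exactly, which makes parameter-recovery
  targets clean — an abundance-dilution mechanism would only control it in
  expectation;
* a **planted core** (default 20 OTUs) with per-sample expected share drawn
  `U(0.003, 0.008)` — comfortably above the 0.1% frequency floor — and
  spread across samples by a symmetric Dirichlet whose concentration is set
  from `core_evenness_target` (default 0.95). Only a quarter of the allowed
  evenness deficit is budgeted to the Dirichlet: unequal depths and
  read-sampling noise also reduce realized evenness and must fit in the
  remainder;
* multinomial read sampling per sample at the configured depths. Generation
  is deliberately with replacement while downstream down-sampling is
  without: the first models the sequencer drawing from an effectively
  infinite template pool, the second subsamples the finite realized reads.

Defaults emulate the motivating study design: 5 samples, 600 OTUs, depths
`(2632, 3446, 7062, 5852, 4440)` (the per-sample high-quality non-chimeric
read totals of the reference soil survey), and a monotone contamination
gradient `z = (0.10, 0.30, 0.55, 0.75, 0.92)` under `sensitivity_scale = 1`,
chosen so that expected non-core richness spans roughly 540 down to 60 —
about the spread the reference gradient shows between its least and most
contaminated soils.

What the generator does **not** emulate: sequence-level noise (chimeras,
homopolymer errors), taxon-taxon interactions, abundance correlations
between samples beyond the planted core, or overdispersion beyond
multinomial. Passing the recovery suites therefore demonstrates that the
statistics behave correctly under the stated sampling model — not that the
thresholds are optimal for any particular real soil system.

# Degenerate inputs and tie-breaks

All-zero OTU columns are dropped (and logged) at table construction;
all-zero count vectors are errors for every estimator rather than silent
zeros. A one-OTU sample has `H' = 0`, evenness defined as 0, and
`chao1 = S_obs = 1`. Depth-0 rarefaction is 0 by convention. Chao1's
interval collapses to `(S_obs, S_obs)` when there are no singletons.
Consensus taxonomy requires a strict majority (> 50%) per rank; at the
first rank without one the lineage is closed with explicit `unclassified`
sentinels down to the deepest member lineage, so ranks are never silently
omitted mid-lineage.

# Problem sizes in the test suite

The validation suites run at sizes chosen to make the statistical oracles
sharp while keeping the suite fast to iterate on: 10,000-draw Monte-Carlo
oracles for the hypergeometric mean and the rarefaction expectation
(agreement within three standard errors), full-permutation oracles at
`n <= 6`, and 20 generator seeds for the planted-core recovery
(precision and recall, reported as means) and gradient-correlation
(median Spearman rho) targets. The whole suite completes in well under a
minute on one CPU.

# Known limitations

* The core criteria compare counts, not latent abundances; an OTU whose
  true abundance is even but whose counts wobble around the 3-read floor in
  a shallow sample will be excluded. Deeper sequencing, not a looser
  threshold, is the remedy.
* Chao1/ACE are lower-bound-style estimators; on under-sampled communities
  they underestimate true richness (the synthetic tests assert exactly
  this directionality), and their subsample means inherit that bias.
* Exact permutation p-values are available only to `n = 8`; beyond that the
  t approximation is used without continuity correction.
* The ACE interval depends on `vegan`'s standard error and is unavailable
  at non-default rare cutoffs.
* `correlate_all()` refuses constant measures (rank correlation is
  undefined there) rather than imputing; with very few samples this can
  surface on discrete measures such as observed richness.
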