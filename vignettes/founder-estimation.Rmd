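---
title: "Estimating minimum founder numbers from multilocus genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating minimum founder numbers from multilocus genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderest)
```

## The question and the model

An introduced population's allelic diversity bounds its founding history
from below: however few animals the historical record claims, the
founders' genotypes must jointly have carried every allele segregating in
the population today (absent mutation and immigration). **founderest**
turns that bound into an estimate. Given a genetic cluster of `N` diploid
individuals at `L` loci, it asks: what is the smallest number `n` of
diploid founders whose simulated genotypes have an appreciable chance of
containing *all* observed alleles at *all* loci?

Founder genotypes are simulated as `2n` gene copies per locus, loci
independent. The independence assumption (no physical linkage) is
standard for microsatellite panels; no mutation is allowed, so the method
estimates founders of the *current allele inventory*, not of the
population census. Three sampling models bracket the biological
uncertainty:

* **`resample`** — copies are drawn *without replacement* from the
  cluster's observed per-locus allele pool (all `2N_l` typed copies).
  This treats the sample itself as the urn; it is the primary model.
* **`empirical`** — copies are drawn *with replacement* from the
  empirical allele frequencies. Rare alleles are then very unlikely to be
  drawn, so this model systematically needs more founders; it serves as
  an upper bracket and is known to overestimate.
* **`equal`** — copies are drawn with replacement with all observed
  alleles equifrequent. Present-day rare alleles were not necessarily
  rare in the founders — drift erodes frequencies — so this deliberately
  conservative model down-weights the frequency information entirely and
  serves as a lower bracket.

A Monte Carlo replicate *succeeds* when every target allele appears at
least once at every locus. The decision rule scans `n = 1, 2, ...`
ascending, running `R = 1000` fresh replicates per `n`, and accepts the
first `n` whose success count reaches `ceiling(0.05 * R)` (a capture
probability of at least 5%). The scan bound defaults to the cluster size
(`resample` cannot need more than `N` anyway, since drawing all `2N`
copies is certain capture) and to three times the cluster size for
`empirical`; a scan that exhausts the bound returns a censored estimate
rather than a number.

## Exact oracle

Every per-locus capture probability has a closed form by
inclusion–exclusion over the subsets `S` of target alleles that might be
missed:

* equal frequencies: `sum_j (-1)^j C(A,j) ((A-j)/A)^(2n)`;
* empirical frequencies `p_a`: `sum_S (-1)^|S| (1 - sum_{a in S} p_a)^(2n)`;
* without replacement (pool counts `c_a`, total `2N_l`):
  `sum_S (-1)^|S| C(2N_l - c_S, 2n) / C(2N_l, 2n)`, with
  `C(m, k) = 0` for `m < k`.

`capture_probability_exact()` multiplies these over loci. Subset
enumeration is `O(2^A)` per locus, so the oracle refuses loci with more
than 20 alleles (the Monte Carlo path has no such limit). The test suite
checks the Monte Carlo estimator against this oracle on randomized small
instances (within four binomial standard errors at 2,000 replicates),
checks the oracle itself against exhaustive enumeration of all `A^(2n)`
outcomes for tiny cases, and verifies monotonicity of `P(n)` in `n`.

## Filtering putative immigrants

Ongoing introductions and admixture add alleles the founders never
carried. Before estimation, each cluster can be filtered:

* **`all`** — no filtering.
* **`drop_low_freq`** — every individual carrying at least one allele
  with within-cluster frequency strictly below 0.02 is removed.
* **`drop_nonprivate_low_freq`** — as above, but individuals whose
  low-frequency alleles are *private* to the cluster are retained:
  a rare private allele is more plausibly a founder allele declining
  under drift than an immigrant's trace, whereas a rare allele that is
  common elsewhere most likely walked in.

Frequencies are computed once, on the unfiltered cluster (the filter is
a single pass, not iterated to a fixed point), and privacy is assessed
against the full unfiltered dataset. The target allele set *is*
recomputed on the retained individuals, so filtered-out alleles are not
demanded of the founders. Individuals removed under the non-private
variant are always a subset of those removed under the plain variant,
so post-filter allele totals are ordered `b ≤ c ≤ a`. Degenerate cases
are footnoted by `run_founder_table()`: no low-frequency alleles (filter
changes nothing), no private alleles (non-private variant not
applicable), all low-frequency alleles private (non-private variant
removes nobody).

The 0.02 threshold is the conventional cut-off for flagging putative
immigrant alleles in microsatellite studies; comparison is strict
(`freq < 0.02`), so a singleton in a cluster of 25 (frequency 0.02) is
*not* flagged. The `equal` model is by default run only on unfiltered
clusters, because its drift rationale addresses the full observed allele
inventory; the restriction can be lifted with
`equal_unfiltered_only = FALSE`.

## Numerical and design choices

* **Success counting, not probability comparison.** Acceptance uses
  integer success counts (`successes >= ceiling(threshold * R)`),
  avoiding floating-point equality at the boundary.
* **Linear ascending scan.** `P̂(n)` is only stochastically monotone, so
  a binary search could bracket wrongly; the scan tests each `n` with
  independent replicates and stops at the first acceptance.
* **Reproducible substreams.** One root seed is hashed with the cluster
  label, model, filter variant and founder count into a per-cell seed,
  so any single cell of a large report can be reproduced in isolation
  and the full grid is bit-for-bit reproducible.
* **Missing data.** A genotype with one missing allele is treated as
  wholly missing (gene-copy totals stay even). Under `resample`, a locus
  whose typed pool holds fewer than `2n` copies contributes its entire
  pool (capture certain at that locus) with a message.
* **Allele-copy pooling.** The `resample` model pools allele *copies*
  per locus rather than drawing whole diploid profiles; a genotype-unit
  variant (`resample_unit = "genotypes"`) is provided for sensitivity
  analysis. On fully typed data the two agree closely; the copy-pool
  model is the documented default because it matches the per-locus
  independence of the other two models.
* **Inclusion–exclusion clamping.** Alternating subset sums can
  undershoot 0 by a few ulps; exact probabilities are clamped to [0, 1].
* **Rarefaction base.** Allelic richness is rarefied to `g` diploid
  individuals, by default the largest base every cluster and locus
  supports; for a survey whose smallest cluster has 13 typed
  individuals this is the conventional base of 13.
* **F_ST estimator.** Pairwise differentiation uses the Weir–Cockerham
  (1984) variance-components estimator θ summed over alleles and loci.
  Negative estimates are reported as computed (they are the expected
  behaviour of θ near zero differentiation), with an optional floor at
  zero for presentation.

## The synthetic-data generator

No benchmark genotype set accompanies the method, so the package ships a
generative model whose outputs have the structure the estimator assumes,
with known ground truth (`emit_dataset()` returns founder allele sets,
alleles lost to drift, and admixed-individual flags).

The model: per-locus source frequencies (uniform, symmetric Dirichlet,
or geometric); `n_founders` diploid founders drawn from the source
(2 independent copies per locus); `drift_generations` of neutral
Wright–Fisher reproduction at fixed census size (each offspring copy
drawn uniformly from the parental pool; random mating, non-overlapping
generations); then a short joint admixture phase in which each
individual is replaced by a migrant-parented offspring with a
per-generation probability; finally `n_sampled` individuals are sampled
and genotypes are masked at a uniform missing rate. Mutation is
deliberately excluded so allele provenance is exact.

`study_scenario()` fixes the defaults to a six-cluster survey shaped
like a well-documented multi-introduction carnivore invasion: cluster
sample sizes 114, 61, 150, 29, 13, 26 at 20 loci; founder counts spanning
historical record and genetic estimates (25, 60, 28, 13, 7, 23); drift
generations by introduction age (22, 15, 25, 15, 10, 8 at census
60–250); migration 0.01 over 4 recent generations; 1% missing data. The
source uses Dirichlet(0.4) spectra over 9–12 alleles per locus, giving a
source gene diversity near 0.7 with many rare alleles — chosen
analytically so that, after founding bottlenecks and drift of this
depth, cluster heterozygosities land near 0.55–0.70 while pairwise θ
stays in the 0.05–0.17 range typical of such surveys; a markedly more
diverse source cannot satisfy both bands at once.

What the generator does *not* emulate: spatially structured dispersal,
population growth curves (census size is fixed during drift),
genotyping error, allele-size homoplasy, and mutation. Passing tests on
synthetic data therefore demonstrate the estimator's statistical
correctness under its own assumptions, not robustness to those
real-data complications.

## Problem sizes used in the checks

The test suite exercises: exact-vs-enumeration on instances with up to 3
alleles and 6 gene copies; Monte-Carlo-vs-oracle on 60 random instances
(≤ 3 loci, ≤ 5 alleles/locus, N ≤ 20) at 2,000 replicates;
founder-recovery on 51 simulated founder sets of size 5, 10 and 25 (20
loci, 8 equifrequent source alleles, no drift), where the estimate must
fall between the analytic lower bound and the true founder count; and a
full study-shaped end-to-end run at 200 replicates, twice, compared byte
for byte. The acceptance script reruns the study-shaped pipeline at 200
replicates and reports the diversity summaries, the θ range, the
founder-estimate grid and the oracle agreement.

## Known limitations

* The estimate is a *minimum*: it says nothing about how many more
  founders there may have been, and it is sensitive to sample size
  (larger samples reveal more rare alleles and push the bound up).
* The `empirical` model reliably overestimates and is reported for
  bracketing only; the `equal` model's drift compensation is a
  heuristic, not a calibrated inference.
* Estimates under filtering variants depend on the 0.02 threshold and
  on cluster assignment quality; misassigned individuals mimic
  immigrants.
* Weir–Cockerham θ is one of several F_ST definitions; values are not
  numerically interchangeable with AMOVA-based Φ statistics computed by
  other programs, though orderings generally agree.
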