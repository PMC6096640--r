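---
title: "Two-part breeding programs with optimal cross selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-part breeding programs with optimal cross selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twopartsim)
```

## The problem

A line-breeding program (wheat is the motivating crop) pursues two goals at
once: releasing new inbred varieties and improving the germplasm from which
future varieties will come. A *two-part* program makes this split explicit.
A **product development** (PD) component runs the familiar pipeline — crossing
block, doubled-haploid (DH) production, headrow screening, preliminary,
advanced and elite yield trials — and, as a by-product, generates the
genotyped and phenotyped lines that train a genomic selection model. A
**population improvement** (PI) component runs one to six *rapid recurrent
genomic selection* cycles per year on outbred germplasm, using nothing but
marker genotypes and the current prediction model.

Rapid cycling is where the gain comes from — and where the danger lies. With
a fixed yearly genotyping budget, more cycles mean smaller populations per
cycle, faster drift, faster loss of genic variance, and a growing genetic
distance between the (PD-derived) training set and the (PI) prediction set.
`twopartsim` simulates whole programs of this kind and implements **optimal
cross selection** (OCS) as the tool to balance selection against maintenance
of genetic diversity.

## Genome, trait, and meiosis

Founders are simulated directly: per-locus allele frequencies are drawn from
U(0.05, 0.95), haplotypes as independent Bernoulli draws, followed by a
configurable number of random-mating generations (default 10) to build
linkage disequilibrium. Loci that drift below the minor-allele-frequency
floor are resampled so every locus segregates. A coalescent founder model
was deliberately left out of scope: the Bernoulli-plus-random-mating
construction is self-contained, seedable and produces enough LD for genomic
selection to work, which is what the program-level comparisons need.

Meiosis follows the Haldane model: crossover counts per chromosome are
Poisson with mean equal to the map length in Morgans and chiasma positions
are uniform, without interference. DH lines double a single recombinant
gamete and are exactly homozygous. The default genome is desk-scale — 10
chromosomes of 1 Morgan, each carrying 100 causal and 100 marker loci — and
every piece of it is configurable.

The trait is strictly additive: the true genetic value is
$g = \mu + \sum_i d_i \alpha_i$ over causal dosages $d_i$, with substitution
effects drawn from N(0, 1) and rescaled so the founder **genic variance**

$$\sigma_\alpha^2 = 2 \sum_{i} p_i (1 - p_i) \alpha_i^2$$

equals one. Genic variance depends only on allele frequencies, which is what
makes it comparable between inbred PD lines and outbred PI germplasm;
genetic variance (the variance of realized values) differs between those two
because of homozygosity and linkage disequilibrium.

## Genomic prediction

The prediction model is weighted ridge regression on markers (RR-BLUP) with
the intercept as the sole fixed effect:

$$\hat\beta = \arg\min_\beta \sum_j w_j (y_j - \mu - x_j^\top\beta)^2 + \lambda \lVert \beta \rVert^2 ,
\qquad \lambda = \sigma_e^2 / \sigma_\beta^2 .$$

The record weights $w_j$ operationalise *heterogeneous error variance*: a
record with weight $w$ has residual variance $\sigma_e^2 / w$, i.e. acts as
$w$ effective replicates. Defaults by trial stage are headrow 1, preliminary
2, advanced 4, elite 8 — a defensible replication ladder, configurable
because real programs differ. The variance ratio is estimated by REML: the
weighted marker crossproduct is eigendecomposed once and the profiled
restricted likelihood is optimised in one dimension over $\log\lambda$.
Tests verify the estimator against an independent GBLUP dual-form solution
(the observation-space mixed model) to 1e-8, and the weighting scheme
against the exact invariance "replicate a record $k$ times at weight $w/k$
and nothing changes".

The training set starts from the last three burn-in years of trial records
(1000 preliminary + 30 advanced + 10 elite per year = 3120 records) and then
grows by the 1000 new preliminary-trial lines each year; later-stage
phenotypes of lines already in the set are not re-appended, so the set grows
by exactly 1000 records per year. The model is retrained once per simulated
year — so within a year, later PI cycles run on an increasingly stale model,
which is precisely the accuracy-drop mechanism the program comparison is
about.

## Optimal cross selection

Candidates carry genomic breeding values $a$ and belong to a female or male
pool (for hermaphroditic plants the pools are a crossing-design device; the
package assigns them by alternating GEBV rank when none are given).
Coancestry is identity-by-state from markers,
$C = \tfrac12\left(1 + XX^\top / n_m\right)$ with $X = M - 1$ for dosages
$M \in \{0,1,2\}$. A crossing plan assigns each candidate an integer number
of crosses $n_i \in \{0,\dots,4\}$ (each pool contributing one parent per
cross) and pairs the pools. With $x = n / (2 n_c)$:

* expected gain $\bar a = x^\top a$,
* group coancestry $\bar c = x^\top C x$ — the expected inbreeding of the
  next generation.

The gain–diversity balance is set on a **penalty degrees** scale. Two anchor
solutions are computed under identical structural constraints: $S_0$
maximises $\bar a$ (solved exactly by greedy allocation — the objective is
linear with a per-parent cap) and $S_{90}$ minimises $\bar c$ (found by a
dedicated run of the evolutionary optimizer). Both coordinates are
normalized between the anchors, and a target angle $\theta$ demands
normalized coancestry at most $\cos\theta$; the fitness is the normalized
gain minus 10 times the positive excess over that target. $\theta = 0°$
returns $S_0$ itself (truncation-equivalent), $\theta = 90°$ returns
$S_{90}$, and $45°$ weighs the two objectives symmetrically. The cosine
mapping is this package's concrete reading of the degrees dial; it
reproduces both endpoints exactly and behaves monotonically in between,
which the tests check against exhaustive enumeration on small instances.

The optimizer is a standard differential evolution (rand/1/bin). A genotype
is a real vector of per-candidate contribution scores plus rank keys used
only to pair the final plan. Scores are decoded per pool by clamping to
[0, cap], scaling to the pool total $n_c$ with water-filling at the cap, and
largest-remainder rounding — every decoded genotype is feasible by
construction. An earlier decoding that greedily filled parents at the cap
was abandoned: it pinned the number of parents at its minimum and could not
represent the many-parent, low-coancestry plans the optimizer exists to
find. Fitness depends on contributions only (pairing does not change
$\bar a$ or $\bar c$), so the keys are free-riding dimensions; duplicate
(female, male) pairs in the decoded plan are repaired by swaps where
possible and otherwise kept as replicate crosses (configurable).

Four ingredients make the search reliable, and each earned its place against
exhaustive enumeration on small instances:

* a **low crossover rate** (CR = 0.1, with occasional larger per-trial
  draws, and dithered F around 0.7): a genotype has two dimensions per
  candidate, and coordinate-sparse trial vectors climb the decoded
  allocation landscape far better than near-complete crossover, which at
  CR = 0.9 stalled at roughly half the attainable normalized gain on
  100-candidate problems;
* **warm starts**: the greedy maximal-gain solution, the equal-spread
  genotype and the min-coancestry anchor join the random initial
  population;
* an **integer polish**: single-unit contribution transfers within a pool,
  applied to the final solution until no move improves the fitness;
* **independent restarts** (2 by default), because the integer landscape
  has well-separated local optima that no amount of single-unit polishing
  connects.

Defaults are population 40, up to 1000 generations with early stop after
200 stagnant ones; whole-program runs use a lighter documented
configuration (population 24, 200 generations, early stop 60, one restart)
because each year contains up to six optimisations and plan quality there
is judged by the program outcome, not by discrete exactness.

## Program orchestration

The simulated timeline is: 20 years of burn-in under the conventional
phenotypic program, then evaluation-phase selection under one of

* `Conv` — parents selected phenotypically among trial entries,
* `ConvP` / `ConvH` — parents by GEBV at the preliminary / headrow stage,
* two-part with `TS` (truncation, minimum parents), `TS+` (truncation,
  maximum parents) or `OCS`, at `k` cycles per year.

The per-cycle PI budget under constrained costs divides a fixed yearly
budget of 64 crosses and 640 genotyped candidates: crosses
$= \lceil 64/k \rceil$, candidates $= \lceil 640/k \rceil$, parents between
$2\lceil \text{crosses}/4 \rceil$ and $2 \cdot \text{crosses}$. (Note the
ceilings make the yearly totals slightly exceed 640 for k = 3 and 6 — 642
genotyped candidates — which is the cost of keeping per-cycle counts
integral.) Unconstrained costs keep 64/640 per cycle at any k.

Stage sizes of the PD pipeline are configuration with desk-scale defaults:
64 crosses, 50 DH per cross, 1000 preliminary, 30 advanced, 10 elite
entries, with entry-stage heritabilities 0.1 / 0.2 / 0.5 / 0.67 against the
initial genic variance. Each stage takes one year. In the two-part program
the PD crossing block is seeded once a year from the top PI germplasm
(truncation at 32 parents by GEBV), and once a year — in the first cycle —
the current headrow DH lines become eligible as PI candidates, which lets
the optimizer pull diversity back from PD when it is worth it. The yearly
headrow-entry DH cohort is therefore the PI-derived DH set, and it is the
metric population: all comparison metrics are recorded on DH lines prior to
headrow selection, with PI-candidate metrics reported separately under
`pi_`-prefixed names.

## Comparison metrics

All programs are standardized against the burn-in's final year: genetic
gain is reported in units of that year's SD of true genetic values, centred
at its mean, and genic SD relative to that year's genic SD.

**Realized effective population size.** Under drift, genic variance decays
as $\sigma^2_{t+1} = \sigma^2_t (1 - \Delta C)$. A gamma GLM with log link
of genic variance on year (IRLS, convergence 1e-10) gives
$\Delta C = 1 - e^\beta$ and $N_e = 1/(2\Delta C)$. On exactly geometric
input the inversion is exact to numerical tolerance; a constant series gives
$\Delta C = 0$ and an undefined $N_e$, reported as missing.

**Conversion efficiency.** Regressing standardized gain $y_t$ on lost
diversity $x_t = 1 - \sigma_{\alpha,t}/\sigma_{\alpha,\mathrm{ref}}$ gives a
slope $b$: gain extracted per unit of genic SD spent (a trajectory from
(0, 0) to (10, 0.4) has efficiency 25). The fit is a Huber M-estimator
(tuning constant 1.345, IRLS, at most 50 iterations) because first/last
years can sit far off the trend line; consecutive exactly-repeated points —
a program at its selection limit — are dropped first.

Replicate aggregation uses the normal approximation, mean ± 1.96 SE.

## The desk-scale study conditions

The package's canonical comparison (`comparison_scenarios()`, used by the
acceptance suite and `scripts/acceptance.R`) runs the default genome
(10 chromosomes × 200 loci), 10 replicates of 20 burn-in + 10 evaluation
years, constrained budgets — scenario sets Conv / TS / TS+ / OCS at k = 4
("core") plus the k ∈ {1, 6} endpoints of the cycle sweep ("full"). The OCS
penalty degrees are a per-k study condition (14°, 45°, 49° for k = 1, 4, 6):
the per-cycle coancestry budget compounds across the year's cycles, so
faster cycling demands a more conservative angle, and these are the angles
at which OCS delivers its best long-term gain at each cycling rate. These sizes are the package's chosen desk-scale study
conditions: small enough to replicate on a laptop, large enough for the
qualitative results to emerge — OCS retaining more genic diversity than
truncation at equal or better gain, truncation's gain collapsing as k grows
while OCS's does not, and efficiency rising with realized $N_e$ across
programs.

What the generator does *not* emulate matters for interpretation: no
genotype-by-environment or genotype-by-year effects, no non-additive gene
action, no mutation, no coalescent founder structure, and a 10-year (not
20-year) evaluation horizon. Passing tests therefore demonstrate the
mechanics and the direction of the comparisons, not calendar-scale absolute
gains; quantitative magnitudes scale with horizon, training design and
heritability.

## Numerical choices and degenerate inputs

* Ridge REML searches $\log\lambda \in [-15, 25]$ with `optimize()`; an
  all-equal phenotype vector raises an estimation-failure condition, and
  program runs fall back to the previous year's model.
* Accuracy with a constant input is reported as `NA`, never 0.
* OCS normalization with coincident anchors (gain or coancestry range below
  1e-12) drops the degenerate coordinate rather than dividing by it.
* Truncation ties break on (−GEBV, id), so plans are reproducible across
  platforms.
* All randomness flows from user-supplied seeds; child streams are derived
  with a fixed integer recurrence (`child_seed`), and the C++ kernels draw
  from R's RNG so `set.seed()` governs everything, including compiled code.

## Known limitations

* The degrees dial's cosine target is one defensible operationalisation;
  other mappings between the anchors would shift which angle corresponds to
  a given coancestry budget (the endpoints are pinned regardless).
* Group-coancestry enumeration in tests caps at ~10 candidates per pool;
  for much larger pools the optimizer's quality is checked only against
  random search and monotonicity properties.
* The realized-$N_e$ estimator inherits the gamma GLM's sensitivity to
  short, noisy series: with 11 yearly points, per-replicate estimates
  scatter widely, which is why grid summaries average replicates.
* A parent belongs to exactly one pool within a cycle, and selfing is never
  generated; programs for strict selfers would need a different crossing
  model.
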