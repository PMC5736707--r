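---
title: "Modeling longitudinal clonal dynamics with clonedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling longitudinal clonal dynamics with clonedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`clonedyn` reconstructs the subclonal composition of a tumor from serial
sequencing of the same patient and quantifies how each subclone grows or
declines under therapy. It was designed around the setting of chronic
lymphocytic leukemia (CLL) treated with a targeted agent: peripheral
blood is sampled repeatedly over the first year of treatment (typically
at days 0, 30, 60, 90, 180 and 365), somatic mutations detected in any
sample are force-called in all samples, and clinical follow-up records
progression. This vignette describes the model, its assumptions, the
tunable parameters and the numerical choices, and what the synthetic
cohort generator does and does not emulate.

## From read counts to cancer cell fractions

For a mutation present at multiplicity $m$ (mutant copies per carrying
cell) in a fraction $c$ of tumor cells, in a sample of purity $\alpha$
with local tumor copy number $q_t$ and normal copy number $q_n$, the
expected variant allele fraction is

$$ f(c) = \frac{\alpha \, m \, c}{\alpha q_t + (1-\alpha) q_n}. $$

`vaf_to_ccf_posterior()` inverts this relation probabilistically: the
posterior over $c$ on a fixed grid $\{0, 0.01, \dots, 1\}$ (101 points)
is proportional to the binomial likelihood of the observed alt/ref
counts under a uniform prior. Two consequences of the grid choice
matter downstream:

* CCFs are reported at two-decimal resolution, matching how such
  estimates are usually published; the band-probability integral used
  in shift testing is exact on the grid.
* CCFs below 0.01 cannot be represented. A clone that decays below the
  grid resolution is indistinguishable from an absent clone, which is
  why the kinetics fit treats sub-resolution timepoints as
  non-detections (see below).

Multiplicity is chosen per mutation by maximizing the marginal
likelihood integrated over the CCF grid (`choose_multiplicity()`), with
ties going to the smallest $m$. Purity is taken from the input timeline
and never re-estimated: it is an upstream quantity in this design, as
is the allelic copy-number segmentation. Mutations whose closed-form
inversion exceeds 1 are not clipped; their posterior mass simply piles
up at 1.0. Zero-depth observations return a uniform posterior with a
warning; zero-alt observations are first class, since force-calling
exists precisely to measure mutations absent from a given sample.

## Clustering mutations across timepoints

Mutations that arose in the same clone share a CCF trajectory, so
clustering is performed jointly over all timepoints.
`gibbs_cluster()` samples a Dirichlet-process mixture by collapsed
Gibbs sampling: a cluster's latent CCF vector is represented on the
grid, per timepoint, by the normalized product of its members'
posteriors, and a mutation's likelihood under a cluster is the
per-timepoint dot product of the two grid distributions, multiplied
over timepoints. The new-cluster term uses the uniform prior
predictive, which on normalized posteriors is exactly $G^{-T}$ (grid
size $G$, $T$ timepoints). The concentration parameter is resampled
every sweep under a Gamma(1,1) prior with the standard
auxiliary-variable scheme, so the number of clusters varies along the
chain. The chain is initialized with all mutations in one cluster.

Defaults are 1000 sweeps with a 500-sweep burn-in. These are desk-scale
settings chosen because the collapsed sampler mixes quickly on
force-called exome data (tens to a couple of hundred mutations); both
are arguments of `gibbs_cluster()` and `clone_fit()`.

`consensus_clusters()` converts the chain into a point partition by
average-linkage hierarchical clustering of the posterior co-clustering
matrix, cut at distance 0.5 — two mutations end up together when they
co-clustered in at least about half of the retained sweeps. Clusters
are ordered by mean baseline CCF, with ties broken by the smallest
member mutation id so the labeling is reproducible. Singleton clusters
are retained but flagged: a cluster supported by one mutation has no
internal replication, and the kinetics stage treats it specially.

## Detecting early clonal shifts

For each patient the baseline sample is compared with the latest
pre-relapse sample within the first 365 days (relapse samples are
excluded here, though they are used for kinetics). The clusters with
the largest positive and negative CCF change are the rising and
falling candidates. For each candidate, the probability that the
two-timepoint CCF distribution lies within ±0.1 of the diagonal,

$$ p = \sum_{|g_i - g_j| \le 0.1} P_{t_0}(g_i)\,P_{t_1}(g_j), $$

quantifies the null hypothesis that the clone did not move. The "±10%
of the diagonal" band is interpreted on the absolute CCF scale (CCF
lives on $[0,1]$), matching the paired call criterion of an absolute
CCF change above 0.1. The two marginals are treated as independent;
this is an approximation (the chain stores marginals, not the joint),
and it is conservative in the usual direction since clustering noise is
shared across timepoints.

All candidates across the cohort are pooled into a single
Benjamini–Hochberg family (`classify_cohort()`), and a patient is
called *evolved* when any of its tests has adjusted $q < 0.1$ together
with $|\Delta \mathrm{CCF}| > \tau$. The default $\tau = 0.1$; a
sensitivity threshold of 0.05 is exposed as an argument (and as
`--ccf-threshold` in the command-line wrapper). Because the band
probability is a conservative null summary rather than a uniform
p-value, the procedure's realized false-call rate on truly flat
cohorts sits well below the nominal FDR level; the test suite checks
the bound, not equality.

## Phylogeny under CCF constraints

`feasible_trees()` enumerates every parent map over the clusters that
satisfies, at every timepoint, (i) the parent-progeny ordering — a
parent's CCF is at least each child's, and (ii) the sibling sum rule —
children of one parent sum to at most the parent's CCF, or at most 1
under the synthetic germline root. The sum rule is enforced against
the parent's CCF when the parent is a real cluster (the stricter,
standard pigeonhole reading) and against 1 only at the germline root.
Constraints are evaluated on CCF point estimates with a tolerance
`eps = 0.02`, since posterior modes carry one to two grid steps of
noise; enumeration is exhaustive and intended for up to 8 clusters.
When no tree is feasible at the default tolerance, `feasible_trees()`
errors; the orchestrating `clone_fit()` instead doubles `eps` (up to
0.32, with a message) because a mode that dips from 1.00 to 0.96 at a
single timepoint should not abort a whole patient.

When several trees are feasible, `select_tree()` fits each clone's
*clone-exclusive* trajectory (cluster CCF minus its children's, clipped
at zero) with an exponential and picks the topology maximizing the
summed $R^2$; ties go to the shallowest tree and then to the
lexicographically smallest parent vector. Every returned tree is
re-verified by an independent checker (`check_tree()`).

## Clone kinetics and back-extrapolation

Clone CCFs are converted to absolute circulating cell numbers by
multiplying the absolute lymphocyte count (cells/µL), the sample
purity, the clone CCF and the blood volume. The blood volume defaults
to 5 L (5×10⁶ µL) and is configurable; all absolute clone sizes scale
linearly with it, and growth *rates* do not depend on it.

`kinetics_mcmc()` runs the mutation-reassignment MCMC with clusters
and tree held fixed (10,000 iterations by default). Each iteration:

1. reassigns every mutation to a clone from a multinomial distribution
   proportional to its grid-overlap likelihood under each clone;
2. draws each clone's per-timepoint CCF from the product posterior of
   its currently assigned members;
3. subtracts children to get clone-exclusive CCFs (clipped at zero),
   converts to cell counts, and fits ln(count) against day by least
   squares.

Reported rates are posterior medians with 2.5/97.5-percentile credible
intervals, and day-0 sizes come from the fitted intercepts
(`back_extrapolate()` provides the general projection
$N_0 = N_{\mathrm{ref}} e^{-g t_{\mathrm{ref}}}$ with the rate bounds
propagated). Step 2 is a deliberate design choice: drawing the CCF
rather than taking the posterior mode propagates read-count uncertainty
into the intervals. With modes, two well-separated clusters produce a
degenerate chain whose intervals have zero width, which makes the
uncertainty statement meaningless.

Two guards shape the fit. First, clones whose consensus CCF never
reaches 0.1 are excluded from the output (they are too small for rate
estimation at exome depth). Second, within an iteration, timepoints
where a clone's exclusive CCF falls below `ccf_floor = 0.02` (two grid
steps) are treated as non-detections and dropped from that iteration's
fit. Without this, a clone whose true CCF decays to 10⁻⁴ is
alternately recorded as absent (dropped) or as 0.01 (overstated by two
orders of magnitude), which biases decline rates toward zero; treating
the sub-resolution regime as censored removes that bias, and interval
coverage for simulated rates then sits in the nominal range.

Fits with exactly two usable timepoints are flagged: their $R^2$ of 1
reflects saturation, not goodness of fit. Singleton clusters bypass
the reassignment chain entirely — reassignment would dissolve a
one-mutation cluster — and instead get a deterministic log-linear
regression of the trajectory implied by their CCF point estimates,
with regression-theory confidence intervals.

`ccf_rate_stats()` summarizes trajectories as absolute CCF change per
day in an early period (baseline to the sample nearest day 30) and a
late period (to the last sample within day 365), with a deceleration
defined as the difference of the two absolute rates divided by the
difference of the period midpoints. The midpoint differencing is this
package's reconstruction; only the symbol, not the formula, is
standard. When no day-30 sample exists the nearest sample is used and
noted.

## Cohort statistics

`fisher_exact()` (two-sided, probability-mass ordering) and
`km_logrank()` (product-limit curves, 1-df log-rank, and the
observed/expected hazard ratio $(O_1/E_1)/(O_2/E_2)$) delegate to the
standard `stats` and `survival` implementations behind a stable
interface; the test suite checks them against independent enumeration
and hand risk-set bookkeeping. A model-based (proportional-hazards)
hazard ratio is deliberately out of scope: with cohorts of tens of
patients and a handful of events, the O/E summary is the honest
resolution, and its sampling spread at $n = 61$ with ~28% events is
wide — roughly a factor of two around the truth — which is why the
acceptance script reports a median over replicate cohorts.

## The synthetic cohort generator

`simulate_patient()` and `simulate_cohort()` generate cohorts with
known ground truth that emulate the study structure: samples at days
0/30/60/90/180/365; negative-binomial sequencing depth with mean 107
and size 72 (quartiles near 97–119); 2–6 clones per patient on a
branched (probability 15/19) or linear topology; a truncal cluster of
~20 mutations plus ~8–14 per subclone, an exome-scale burden of about
one mutation per megabase; per-clone exponential kinetics with rates
of a few percent per day; ALC declining as the tumor responds (normal
lymphocytes held constant at 1500/µL); purity derived from the tumor
fraction; and a 19/61 prevalence of true early shifts whose presence
multiplies the progression hazard threefold (baseline hazard
2.34×10⁻⁴/day, administrative censoring at day 900, giving ~28%
events). Null (non-evolved) patients share a single rate across all
clones, so their true CCFs are exactly flat. The relapse preset seeds
a resistant clone at 1000 cells growing at 5%/day and adds late
relapse-flagged samples (days 240–365), echoing the regime where
back-extrapolation to treatment start is informative. A `"loh"`
copy-number preset places part of the truncal burden on a
single-copy (del(17p)-like) region to exercise the copy-number-aware
CCF model.

What the generator does **not** emulate: sequencing error and
cross-sample contamination, subclonal copy number, multiplicity above
one, overdispersed (beta-binomial) counts, purity estimation error,
and measurement error in the ALC. Passing tests on this generator
therefore demonstrate correctness of the inference machinery under the
stated generative model, not robustness to assay artifacts — on real
data those enter through the purity, segmentation and count inputs.

## Numerical choices and degenerate inputs

* Grid likelihoods are floored at 10⁻¹² (log scale) before products to
  avoid -Inf; chain dot products are floored at 10⁻³⁰⁰.
* Consensus ties and tree-selection ties have deterministic breaks
  (smallest member id; shallowest tree, then lexicographic parent
  vector), so a fixed seed gives byte-identical output.
* One mutation, one cluster, or one feasible tree are all valid inputs
  and short-circuit sensibly; an empty shift window (no pre-relapse
  follow-up sample) yields no test rather than an error.
* Per-patient seeds in cohort fits are derived from the master seed by
  fixed offsets, keeping runs reproducible under patient-level
  parallelization and all derived seeds below 2³¹.

## Problem sizes used in validation

The test suite and acceptance script run at sizes chosen to exercise
the study regime while staying desk-scale: clustering recovery on
120–150 mutations at depth 100; calibration on 200 null cohorts of 5
patients with a 200-sweep chain; interval coverage on 100 simulated
patients at the full 10,000 kinetics iterations; and end-to-end cohort
analyses of 61 patients with a 600-sweep clustering chain and
2000-iteration kinetics chain, replicated four times in the acceptance
script. These are the package's own validation choices; all lengths
are arguments and can be raised.

## Known limitations

* The clustering likelihood is built from posterior overlap on a fixed
  grid rather than from raw counts; very deep data (≫10⁴×) will be
  limited by the 0.01 grid resolution.
* The band test treats timepoint marginals as independent.
* Phylogeny enumeration is exhaustive and capped at 8 clusters.
* Exponential kinetics are assumed throughout; density-dependent or
  logistic dynamics are out of scope.
* Absolute clone sizes inherit any error in ALC, purity, and the
  assumed blood volume linearly.
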