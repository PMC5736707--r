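# clonedyn

Longitudinal subclonal reconstruction and clonal growth kinetics from
serial tumor sequencing.

`clonedyn` is for analysts tracking how the clonal composition of a
tumor changes under therapy from repeated sequencing of the same
patient — the motivating setting is chronic lymphocytic leukemia (CLL)
on a targeted agent, with peripheral blood exomes at several timepoints
during the first year of treatment, force-called somatic read counts,
per-sample purity and allelic copy number, absolute lymphocyte counts
(ALC), and clinical follow-up.

The package provides, per patient:

* **CCF inference** — posteriors of the cancer cell fraction of every
  mutation at every timepoint on a 101-point grid, from alt/ref counts
  given purity α, local tumor copy number *q*ₜ and multiplicity *m*,
  via the standard allele-fraction model
  *f* = α·*m*·CCF / (α·*q*ₜ + (1−α)·*q*ₙ);
* **multi-timepoint clustering** — a Dirichlet-process mixture sampled
  by collapsed Gibbs, grouping mutations into subclones that share a
  CCF trajectory;
* **clonal-shift testing** — the probability that the largest rising
  and falling clones stayed within ±0.1 of the CCF diagonal between
  baseline and the latest pre-relapse sample, pooled across the cohort
  into one Benjamini–Hochberg FDR family (evolved = adjusted *q* < 0.1
  and |ΔCCF| > 0.1);
* **phylogeny** — exhaustive enumeration of clone trees under the
  pigeonhole (parent ≥ child at every timepoint) and sibling-sum
  (children sum ≤ parent, or ≤ 1 at the root) constraints, selecting
  the topology that maximizes exponential-fit goodness;
* **growth kinetics** — clone CCFs converted to absolute circulating
  cell numbers (ALC × purity × blood volume × CCF) and fitted with
  per-clone exponentials *N(t) = N₀·e^{g·t}* through a 10,000-iteration
  mutation-reassignment MCMC, yielding rates *g* (per day) with 95%
  credible intervals and back-extrapolated clone sizes at treatment
  initiation;
* **cohort statistics** — Fisher exact tests, Kaplan–Meier curves and
  the log-rank test with an O/E hazard-ratio summary;
* **a synthetic-cohort generator** with known ground truth emulating
  the study structure (days 0/30/60/90/180/365, depth ~×107, 2–6
  clones, branched/linear topologies, declining ALC, relapse presets),
  so the whole pipeline is testable end to end without external data.

## Worked example

Simulate one evolved patient (three true clones, a rising subclone)
and fit the full per-patient model:

```r
library(clonedyn)

cfg <- sim_config(n_clones_range = c(3, 3))
sp  <- simulate_patient(cfg, seed = 42, evolved = TRUE)
fit <- clone_fit(sp$mutations, sp$timeline, sp$segments, seed = 7)
summary(fit)
```

```
Patient P01

Subclone CCFs:
 patient_id cluster_id n_mutations sample_id  ccf singleton
        P01          1          20   P01_S01 1.00     FALSE
        ...
        P01          2          25   P01_S01 0.24     FALSE
        P01          2          25   P01_S02 0.51     FALSE
        P01          2          25   P01_S03 0.78     FALSE
        P01          2          25   P01_S04 0.94     FALSE
        P01          2          25   P01_S05 1.00     FALSE
        P01          2          25   P01_S06 0.99     FALSE

Phylogeny: ((2)1)germline; (1 feasible)

Growth kinetics:
 patient_id clone           g      ci_low    ci_high        r2 n_points
        P01     1 -0.02554361 -0.03764514 0.01046455 0.9734802        5
        P01     2  0.01932914  0.01915058 0.01950045 0.9978904        6

Shift candidates (cohort FDR pending):
 patient_id cluster_id direction t0_day t1_day delta_ccf     band_prob
        P01          2    rising      0    365      0.75 9.599861e-150
```

The clustering recovered a truncal clone (20 mutations, CCF 1
throughout) and a rising subclone (25 mutations, CCF 0.24 → 0.99; the
two nested true subclones share a trajectory closely enough to merge).
The only feasible phylogeny nests clone 2 under the trunk. The
kinetics MCMC estimates the subclone's growth rate at 0.0193/day
(about 1.9%/day; the generative rate was 0.02/day) with a tight
credible interval, and the near-zero band probability marks a clear
clonal shift, pending cohort-level FDR adjustment — that plus survival
association comes from `cohort_fit()` on a list of patients:

```r
co   <- simulate_cohort(sim_config(n_patients = 61), seed = 1)
cfit <- cohort_fit(co, seed = 2)
print(cfit)          # evolved fraction, Fisher p, log-rank HR and p
```

`coef()`, `predict()`, `plot()`, `residuals()` and `simulate()`
methods operate on the fitted object; `write_report()` emits the
cluster/shift/kinetics tables and a JSON summary, and
`run_pipeline()` drives everything from the four tab-separated input
tables (`mutations.tsv`, `segments.tsv`, `timeline.tsv`,
`outcomes.tsv`; see `inst/scripts/clonedyn.R` for a command-line
wrapper with `simulate` and `run` subcommands).

## Method notes

See the methods vignette (`vignettes/clonal-dynamics.Rmd`) for the
model assumptions, parameter defaults and units, numerical choices
(grid resolution, detection floor, constraint tolerances, tie-breaks),
what the synthetic generator does and does not emulate, and known
limitations.
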