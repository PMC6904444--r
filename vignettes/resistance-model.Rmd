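---
title: "A branching-process model of platinum resistance and virtual clinical trials in HGSOC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A branching-process model of platinum resistance and virtual clinical trials in HGSOC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vctsim)
```

## The model

High-grade serous ovarian cancer (HGSOC) responds well to first-line
platinum–taxane chemotherapy, yet nearly all advanced tumors relapse
platinum-resistant. `vctsim` models this as a multitype branching
process over eight cell genotypes: three binary resistance mechanisms —
pre-target (reduced platinum bioavailability in the cell), on-target
(enhanced DNA-damage repair) and post-target (dysfunctional apoptosis)
— each irreversibly switched on during cell division.

Every cell divides at rate $b$ and dies at rate $d$ ($b > d$, so the
net growth rate is $\lambda = b - d$). At each division, each inactive
mechanism activates independently with probability $u$ in one daughter
cell; double activations in one division occur with probability $u^2$
and are allowed. A patient's course has three phases:

1. **Pre-treatment.** Growth from a single sensitive cell until the
   total burden first reaches the patient's diagnosis burden
   $M_{\mathrm{diagnosis}}$.
2. **Treatment.** Three cycles of neoadjuvant chemotherapy (NACT),
   interval debulking surgery (IDS), and three adjuvant cycles (ADJ),
   consecutive events separated by one cycle interval. Each
   chemotherapy cycle is an instantaneous pulse that kills a genotype-
   dependent fraction of cells; surgery multiplies every genotype by
   $10^{-\beta}$.
3. **Post-treatment.** Regrowth until the burden re-reaches
   $M_{\mathrm{relapse}}$. The platinum-free interval (PFI) — the
   primary outcome — is the time from the last platinum pulse to that
   relapse, reported in months (30.44 days/month).

A chemotherapy pulse kills a cell with $k$ active mechanisms with
probability $d_{\mathrm{chemo}} \cdot w(k)$, where the weight ladder is
$w(0) = 1$, $w(1) = \alpha_1$, $w(2) = \alpha_2$, $w(3) = 0$:

```{r}
p <- model_parameters()
chemo_weight(0:3, p)
```

### Standard parameters

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `b` | 0.667 | 1/day | division rate |
| `d` | 0.661 | 1/day | death rate (net growth 0.006/day) |
| `u` | 1e-5 | 1/division | per-mechanism activation probability |
| `M_diagnosis_mean` | 3.959e11 | cells | mean burden at diagnosis |
| `M_relapse` | 1e9 | cells | burden defining relapse |
| `d_chemotherapy_mean` | 0.856 | — | mean per-cycle kill on sensitive cells |
| `alpha1`, `alpha2` | 0.02, 0.01 | — | chemotherapy weights, 1 and 2 mechanisms |
| `beta_surgery` | 2 | cell-log kill | debulking surgery |
| `sigma_log_M`, `sigma_log_dchemo` | 0.5, 0.1 | — | patient-level log-normal spreads |
| `cycle_interval_days` | 21 | days | spacing of treatment events |
| `followup_cap_days` | 3653 | days | censoring horizon (120 months) |

The growth, burden and chemotherapy-weight values are the standard set
for advanced HGSOC; `alpha1`, `alpha2` and `u` are the quantities the
grid-search calibration (below) estimates from a PFI cohort. The cycle
interval is not part of that standard set: 21 days is the platinum–
taxane q3w convention, with surgery placed one interval after the last
NACT pulse and the first ADJ pulse one interval after surgery. The
patient-level spreads `sigma_log_M` and `sigma_log_dchemo` are
calibration knobs, not measured truths; the defaults give a virtual
standard-of-care cohort whose Kaplan-Meier curve has a clinically
plausible spread around its median. Both log-normals are parameterized
by their *arithmetic* mean, and the sampled chemotherapy effect is
clamped below 1.

## Targeted drugs

Three agents target the three mechanism classes: trientine (copper
chelation, restores platinum uptake; pre-target), a Wee1 inhibitor
(abrogates the G2/M checkpoint, resensitizing repair-proficient cells;
on-target) and birinapant (IAP antagonist, restores apoptosis;
post-target). A drug's *total relative efficacy* aggregates three
evidence levels, $E = 0.2\,I + 0.3\,V + 0.5\,C$ (clinical evidence
weighted 2.5× in vitro, in vivo at 60% of clinical). The registry
carries the aggregate efficacies $E = 0.41$ (trientine), $0.85$ (Wee1)
and $0.35$ (birinapant); the underlying per-level values are not
re-derived here, so the registry stores the aggregates directly and
applies the formula only when a user supplies all of $I, V, C$.

**Drug action (a genuinely open design point).** The per-level
evidence summaries do not fix *how* $E$ enters the dynamics. `vctsim`
adopts a uniform mechanism-neutralization model: at each pulse, a drug
whose target mechanism is active in a genotype moves that genotype's
weight one rung back toward sensitivity,
$w \leftarrow w + E\,(w(k-1) - w)$, applied once per covered active
mechanism in fixed (pre, on, post) order. Drugs never touch genotypes
that lack their target. This keeps all three drug classes comparable
through a single efficacy scale and makes kill fractions monotone in
$E$ and in the drug set:

```{r}
wee1 <- default_drug_registry()$wee1
build_kill_map(p, 0.856, wee1)
```

An alternative reading treats $E$ as a prescribed relative reduction
in post-treatment burden. `calibrate_drug_effect()` implements that as
a switch: it bisects the neutralization strength until a pilot cohort
matches a target reduction. Because a single-mechanism drug can only
deplete the genotypes carrying its target, and the three
single-mechanism compartments are statistically exchangeable at
diagnosis, reductions beyond roughly that compartment's share
(about one third of the residual, plus composition effects) are
structurally unattainable under this model family; the function then
reports the achievable maximum rather than silently failing. This
ceiling is the main known divergence from the published per-arm
magnitudes (99%+ reductions, 26-month single-drug medians), which
evidently relied on stronger cross-compartment drug mechanics whose
details are not reconstructible from the available description; the
`cmd_reproduce()` report tabulates simulated values next to the
published ones and flags every deviation beyond 20%.

## Simulation engines

* **`exact`** — Gillespie simulation of the 8-type
  birth–death–mutation process (compiled). Feasible up to ~1e6 cells;
  the reference for correctness.
* **`hybrid`** (default) — clones above `hybrid_threshold` (1e4 cells;
  drift is negligible there at $\lambda = 0.006$/day) grow
  deterministically at their genotype's effective net rate
  $\lambda_i = b(1-u)^{m_i} - d$ ($m_i$ inactive mechanisms: a
  mutating daughter leaves its parent's genotype). New mutant lineages
  are emitted as a Poisson process with rate $u\,b\,N(t)$ per inactive
  mechanism; each founder is thinned by its exact finite-horizon
  survival probability $1-\alpha(\delta)$ and, if it survives to the
  end of the step ($\delta$ away), enters with the exact single-cell
  linear birth–death size law $1 + \mathrm{Geom}(1-\beta(\delta))$ —
  so each lineage is exact in distribution at every horizon, not just
  asymptotically; early drift extinction (probability $d/b \approx
  0.991$ per lineage) is in the thinning. Only a new lineage's *own*
  onward mutation within its founding step is neglected, which the
  step-size cap $u\,b\,\Delta \le 0.01$ controls. When the expected
  number of surviving founders in a step exceeds 300, the flux is
  added as its exact expectation instead (relative fluctuations are
  then below ~3%). Clones below the threshold are advanced with the
  exact linear birth–death transition law (binomial survivors plus
  negative-binomial offspring), so small-clone extinction costs no
  per-event work.
* **`deterministic`** — mean-field matrix exponential of the 8×8 rate
  generator; used for closed-form checks and fast previews.

Stochastic engines condition the pre-treatment phase on non-extinction
by resampling (extinction probability from one cell is $d/b \approx
0.991$; the resample cap is 10,000 attempts). A `"seeded"` shortcut
instead starts the deterministic core at $b/(b-d) \approx 111$ cells —
the mean size of a surviving lineage — and is validated against
resampling in the test suite.

Numerical conventions: chunked stepping with chunks of at most
$1/\lambda$ days; early stopping on a burden threshold aims the last
chunk at the projected crossing, so the diagnosis state overshoots
$M_{\mathrm{diagnosis}}$ by less than one e-fold (exactly hit in the
deterministic engine); stochastic pulses draw binomial survivors for
clones below the hybrid threshold and act multiplicatively above it;
an empty tumor at or after treatment is a censored outcome at the
follow-up cap. Hybrid steps are capped at one e-fold of growth
($1/\lambda$ days) and additionally at $0.01/(u\,b)$ days so that
within-step second-order mutation stays negligible.

## Virtual clinical trials

`run_rcts()` assigns `n_per_arm` *independent* virtual patients to
each arm (the first arm is the chemotherapy-alone reference), each
patient defined by a log-normal draw of $(M_{\mathrm{diagnosis}},
d_{\mathrm{chemo}})$ and a private simulation seed; one base seed
spawns interleaved, prefix-stable per-patient substreams, so enlarging
a cohort never reshuffles existing patients. Readouts: per-arm
Kaplan-Meier curves and medians (product-limit estimator via the
`survival` package), mean post-treatment burden and its ratio to the
reference arm, mean residual composition, and pairwise log-rank tests.

`run_mscts()` stratifies by an ideal biomarker (100% sensitivity and
specificity) for the *dominant* resistance mechanism — the mechanism
carried by the most cells at diagnosis, ties broken in (pre, on, post)
order, tumors without resistant cells assigned "pre" by the same rule.
Both arms receive chemotherapy plus the drug. Two filling modes are
provided because the published design is ambiguous: `"fill"` (default)
samples patients until each arm holds `n_per_arm`; `"pool"` splits one
cohort of `n_per_arm` by biomarker, giving unequal arms.

## Calibration

`calibrate_grid()` estimates $(u, \alpha_1, \alpha_2)$ from a PFI
cohort by grid search: for each combination it simulates a
standard-of-care cohort (common random numbers across grid points),
computes the Kaplan-Meier curve, and scores the root-mean-square error
against the cohort's curve on a monthly grid from 0 to the 95th
percentile of observed times (the evaluation grid is a package
convention; only "a PFI analysis" is prescribed). Combinations with
$\alpha_2 > \alpha_1$ violate the weight ordering and are skipped. The
paper-scale grid (100 log-spaced values of $u$ in $[10^{-8}, 10^{-4}]$
× 101 × 101 weight values ≈ 1.02 million combinations) is expressible
but long-running; the packaged experiments use coarse grids with
reduced burdens.

Identifiability note: $\alpha_2$ only acts through double-mutant
cells, whose load scales like $(u\,b\,t)^2$. At the standard $u =
10^{-5}$ the residual is dominated by single-mechanism cells and
$\alpha_2$ is nearly unidentifiable from PFI curves alone. The
parameter-recovery experiment in the test suite therefore probes a
regime where doubles matter ($u = 10^{-4}$, large $\alpha_1$), which
is the honest statement of what a PFI-only calibration can and cannot
pin down.

Because the real calibration and validation cohorts are not shipped,
`generate_synthetic_cohort()` draws PFIs from a Weibull scaled to a
target median (shape 1.5 for a realistic right skew, optional uniform
censoring). It is labelled synthetic throughout: it reproduces a
median and skew, not the covariate structure, follow-up pattern or
measurement process of any clinical series — so tests passing against
it demonstrate the machinery, not clinical validity.

## Problem sizes and what the tests show

The packaged experiments use scaled instances chosen to keep the full
suite reproducible on a single CPU: engine-equivalence comparisons at
~1e5 cells with $u = 10^{-3}$ (200 replicates, means within 3
Monte-Carlo SE), lineage-survival checks against $(b-d)/b$ with 1e5
single-cell replicates, parameter recovery on a 3×3×3 grid with
1e6-cell tumors, and full-scale (3.959e11 cells) trial arms of 1,000
patients for the headline readouts. The hybrid engine makes the
full-scale patient ~10 ms, so paper-scale cohorts are routine; the
exact engine is only feasible at the scaled sizes, which is precisely
why the hybrid engine exists.

Under the standard parameters the simulated standard-of-care median
PFI and the drug-arm magnitudes come out below the published reference
values (the `cmd_reproduce()` report quantifies this per arm). What
does reproduce under the neutralization model: the Wee1 arm dominates
every other arm, the Wee1 arm retains the largest sensitive residual
fraction of the single-drug arms, tumors are mostly sensitive at
diagnosis, and the post-chemotherapy residual is dominated by
single-mechanism cells. What does not: the published
birinapant-over-trientine ordering (any model monotone in a single
efficacy scale with exchangeable mechanisms favours trientine,
E = 0.41, over birinapant, E = 0.35) and the published
stratification-benefit ordering, which at 1,000 patients per arm sits
within Monte-Carlo noise here.

## Limitations

No pharmacokinetics, dose–response or toxicity; no tumor
microenvironment; no second-line treatment or platinum rechallenge; no
spatial structure; biomarkers are ideal; drug action is the
neutralization model described above. The hybrid engine neglects a new
lineage's own mutations within its founding step and treats
above-threshold clones as continuous masses; both approximations are
validated against the exact engine at scaled sizes in the test suite.
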