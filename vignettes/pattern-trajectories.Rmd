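---
title: "Modelling combined multimorbidity–polypharmacy pattern trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling combined multimorbidity–polypharmacy pattern trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mptraj)
```

## The problem and the model

In cohorts of older adults with cardiovascular disease, chronic conditions
and their medications cluster together and evolve jointly. `mptraj` models
a yearly person×wave panel in two steps: a cross-sectional soft clustering
of person-waves in a reduced feature space, then a hidden Markov model
(HMM) over each person's yearly sequence whose live states correspond to
the clusters.

Formally, person $i$ contributes score vectors $x_{i1},\dots,x_{iT_i}$
(the retained mixed-data principal components of their disease–drug group
indicators, age and sex). A latent state $q_{it}$ follows a first-order
Markov chain over $K$ live states with initial law $\pi$ and transition
matrix $A$ of size $(K{+}2)\times(K{+}2)$; states $K{+}1$ (death) and
$K{+}2$ (dropout) are absorbing. Emissions are diagonal Gaussians
$x_{it}\mid q_{it}=k \sim \mathcal N(\mu_k,\mathrm{diag}\,\sigma^2_k)$.

Death and dropout are *observed*, not inferred: their labels are in the
data, so their emission probability is 1 in their own state and 0
elsewhere, and only the incoming transition rates $A_{k,K+1}, A_{k,K+2}$
are estimated. A sequence ending in an exit has likelihood equal to its
live-part likelihood times the exit transition probability; a person still
active at the study horizon contributes the live part only (administrative
censoring). The EM (Baum–Welch) updates follow from this likelihood
exactly, which is why the implementation can assert a non-decreasing
log-likelihood trace on every fit.

## Feature construction

The raw panel carries 60 binary chronic-disease indicators and 89 drug
invoice counts per person-wave. The defaults mirror the conventions of the
multimorbidity literature:

* **chronic use**: ≥ 3 packages of a drug category (`min_packages = 3`).
  The package counts packages *per wave* so that indicators exist per
  year; counting over the whole period is available by pooling before the
  call.
* **polypharmacy**: ≥ 5 chronically used categories; **multimorbidity**:
  ≥ 2 of the 60 disease categories.
* **baseline-use filter**: drug categories chronically used by < 1% of the
  wave-1 active population are dropped (`baseline_use_fraction = 0.01`).
* **disease–drug groups**: a mapped category requires diagnosis AND ≥ 1
  chronically used mapped drug. The mapping ships 46 mapped + 14
  disease-only categories. Because the literature is ambiguous on whether
  concurrent drug use should be required, a `diagnosis_only` mode is
  provided; the default is the stricter `and` rule, since the groups are
  explicitly *disease–drug* constructs distinct from the "(D)"
  disease-only categories.
* **median-prevalence filter**: keep groups whose median prevalence across
  waves is ≥ 2% (`median_prevalence_threshold = 0.02`). Prevalence
  denominators at wave $t$ are the persons active at $t$: summaries are
  reported among survivors, so the dead must not dilute them.

Duplicate (person, wave) rows are hard errors, never silently
de-duplicated.

## Mixed-data reduction and component retention

Quantitative columns are centred and scaled to unit population variance;
each categorical variable is expanded to level indicators, centred by the
level frequency $p_s$ and scaled by $1/\sqrt{p_s}$. With uniform row
weights $1/n$ the total variance is $P = p_{\text{quant}} + (q -
p_{\text{qual}})$, and the decomposition coincides with
correlation-matrix PCA when all variables are quantitative and with
multiple correspondence analysis (eigenvalues scaled by
$p_{\text{qual}}$) when all are categorical — both limits are enforced in
the test suite to $10^{-8}$ against independently coded oracles.

Binary group indicators enter as two-level categorical variables (the
mixed-data convention), not as 0/1 numeric columns. Components are
retained by the Karlis–Saporta–Spinaki rule, $\lambda > 1 +
2\sqrt{(P-1)/(n-1)}$; the rule is stated for PCA, and we use the
effective variable count $P$ above to preserve its mean-eigenvalue-of-1
logic for mixed data — an interpretation, flagged as such. All
person-waves are pooled for one fit (the longitudinal data are reduced
jointly), and per-wave rows are scored by projection with the stored
scaling constants. Loading signs are fixed by making each vector's
largest-magnitude entry positive, so runs are platform-reproducible.

Degenerate inputs: zero-variance quantitative columns and unobserved
categorical levels are errors naming the column; rank-deficient inputs
return fewer eigenpairs rather than NaNs.

## Fuzzy c-means

The fuzzifier is not dictated by the source methodology, so the field
standard $m = 2$ is the default. Initialization is k-means++-style seeding
on the scores with a small jitter (seeds that sit exactly on data points
would otherwise be pinned by the zero-distance rule at extreme fuzzifier
values), multi-restart with best-objective selection (`fcm_restarts = 5`
inside `mpt_fit()`), and the degenerate zero-distance case assigns
singleton membership to the lowest coincident cluster index. The
objective trace is checked to be non-increasing on every fit.

## HMM estimation choices

* **Initialization from the clustering**: $\mu_k$ = fuzzy centroid,
  $\sigma^2_k$ = membership-weighted within-cluster variance (floored at
  `variance_floor = 1e-4` to prevent collapse on duplicated rows), $\pi$ =
  mean wave-1 membership, live transition block = row-normalized
  consecutive-wave crisp-label counts, exit columns = empirical exit
  frequencies. Empty crisp clusters are re-seeded from the global
  distribution, with a message.
* **Restarts**: the default `n_restarts = 100` runs EM from the cluster
  initialization plus 99 perturbed versions and keeps the best final
  log-likelihood — restarts mitigate EM's local optima. After selection,
  states are relabelled to the nearest fuzzy centroid so pattern names
  are stable across restarts.
* **Decoding**: Viterbi in log space, ties toward the lower state index.
  The decoded exit appears exactly at the person's exit wave; live-wave
  posteriors come from the scaled forward–backward pass (underflow-safe
  via per-wave renormalization plus a per-observation log-density shift).
* **Choosing K**: `scan_K()` reports best log-likelihood per K and makes
  no automatic choice; with nested models and enough restarts the profile
  is non-decreasing in K, and the analyst balances fit against
  interpretability.

## The synthetic cohort generator

The generator emulates the study design the method targets: a *closed*
cohort aged 65–99 at baseline (no new entries), five yearly waves, exits
only through death or transfer, one panel record per person-wave up to
and including the exit wave. Each person carries a latent pattern
evolving by a configurable $(K{+}2)\times(K{+}2)$ chain; wave-1 states
are always live. Within-person randomness uses a per-person substream of
the global seed, so a person's records are invariant to cohort size and
ordering.

Default emission of observables, chosen once as field-plausible values:

* diseases: baseline Bernoulli by the pattern profile, then monotone
  acquisition with per-wave onset probability `incidence_factor` × the
  profile prevalence (default 0.05 — chronic diseases persist and accrue
  slowly);
* drugs: per-wave use Bernoulli by profile; used categories invoice
  Poisson(`invoice_rate = 6`) packages a year, unused ones
  Poisson(`sporadic_rate = 0.2`), which makes the ≥ 3-package chronic-use
  dichotomy noisy but informative;
* demographics: pattern-specific truncated-normal ages (+1 per wave),
  pattern-specific sex probabilities, a 6-level deprivation category
  independent of pattern (descriptive only), Poisson visit counts.

`example_cohort_config()` plants disjoint signature-disease blocks per
pattern (prevalence `separation = 0.65`) over a common background
(`background = 0.08`), sized so that exactly 41 of the 60 groups survive
the 2% median-prevalence filter, and so that each signature group's O/E
ratio exceeds 2 in its pattern.

What the generator does **not** emulate: laboratory values, ICD-coded
diagnoses, open-cohort dynamics, informative dropout, or onset dynamics
calibrated to any real registry. Passing recovery tests therefore shows
the pipeline recovers the truth of *this* generative family — Markov
patterns expressed through disease/drug Bernoulli profiles — not that
real EHR panels satisfy those assumptions.

## Benchmarks and problem sizes

The recovery benchmark in the test suite uses K = 4 patterns, n = 3000
persons, 5 waves and 10 EM restarts, with a *well-separated* variant of
the example configuration (`separation = 0.7`, `background = 0.04`,
`incidence_factor = 1`): onset probability equal to the profile prevalence
makes the current latent state fully expressed in that wave's features,
which is what "well separated" must mean for yearly decoding to be
identifiable at all — under slow onset (the realistic default) a person's
features lag their latent switch by design, and no decoder can attribute
the lag wave correctly. On this benchmark the pipeline attains an
adjusted Rand index ≥ 0.90 between decoded and true live states and
recovers every transition-matrix entry within 0.05 after state matching.
Smaller configurations (a few hundred persons, K = 2–3) are used
throughout the unit tests to keep the suite fast.

## Numerical conventions

* report tables round half-up to 2 decimals; raw full-precision tables
  are always emitted alongside;
* O/E is flagged at strictly > 2; exclusivity at ≥ 30%;
* empirical transition rows with no observed outgoing moves (a pattern
  never occupied before the final wave) are set to "stay" (identity row)
  so summaries remain row-stochastic;
* per-pattern-wave statistics on an empty pattern are reported missing
  (`NA`), never as 0;
* the time-homogeneous transition summary pools all consecutive wave
  pairs; per-wave-pair matrices are available with `by_wave = TRUE`, since
  a single pooled matrix and per-period views answer different questions
  and the literature mixes both.

## Known limitations

Transitions are time-homogeneous and covariate-free; there is no
semi-Markov dwell-time modelling, no missing-wave interpolation, and no
statistical testing across patterns (the summary tables expose the counts
needed to run tests externally). Emissions are diagonal Gaussians over
scores; full covariance is a possible extension. The KSS rule's mixed-data
form is an interpretation, and the number of retained components on real
data should be inspected (`print(fit$pcamix)`), not trusted blindly.
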