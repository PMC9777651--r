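# mptraj: combined multimorbidity–polypharmacy pattern trajectories

Older people with cardiovascular disease rarely carry one diagnosis or one
prescription. They accumulate chronic conditions (multimorbidity, here: two
or more of 60 chronic-disease categories) and the drugs that treat them
(polypharmacy: chronic use of five or more ATC level-4 drug categories).
`mptraj` identifies *combined* patterns of diseases **and** their
medication in longitudinal primary-care panels, and models how people move
between patterns from year to year — including the moves nobody returns
from: death and dropout.

The package is aimed at epidemiologists and health-services researchers
working with EHR-derived yearly panels, and at methodologists who want a
fully testable implementation of this two-step clustering pipeline with a
ground-truth synthetic cohort generator.

## The method

1. **Feature construction.** Per person-wave, each drug category is flagged
   as chronically used when ≥ 3 packages were invoiced that year; drug
   categories used by < 1% of the baseline population are dropped. Each
   disease category becomes a *disease–drug group*: diagnosis **and**
   chronic use of a mapped drug (diagnosis alone for the 14 unmappable
   "(D)" categories). Groups with median prevalence across waves < 2% are
   filtered out.
2. **Mixed-data reduction (PCAmix).** Age (quantitative) plus sex and the
   binary group indicators (categorical) are jointly decomposed; with q
   total levels over p_qual categorical variables the total variance is
   P = p_quant + (q − p_qual). Components with eigenvalue
   λ > 1 + 2·√((P−1)/(n−1)) are retained (Karlis–Saporta–Spinaki rule).
3. **Fuzzy c-means** (fuzzifier m = 2) on the component scores gives soft
   memberships u_ik with Σ_k u_ik = 1, minimizing
   J = Σ_i Σ_k u_ik^m ‖x_i − c_k‖².
4. **Hidden Markov model.** Each cluster seeds one live hidden state with
   diagonal-Gaussian emissions over the scores; two absorbing states
   (death, dropout) are *observed* at exit. Parameters (π, A, μ_k, σ²_k)
   are estimated by Baum–Welch from the cluster initialization plus
   randomly perturbed restarts (default 100), keeping the best
   log-likelihood; trajectories are decoded with Viterbi.
5. **Pattern statistics.** Per pattern/group/wave: prevalence, the
   observed/expected ratio O/E = cluster prevalence ÷ population prevalence
   (overrepresented when O/E > 2), exclusivity = share of all carriers in
   the pattern (salient when ≥ 30%), plus empirical transition matrices,
   permanence (the live diagonal), per-pattern mortality, and a
   sequence-index export.

Because primary-care registry data of this kind (e.g., SIDIAP) cannot
generally be shared, the package
ships a seeded generator for closed cohorts of 65–99-year-olds with known
latent patterns, monotone chronic-disease acquisition, Poisson drug
invoicing and a first-order Markov trajectory process with absorbing death
and dropout — so every stage is testable against known truth.

## Worked example

```r
library(mptraj)

cfg    <- example_cohort_config(n_individuals = 1000, K = 3, seed = 42)
cohort <- generate_cohort(cfg)       # panel + ground truth
fit    <- mpt_fit(cohort$panel, K = 3, n_restarts = 10, seed = 42)
summary(fit)
```

```
Patterns: 3  persons: 1000 
Baseline sizes: 360, 326, 314 
Permanence (%): 89.2, 88.5, 88.4 
Mortality (%):   28.3, 27, 31.2 
Log-likelihood: -14248.96 

Top overrepresented groups, wave_1 (O/E > 2 flagged):
 pattern group prevalence   oe exclusivity overrepresented
       1 d_024      67.22 2.62       94.16            TRUE
       1 d_033      62.78 2.60       93.78            TRUE
       1 d_015      60.28 2.60       93.53            TRUE
       ...
```

Reading this: 1000 simulated persons fall into three patterns of roughly
equal size; between consecutive years ~89% stay in their pattern
(permanence), and 27–31% of each pattern's baseline members die within the
five waves. Group `d_024` is carried by 67.2% of pattern 1's members —
2.62 times its population prevalence (overrepresented), and 94% of
everyone carrying it sits in pattern 1 (exclusivity). `plot(fit)` draws
the sequence-index figure; `predict(fit, new_panel)` decodes new persons;
`simulate(fit, nsim)` draws trajectories from the fitted model;
`run_pipeline()` executes the same flow from a YAML/JSON config and writes
every table to disk with a checksum manifest.

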