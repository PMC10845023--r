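# breathloop

Simulation and analysis of a two-arm digital mindfulness/compassion trial
built around **closed-loop, performance-adaptive attention-to-breath
training**, for researchers developing or evaluating digital meditation
interventions with behavioural and EEG outcomes.

The package covers the full study loop:

* **Training engine** — the adaptive state machine: at level *L* the
  trainee taps after every *L* breaths for *L*-minute blocks; three
  consecutive consistent blocks (tap count within ±1 of expected and
  inter-tap CV ≤ 0.25) promote the level, capped at 10; chimes flag
  distracted intervals; ten compassion prompts advance every 6 of 60
  sessions. A stochastic simulated user (lognormal breathing, per-breath
  lapses, truncated-normal motivation) produces realistic session logs.
* **Interoceptive assessment** — the eyes-closed breath-monitoring task is
  scored from inter-tap response times: a trial is *attended* when
  |RT − median| ≤ MAD (unscaled median absolute deviation), *distracted*
  otherwise.
* **EEG pipeline** — 24-channel 10-20 recordings are band-passed to
  8–12 Hz, cut into 4 s pre-tap epochs, projected onto ~200 spherical-head
  cortical sources by a Tikhonov minimum-norm inverse
  (K = Gᵀ(GGᵀ + λμI)⁻¹, λ = 0.1), and summarised as mean alpha envelopes
  for the FPN, CON and DMN networks by attention condition, with a
  forward-model synthetic EEG generator for validation.
* **Trial statistics** — pooled-SD Cohen *d* = (m₂ − m₁)/√((s₁² + s₂²)/2),
  normality-gated paired tests (Shapiro–Wilk gate, Wilcoxon fallback),
  Cronbach α, Spearman and rank-residual partial Spearman correlations,
  and the 2 × 2 mixed ANOVA with partial η² (Greenhouse–Geisser ε = 1 at
  two levels, noted in the report).
* **Synthetic cohort** — a Gaussian-copula generator reproducing the
  study conditions (n = 22/21, published per-timepoint means/SDs,
  adherence mean 40.64 SD 17.79 of 60 sessions, configured
  adherence↔outcome and DMN↔outcome rank correlations, follow-up dropout
  2/1) so every stage is exercisable without raw data.

## Worked example

The published pooled-SD effect size for the trained group's
self-compassion gain reproduces directly from the printed summary
statistics:

```r
library(breathloop)
cohen_d_within(2.69, 0.57, 3.02, 0.58)
#> 0.57
```

Scoring an interoceptive run — the median/MAD rule flags the two slow
outliers (8.4 s, 12.1 s) and the fast-tap miscounts relative to the 5 s
breathing cluster:

```r
classify_trials(c(5.1, 4.9, 5.0, 5.2, 8.4, 5.0, 4.8, 12.1))
#> Interoceptive trial series: 8 trials
#>   median RT 5.05 s, MAD 0.15 s (two-sided rule)
#>   attended 5, distracted 3
```

A full synthetic trial, generated and analysed end to end:

```r
coh <- generate_cohort(cohort_spec(), seed = 7, session_logs = FALSE)
an  <- analyze_trial(coh$outcomes, coh$activity, training_group = "training")
an$effect_sizes[an$effect_sizes$outcome == "self_compassion",
                c("group", "contrast", "n", "cohen_d", "p", "test_used")]
#>     group contrast  n    cohen_d            p test_used
#>  training    T2-T1 22 0.80165611 0.0002900745  paired-t
#>   control    T2-T1 21 0.00808785 0.9592763787  paired-t
#>  training    T3-T1 20 0.91078719 0.0005305524  paired-t
#>   control    T3-T1 20 0.57274844 0.0387080428  paired-t

an$adherence
#>                              pair       rho           p  n
#>    sessions~delta_self_compassion 0.6274945 0.001771323 22
#>  sessions~delta_state_mindfulness 0.2958594 0.181268138 22
```

The trained group improves (d ≈ 0.8 at this seed; the configured
population value is 0.57 — single 22-participant samples scatter around
it), the control group does not, and more practice tracks larger
self-compassion gains, mirroring the generator's configured couplings.
`run_full_pipeline(run_config(seed = 1), "out/")` chains cohort
generation, training simulation, assessment scoring, the EEG stage and
the analysis into a JSON + Markdown report with a provenance block, and
is byte-reproducible for a fixed seed.

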