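---
title: "Methods: closed-loop breath training, interoceptive scoring, and alpha-band network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: closed-loop breath training, interoceptive scoring, and alpha-band network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathloop)
```

`breathloop` models a two-arm digital mindfulness/compassion trial end to
end: a closed-loop, performance-adaptive breath-counting intervention; an
eyes-closed interoceptive assessment scored by a median/MAD response-time
rule; alpha-band (8–12 Hz) EEG source-network activity for the
fronto-parietal (FPN), cingulo-opercular (CON) and default mode (DMN)
networks; and the trial's inferential statistics. Because raw participant
data of such trials are rarely public, every stage is paired with a
synthetic generator whose defaults encode the published study conditions
(n = 22 trained / 21 control; adherence mean 40.64, SD 17.79 of 60
sessions; the per-timepoint outcome means/SDs), so the full analysis is
reproducible and testable from nothing but code.

## The closed-loop training engine

At level $L$ the trainee taps after every $L$ breaths and a block lasts
$L$ minutes, so the level jointly encodes counting span and time on task.
Promotion requires `repeats_required = 3` *consecutive* consistent blocks;
an inconsistent block resets the streak; there is no demotion, so the level
trajectory is nondecreasing and capped at 10, where the trainee stays for
the remainder of the 60 assigned sessions. Ten compassion prompts advance
every 6 sessions (`prompt_id = min(ceiling(session/6), 10)`).

The deployed app's consistency rule is not published, so the package makes
it explicit and configurable:

* **count rule** — the tap count must lie within ±1 of the expected count,
  which at the nominal 6 s breath period is 10 taps for every level
  ($L$ minutes at $L$ breaths per tap);
* **regularity rule** — the coefficient of variation of inter-tap
  intervals must not exceed 0.25;
* **chime rule** — a reminder chime fires whenever an interval exceeds
  $(1 + 0.25)\times$ the running median of the preceding intervals, a
  concrete stand-in for "distraction feedback".

Sessions are packed from blocks at the current level until at least 5
minutes are reached (never exceeding 10), which reproduces 5–10-minute
sessions at every level; promotions can occur mid-session.

The simulated user draws lognormal breath periods (mean 6 s, SD 0.6 s by
default) and has two per-breath lapse channels: a *miscount* (probability
`lapse_rate`) silently inserts an extra breath into the current interval —
a large relative error at low levels, negligible at high ones — and a
*zone-out* (probability `lapse_rate/3`) suppresses the tap entirely, which
bites hardest at high levels where one tap spans many breaths. This keeps
per-block difficulty roughly level-flat, so attainment is limited mainly
by sessions practised; with the cohort default of Beta(3, 120) lapse-rate
heterogeneity (mean ≈ 0.024), the sessions-completed ↔ final-level
Spearman correlation is reliably positive (typically 0.5–0.6 at n = 22).
Sessions completed are drawn from a normal distribution (mean 40.64,
SD 17.79) clipped to 0–60; the point mass at 60 mimics completers.

## Interoceptive trial scoring

Response times are inter-tap intervals (the first tap has no RT). A trial
is *attended* when $|RT - \mathrm{median}| \le \mathrm{MAD}$ and
*distracted* otherwise, with the MAD left unscaled (no 1.4826 factor) —
the rule is the study's operational definition, not a robust-SD estimate.
The rule is applied two-sided by default because both slow and fast taps
indicate miscounting; a one-sided variant (only slow outliers distracted)
is available. Ties at exactly one MAD are attended, and an epsilon guard
makes the boundary robust to floating-point representation.

One structural property deserves emphasis: since the MAD is the *median*
absolute deviation, roughly half of all trials fall within one MAD of the
median for any continuous RT distribution, so the *fraction* of distracted
trials is pinned near one half regardless of how distractible the
participant is. Lapses instead show up in the *magnitude* of the MAD and
of the outlying deviations. Tests therefore assert the magnitude
signature, not a count signature, and downstream contrasts
(distracted − attended activity) rely on the labels, not the label
proportions.

## Alpha-band EEG network pipeline

The sensor model is a 24-channel 10–20 montage on a unit sphere; sources
are ~200 radially oriented dipoles on a Fibonacci lattice at radius 0.8,
with free-space dipole gains column-normalised to unit norm. Eleven named
regions (DMN: medial prefrontal, posterior cingulate/precuneus, bilateral
angular; FPN: bilateral dorsolateral prefrontal and superior parietal;
CON: bilateral anterior insula/operculum and dorsal anterior cingulate)
each claim their 3 nearest grid sources. The lead field is built
deterministically in code — no fixture files.

Processing per session: zero-phase 4th-order Butterworth band-pass at
8–12 Hz → 4 s pre-tap epochs (events without a full window are dropped
and logged) → ±100 µV amplitude-threshold epoch rejection → Tikhonov
minimum-norm inverse $K = G^\top (GG^\top + \lambda\mu I)^{-1}$ with
$\lambda = 0.1$ relative to the mean sensor eigenvalue
$\mu = \mathrm{tr}(GG^\top)/n_\mathrm{ch}$ → per-source mean analytic-signal
(Hilbert) envelope over the epoch, with no baseline correction (the
pre-response window *is* the baseline period) → network means by
attention condition, reported in $10^{-4}$ arbitrary cortical-source
units. The distracted-versus-attended relative response is a difference
by default; a ratio variant is a flag.

Two numerical points. First, with 24 sensors the minimum-norm point
spread is wide: the parcellation seed directions and the 3-source patch
size were chosen so that noiseless single-network input attributes at
least 70% of the summed network-mean envelope to the correct network
(measured ≈ 0.73–0.77); with a cruder geometry the attainable share is
~0.60 no matter the regularisation, which is a property of the sensor
count, not of the solver. Second, network oscillators are simulated with
independent phases and per-trial frequency jitter inside 8.5–11.5 Hz, so
cross-network leakage adds in quadrature and first-order contamination of
null networks by a changing DMN is negligible — this is what lets a
simulated DMN-only suppression leave FPN/CON statistically flat.

The synthetic session generator places condition-dependent oscillator
amplitudes on network sources during each pre-tap window, applies
session-level (lognormal, SD 0.2) and trial-level (SD 0.1) amplitude
state jitter, projects through the lead field and adds white plus 1/f
sensor noise. RT sequences are built so the median/MAD classifier
recovers the intended attended/distracted mix.

What the generator does *not* emulate: eye/muscle artifacts beyond
amplitude outliers, individual head geometry, non-alpha rhythms,
volume-conduction inhomogeneity, or electrode misplacement. Passing
recovery tests therefore demonstrates the pipeline's statistical
machinery, not robustness to real-world EEG contamination.

## Trial statistics

* **Effect sizes.** Within-group Cohen $d = (m_2 - m_1)/\sqrt{(s_1^2 +
  s_2^2)/2}$ — the pooled-SD convention used for the published tables;
  rounding to two decimals happens only at report formatting. The
  between-group effect uses change scores with Hedges-pooled SD; the
  published between-group values are not exactly recoverable from printed
  summary statistics, so this is declared as the package's convention.
* **Test selection.** The published analysis gates paired t versus
  Wilcoxon signed-rank "depending on the distribution" but names the
  Levene test, which tests variance homogeneity, not normality. The
  package defaults to Shapiro–Wilk on the difference scores (α = 0.05)
  with a Brown–Forsythe/Levene-style option, and records the test used
  next to every p value. Under null normal data the combined procedure's
  type-I error is 0.05 within Monte-Carlo error.
* **Correlations.** Spearman via ranks; the partial variant rank-transforms
  all variables, residualises on the covariates by least squares, and
  correlates residuals with $n - 2 - k$ degrees of freedom. With no
  covariates it equals plain Spearman exactly.
* **Reliability.** Cronbach's α from the classical variance decomposition.
* **Mixed ANOVA.** 2 (group) × 2 (session) split-plot via `aov()` with the
  group-by-session interaction F, partial η², and a Greenhouse–Geisser
  note: with two within-subject levels ε = 1 and the correction is a
  no-op, which the report states explicitly.
* **Scale scoring.** The 12-item self-compassion short form scores the six
  positive items (compassionate self-responding, CSR), the six negative
  items unreversed (uncompassionate self-responding, USR), and the total
  with negatives reverse-scored; burnout subscales are generic sums with
  the published interpretive midpoints (18/16/10). No item text ships
  with the package. Which items form the "state" mindfulness subset is a
  configuration choice, not hard-coded.
* **Multiplicity.** No correction by default, mirroring the published
  analysis; Benjamini–Hochberg can be applied by the user on the report.

## Synthetic cohort: coupling by construction

Latent scores are Gaussian, matched to per-group, per-timepoint means and
SDs, and anchored to baseline through a test–retest correlation
($r_{tt} = 0.7$ for behavioural scales — typical short-interval stability;
0.3 for alpha-band network activity, whose state-like variability is much
higher). Couplings are induced on the standard-normal innovations — a
Gaussian copula — so monotone clipping to scale ranges cannot destroy the
targeted rank correlations:

* sessions ↔ self-compassion change (target Spearman 0.52) and
  ↔ mindfulness change (0.38) share the adherence latent, with the mixing
  weight solved in closed form from the target and the implied change-score
  SD; infeasible targets raise an error naming the pair;
* DMN change is tied (negatively, target −0.368) to the standardised
  self-compassion innovation in both groups;
* USR falls when total self-compassion rises (coupling 0.8), and CSR is
  *derived* from the scoring identity `total = (csr + (6 - usr))/2`, so
  the three scores are always mutually consistent;
* follow-up dropout (2 trained, 1 control) is missing completely at
  random, and downstream analysis is complete-case.

The low activity $r_{tt}$ is also what makes a strong negative
baseline-to-change DMN correlation structurally possible; the EEG
sub-cohort generator additionally offers an explicit baseline-coupled
change (target Spearman −0.74, switchable) for amplitude ground truth.

Two small biases are worth knowing when interpreting recovery numbers at
n = 22: the sample Cohen d is inflated by ~3–4% (Jensen's inequality on
the inverted SD), and clipping to the 1–5 scale range adds 1–3% more for
outcomes whose T2 distribution approaches the scale ceiling. The
Monte-Carlo recovery checks use a ±0.05 absolute band that absorbs both.

## Problem sizes and determinism

Simulation sizes were chosen as the smallest that leave the Monte-Carlo
error clearly below each decision band: 200 cohort seeds for effect-size
recovery; 10,000 replicates for test calibration; 20 seeded batches of 17
subjects (12 trials/session at 200 Hz through the full sensor→source
path) for EEG parameter recovery. Every stochastic entry point takes an
explicit seed, and `run_full_pipeline()` is byte-reproducible: the same
configuration and seed yield identical JSON reports, with a provenance
block (config hash, seed, package version) embedded.

## Known limitations

* The interoceptive classifier's ~50% split is intrinsic to the MAD rule
  (see above); analyses needing a tunable distracted fraction must use a
  fixed threshold instead.
* The spherical three-network head model supports method validation, not
  anatomical inference; region labels are nominal.
* Between-group effect sizes and raw-data-dependent statistics (exact p
  values, observed correlations) depend on unpublished individual data;
  the package recovers their direction and approximate magnitude from
  configured ground truth, not their printed values.
* The adaptive engine's consistency thresholds are stand-ins for an
  unpublished app rule; both are exposed in `training_config()`.
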