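---
title: "Modeling candidate motivation from facial action-unit dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling candidate motivation from facial action-unit dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motivAU)
```

## The problem

Structured video interviews produce, through facial-analysis software such
as OpenFace, per-frame intensity traces of 17 facial action units (AUs) —
anatomically defined movements such as the lip-corner puller (AU12, the
smile), the brow lowerer (AU04), or the blink (AU45). The scientific
question motivAU addresses is whether a candidate's *motivation* — their
self-reported willingness to work for the hiring company, on a 10-point
Likert scale — can be read from these traces more reliably than human
recruiters can read it from the same soundless videos.

The package implements the complete analysis chain: trace featurization,
sparse linear modeling of motivation from the features, interrater
reliability and bias analysis of human raters, and signal-detection
evaluation of model-based candidate selection. Because behavioral interview
recordings are personal data that cannot ship with software, the package
includes a first-class synthetic cohort generator whose statistical
structure mirrors the assumptions of the analysis, so every stage is
testable end to end.

## From traces to features

Each AU trace, each EMFACS-style emotion composite (the per-frame mean of
the emotion's constituent AUs), and the derived valence trace (happiness
minus the mean of the negative emotions) is compressed into seven
statistics:

| statistic | definition | units |
|---|---|---|
| `mean_raw` | mean of the trace | intensity |
| `mean_highpass` | mean absolute residual after subtracting a centered moving average (default window 10 s) | intensity |
| `trend` | OLS slope of intensity against time | intensity/s |
| `rate` | supra-threshold episodes per minute | 1/min |
| `mean_duration` | mean episode length | s |
| `mean_area` | mean above-threshold area per episode | intensity·s |
| `mean_amplitude` | mean episode peak | intensity |

An *episode* is a maximal run of frames strictly above
`median(trace) + 1 SD(trace)`. Three conventions that the definition leaves
open are fixed as follows and exposed in the API:

* **SD convention.** The threshold uses the population SD (divide by N).
  For a constant trace the SD is zero and no frame is strictly above the
  threshold, so a flat trace has no episodes — the degenerate case falls
  out of the definition rather than needing a guard.
* **Rectified high-pass.** The signed mean of a high-pass-filtered signal
  is ~0 by construction and carries no information, so `mean_highpass`
  averages the *absolute* residual; the signed variant is available via
  `rectify = FALSE`.
* **Area above threshold.** Episode area integrates intensity above the
  threshold, not above zero, so it measures the excursion itself and is
  invariant to baseline shifts (as are episode rate and duration; the
  threshold shifts with the trace).
* **Low-pass filter.** A centered moving average whose window shrinks at
  the trace edges, chosen over IIR filters for determinism, linear phase,
  and interpretability; the window (default 10 s) only needs to separate
  "slowly drifting baseline" from "expression-scale events".

With the default emotion dictionary (happiness, sadness, surprise, fear,
anger, disgust — contempt is omitted because its unilateral AUs are not
separated by the 17-channel intensity set) the feature matrix has
7 × (17 + 6 + 1) = 168 columns. Emotion mappings are configuration, not
constants.

## The motivation model

The model chain is a dimension-reduction-then-shrinkage pipeline, identical
for the candidate-based model (CBMM, trained on self-reports) and the
recruiter-based model (RBMM, trained on mean recruiter ratings):

1. **Screening.** Features are ranked by |Spearman correlation| with the
   target and the top 30% kept. Spearman (not Pearson) matches the ordinal
   1–10 target and the evaluation metric.
2. **VIF pruning.** While any selected feature has a variance inflation
   factor above 10, an offender is removed and replaced by the
   highest-ranked unused feature, recomputing VIFs after every swap.
   *Which* offender to remove is a genuinely open design point: we remove
   the offender that ranks lowest in the screening order. The alternative
   (removing the max-VIF feature) preferentially deletes the *hub* of a
   redundant cluster — and because emotion composites are computed from
   the very AUs they summarize, the hub is typically the direct AU feature
   carrying the signal, while its derived duplicates survive. Discarding
   the weakest target-correlate instead keeps the strongest predictors and
   leaves the final set equally below the VIF ceiling; `victim = "max_vif"`
   restores the other behavior.
3. **Repeated cross-validated Lasso.** For each of 1000 iterations (fresh
   80/20 train/test split each time) the Lasso is fitted at 20 log-spaced
   penalties from 10^-1 (effectively ordinary least squares) to 10^3
   (all coefficients suppressed to zero), with predictors z-scored by
   training-split statistics — necessary for a single penalty to act
   comparably on features measured in units as different as
   episodes/minute and intensity·seconds. The chosen penalty minimizes
   mean test RMSE, ties broken toward the larger penalty; a
   one-standard-error rule is available (`rule = "1se"`).
4. **Simplification.** The Lasso support at the chosen penalty is refitted
   by OLS, and features are dropped one at a time — always the current
   largest p-value — while any coefficient's p exceeds 0.75. The Lasso
   itself yields no p-values; the OLS refit is what makes a
   "significance above 0.75" rule well defined. The ceiling 0.75 is
   deliberately permissive: the step removes only clearly uninformative
   survivors (a pure-noise coefficient exceeds it with probability ~0.25)
   rather than enforcing conventional significance.

Predictions are `intercept + Σ coefficient × z-scored feature`, clipped to
the 1–10 rating scale (unclipped available via `clip = FALSE`).

## Rater analysis

Interrater reliability is Krippendorff's alpha in the coincidence-matrix
formulation, which handles any number of raters and missing ratings;
candidates rated once contribute nothing. The default difference function
is interval, `(v - v')²`, with the ordinal metric available — on a 10-point
Likert instrument both are defensible and the package reports which was
used. Rater demographic bias uses the pooled-variance Student t
(df = n1 + n2 - 2); the pooled form is what makes df equal n - 2 for n
rated candidates. Age bias uses the same Spearman machinery as the
validity correlations.

## Selection performance

The matched-threshold ROC sweeps a percentile cut from 1 to 99: at each
cut the truly-motivated class is "true score strictly above the cut
percentile of true scores" and the selection is "predicted score strictly
above the same percentile of predictions". The confusion curve asks, for
each percentile q, how often a candidate selected into the top q% of
predictions actually lies in the bottom q% of true scores; random
selection confuses the tails with probability exactly q/100, which is the
analytic chance baseline. Percentiles interpolate linearly between order
statistics (R's type-7 quantile); both curves are invariant under strictly
monotone transforms of the predictions. A classical fixed-positive-class
ROC is available via `fixed_positive_class`.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, at the study's own scale (154 candidates; 51 men, 53 women, the
remainder unspecified; 6 recruiters each rating a random 104-candidate
subset). Design choices a user should know:

* **Latent motivation.** Drawn from a normal distribution truncated to
  [1, 10] whose *observed* mean and SD hit the configured 4.6 and 2.5 —
  the generator solves for the underlying normal parameters numerically,
  because naive truncation of N(4.6, 2.5) compresses the SD to ~2.05.
  Self-reports are the rounded latent score, mirroring the Likert
  instrument; the continuous value is logged for oracle comparisons.
* **Traces.** Each AU trace is a baseline level (per-candidate offset SD
  0.3) plus Gaussian frame noise smoothed by a 1/3-s moving average (the
  temporal coherence of real facial dynamics; it also keeps the episode
  threshold several SD above the noise floor so episode counts are not
  contaminated by single-frame crossings) plus rectangular bursts with
  jittered placement, length, and height. Every AU shows *spontaneous
  background activity* (bursts at 2–8/min, height ~2.2 ± 0.7, independent
  of motivation). Without it, episode peaks on an otherwise flat trace
  degenerate to baseline + threshold and `mean_amplitude` duplicates
  `mean_raw` exactly — a degeneracy real expressive faces do not have.
* **Planted effects.** Five linear effects of the latent score: smile
  episode rate (AU12, +0.5/min per scale unit), dimpler episode strength
  (AU14, −0.18 per unit), brow-lowerer baseline (AU04, −0.1 per unit),
  chin-raiser episode length (AU17, +0.06 s per unit), and blink rate
  (AU45, −0.8/min per unit). Each effect has a per-candidate *style*
  deviation (`noise`) so that its feature–motivation correlation lands
  around 0.6–0.7, the regime where a real behavioral marker lives;
  near-deterministic planted features would make the top predictors
  mutually collinear at VIF far above 10, which is both unrealistic and
  destroys any screening-based procedure. All burst parameters other than
  the planted one vary per candidate independently of motivation, so the
  planted statistic — not its within-trace surrogates — carries the
  signal. These spreads were calibrated by simulation against the
  pipeline's own recovery behavior, then frozen.
* **Recruiters.** A rating is
  `round(offset + w · composite + bias · male · biased_rater + noise)`
  clipped to the scale, where the composite is the standardized sum of the
  candidate's happiness episode rate and mean valence — the visible
  positivity cues raters plausibly track. The default weight w is
  *negative* (−0.7) with noise SD 1.0 and offset 6.9, producing the
  elevated (~6.8 ± 1.25), poorly agreeing (alpha ≈ 0.3), anticorrelated
  rater behavior the analysis is designed to detect; one rater adds +1
  score unit for male candidates.

**What passing tests do and do not show.** The generator plants *linear*
effects with Gaussian style noise and stationary bursts; real AU traces
have autocorrelated non-Gaussian dynamics, question-dependent structure,
posed or suppressed expressions, and effects that are at best monotone.
Recovery of planted signs on synthetic cohorts validates the pipeline's
mechanics — screening, collinearity handling, penalty selection, and
inference — not the substantive claim that these five AUs mark motivation
in any real population.

## Numerical choices and degenerate inputs

* Episode threshold on a constant trace: no episodes; episode-dependent
  features are 0 by convention.
* Z-scoring guards: a feature constant within a training split gets SD 1
  (its centered values are 0, so it cannot influence the fit).
* Lasso: glmnet with internal standardization disabled (the pipeline owns
  standardization), convergence threshold 1e-12; a single-feature fit uses
  the exact univariate soft-threshold closed form.
* Tie-breaks are deterministic everywhere (screening ties by feature name;
  penalty ties toward stronger regularization), and all randomness flows
  from one integer seed per entry point, so every result is reproducible
  bit for bit.
* Interpolation of invalid frames is linear between valid neighbors with
  nearest-value extension at the edges, and never leaves the range of the
  surrounding valid samples.

## Problem sizes used in the shipped checks

The test suite runs the full chain on cohorts of 154 candidates with
100 CV iterations over a fixed panel of 20 seeds, and the quick end-to-end
checks on 24–60 candidates with 10–50 iterations; the acceptance script
uses 200 CV iterations for the headline model and a 10-seed recovery
panel. These sizes were chosen so the whole verification cycle runs on a
laptop-class single core in minutes while keeping every statistical margin
(recovery rate, validity correlations, chance baselines) far from its
pass/fail boundary.

## Known limitations

* The EMFACS dictionary shipped as default is one common reading; the
  literature varies, which is why the mapping is a config table.
* `mean_highpass` (total burst mass) is intrinsically correlated with
  episode rate and area on any bursty trace; no decorrelation can remove
  this entirely, and the VIF step exists precisely to manage it.
* Krippendorff's alpha is computed on the realized rating matrix; it is
  not a variance-components model and says nothing about *why* raters
  disagree.
* The matched-threshold ROC is a selection-operating characteristic, not
  the classical fixed-class ROC; its AUC is descriptive and the two should
  not be numerically compared.
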