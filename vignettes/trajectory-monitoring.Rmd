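---
title: "Modelling angio-biomarker trajectories and nadir alarm rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling angio-biomarker trajectories and nadir alarm rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiotraj)
```

## The problem

VEGF-pathway inhibitors such as bevacizumab improve progression-free
survival (PFS) in ovarian cancer, but clinicians lack biomarkers that warn
when the benefit is exhausted. Circulating angiogenesis-associated proteins
— Tie2, its angiopoietin ligands Ang1/Ang2, VEGF family members and Ca125 as
the tumour-burden "gold standard" — can be measured repeatedly from plasma.
`angiotraj` implements the full analysis chain for such data: correlation
networks of the panel, a hierarchical Bayesian changepoint model of each
biomarker's trajectory, posterior-driven pseudo-trials under clinic-like
monthly monitoring, and nadir-based alarm rules scored by how many progressed
patients they catch and how early.

Because the underlying trial samples are not publicly deposited, the package
ships a first-class synthetic-cohort generator whose defaults encode the
study conditions the analyses assume; every claim the test suite makes is a
claim about data with this structure, not about any particular trial.

## The trajectory model

For one patient and biomarker, with $t$ in months from treatment start
(30-day months throughout the package), the natural-log concentration is

$$\log C(t) = \alpha + \beta\,\min(t, t_\mathrm{infl})
  + S(t)\,\gamma\,(t - t_\mathrm{infl}) + \varepsilon,
  \qquad S(t) = \mathbf 1\{t > t_\mathrm{infl}\},$$

with $\varepsilon \sim N(0, \sigma^2)$. This form is continuous in $t$ and
makes $\beta$ and $\gamma$ literally the slopes before and after the
inflection point; the clinical reading of $t_\mathrm{infl}$ is the earliest
sign of a change in tumour (or vasculature) behaviour. Pre-treatment samples
($t < 0$) are treated as replicates of the level $\alpha$ — we assume no
systematic drift between the two baseline draws.

Modelling on the log scale keeps concentrations positive, matches the
multiplicative biology of plasma proteins, and makes the descriptive
"log-ratio over baseline" plots a linear transform of the model's state.

### Hierarchy, priors and sampling

Patient-level $(\alpha_i, \beta_i, \gamma_i)$ are exchangeable normal draws
around arm-level means; arms are fitted separately so the arm contrast is
read off patient-level posterior means (Mann–Whitney), not forced through a
shared hierarchy. Priors are weakly informative and scale-free:

* group means of $\alpha, \beta, \gamma$: $N(0, 10^2)$ (log units, or log
  units per month);
* between-patient SDs: Half-Normal(5);
* residual SD $\sigma$: Half-Normal(2), truncated below at $10^{-4}$;
* $t_{\mathrm{infl},i}$: Uniform(0, last observation time of patient $i$).

All are overridable via the `priors` argument of `fit_hierarchical()`. The
$10^{-4}$ floor on $\sigma$ is numerical, not substantive: it keeps the
Gaussian likelihood evaluable on exactly noiseless data, so
parameter-recovery checks at `noise_sd = 0` are meaningful. The sampler is
JAGS (Gibbs/slice); the package's contract is seeded reproducibility plus
potential-scale-reduction screening (warn above 1.1, never abort), not a
specific kernel. Patients contribute only if they have at least three
post-treatment observations — with fewer, the three-parameter line plus
changepoint is unidentified at the patient level and the fit refuses rather
than silently leaning on the prior.

The Ang1 × Tie2 composite studied alongside Tie2 is the product of the Tie2
concentration and log2-transformed Ang1 (`composite_ang1_tie2()`,
`add_composite_ang1_tie2()`); it is fitted with the same model on the log of
the composite.

## What the synthetic cohort emulates

`cohort_config()` defaults are the study conditions, chosen once:

* **Arms**: 44 standard / 48 experimental patients.
* **Schedule**: two pre-treatment draws (days −14, −1), end of cycle-1
  infusion (day 0), pre-cycle-2 (21), pre-cycle-6 (105), end of cycle-6
  infusion (126), months 6/9/12 (183, 274, 365), plus a progression draw —
  at most 10 samples. The day values are our reconstruction of a 3-weekly
  cycle calendar from the visit labels.
* **PFS**: lognormal with median 540 days (≈ 18 months, typical of
  first-line ovarian-cancer trials), floored at 60 days; 15% of patients
  censored. Fixed-PFS and Weibull options exist for controlled experiments.
* **Trajectories**: per-patient piecewise-linear log trajectories with the
  inflection at a Normal(0.6, 0.1) fraction of that patient's PFS —
  inflection-as-%PFS keeps the changepoint clinically comparable across
  patients. Default group slopes follow the fitted per-month values of the
  markers they emulate: Tie2 experimental arm $\beta = -3.4$,
  $\gamma = 0.9$; standard arm inflection-free at $0.2$; Ca125
  $\beta = -4.4$, $\gamma \approx 1$ in both arms (tumour-burden marker,
  no bevacizumab-specific effect); Ang1 a milder bevacizumab-specific dip.
  Residual noise `noise_sd = 0.2` log units.
* **Correlation**: within a `correlation_block`, baselines share a
  patient-level latent factor and same-visit residuals a draw-level one,
  each with loading $\lambda$; two markers in a block then correlate at
  $\lambda^2$ per shared component (the closed form the generator tests
  freeze). Tie2 and Ang1 share a block with $\lambda = \sqrt{0.55}$ so their
  pooled pre-treatment correlation lands near the median correlation the
  display threshold of the networks is designed around.
* **Missingness**: each on-treatment, non-progression visit is dropped
  independently with probability 0.25, reproducing ~7 usable samples per
  patient; pre-treatment and progression draws are never dropped, because a
  blood draw is missed as a whole, the baseline is required by
  normalisation, and the progression sample anchors the post-inflection
  slope. Real missingness is plausibly informative (sicker patients miss
  visits); the independence assumption is a stand-in, and passing tests
  say nothing about informative dropout.

Other realities the generator ignores: assay batch effects, detection
limits, Ca125-specific kinetics beyond the piecewise family, and any link
between biomarker level and survival after progression.

## Networks

Correlations are computed on log concentrations, pooling all qualifying
samples (a per-patient-mean option exists for those worried about repeated
measures; with few dozen patients, pooling is what keeps the row count
workable). Partial correlations come from the standardised inverse
correlation matrix; when markers outnumber samples — the regime of a
15-marker panel against a small cohort — the correlation matrix is first
shrunk toward the identity with a data-driven Ledoit–Wolf-style intensity
(Schäfer–Strimmer estimate from the empirical variance of the pairwise
correlations). Edges below |0.3| are suppressed for display, and the edge
table reports the maximum and median displayed |correlation|. Comparison
across subsets is descriptive (edge tables side by side); no differential-
network test is attempted.

## Alarm rules and pseudo-trials

The nadir at step $k$ of a monitored series is the minimum concentration
observed up to and including $k$; the alarm fires at the first step whose
concentration reaches $\mathrm{nadir}\times(1+\theta)$. Ties trigger
(`>=`): "exceeds" is made deterministic rather than left to floating-point
luck. Rules operate on raw concentrations — percent-over-nadir is
scale-dependent, so log transforms are deliberately not applied. The
GCIG-style Ca125 rule is the special case $\theta = 1$ (doubling from
nadir) without a confirmation sample by default: under monthly imputed
monitoring a mandatory confirmation visit would systematically delay alarms
by one interval; a `require_confirmation` flag provides the stricter
variant. The package does not implement the upper-limit-of-normal branch of
the clinical Ca125 criteria for never-normalised patients.

Pseudo-trials take joint posterior draws of an existing patient's
parameters (never group-level resamples — the replicates are "the same
trial on the same patients, observed anew"), re-observe the trajectory at
$30k \pm U(-5,5)$ days up to the patient's PFS, add predictive noise with
the drawn $\sigma$, and scan the rules forward. Per patient this yields an
alarm probability across replicates; the cohort prediction rate is the mean
of those probabilities (`aggregate = "mean"`), with a majority-vote
alternative (`"majority"`) behind a flag since either aggregation is
defensible. Prediction quality is the mean %PFS time of the alarm among
alarmed replicates, averaged over patients. Censored patients are excluded
from prediction-rate denominators — counting them would conflate censoring
with rule failure.

## Numerical choices and problem sizes

* Continuity of the trajectory at the changepoint is exact by construction
  and verified to $10^{-12}$ over $10^4$ random parameter draws.
* Mann–Whitney p-values are exact (via the tie-free null distribution, or
  full enumeration under ties) whenever both groups have ≤ 8 observations,
  and tie-corrected normal beyond; the Bonferroni family for the
  trajectory comparisons is biomarkers × bins (15 × 10 by default).
* %PFS bins are $(0,10], \dots, (90,100]$ with patient values linearly
  interpolated at bin midpoints from each patient's own series, never
  extrapolated; interpolation is confined to binning and never enters the
  trajectory model.
* The test suite sizes simulations to what the properties need: slope
  recovery runs 60 seeded replicates of 48-patient arms at 2 chains × 1000
  retained draws (a 20-replicate coverage estimate has a ~7-point binomial
  SE, too coarse to resolve a 90% bound); arm-contrast calibration runs 20
  replicates of 40-patient arms at 2 × 500 draws; rule-engine
  checks enumerate all ~1.1 million series of length ≤ 6 on a 10-value
  grid; pseudo-trial determinism uses point-mass posteriors where the whole
  pipeline is analytic.
* `generate_cohort()`, `fit_hierarchical()` and the pseudo-trial engine are
  deterministic functions of their seed; child seeds for per-patient and
  per-chain streams are derived with a Lehmer step so independent stages do
  not share streams.

## Known limitations

* The changepoint model assumes exactly one inflection; biphasic rebounds
  or transient spikes are absorbed into $\sigma$.
* Arm-level inference treats patient-level posterior means as data for the
  rank test; this is a pragmatic two-stage contrast, not a joint model of
  both arms.
* Pseudo-trial prediction rates inherit the model's assumptions; on real
  data, model misfit (e.g. non-Gaussian assay noise) would propagate into
  alarm probabilities.
* With heavy missingness late in follow-up, the last observation time
  truncates the uniform prior on $t_{\mathrm{infl}}$, which mildly biases
  inflection times early for patients with short series.
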