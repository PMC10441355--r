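---
title: "Models and methods behind rejuvclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rejuvclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rejuvclock)
```

rejuvclock implements the computational side of an epigenetic-rejuvenation
study design: penalized-regression epigenetic clocks for rat tissues and a
combined human + rat panel, quantification of how much a treatment reduces
the epigenetic age of treated old animals, a per-CpG epigenome-wide
association analysis (EWAS) of age and treatment, and an IgG Fc N-glycan
aging analysis. Because studies of this kind rarely deposit their raw
methylation matrices, the package ships a synthetic-data generator with
planted ground truth; every downstream stage can therefore be scored
against known answers. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, and what passing
tests on synthetic data do and do not establish about real data.

## Epigenetic clocks

A clock is a sparse linear model of (transformed) age on CpG beta values,

$$\hat a(x) = g^{-1}\Big(\beta_0 + \sum_{j \in S} \beta_j x_j\Big),$$

fitted by elastic-net regression with the mixing parameter fixed at
$\alpha = 0.5$, midway between ridge and lasso; $\alpha$ is a design
constant, not optimized. The penalty strength $\lambda$ is chosen by
internal 10-fold cross-validation minimizing mean squared error; when
several $\lambda$ values tie, the largest (sparsest model) wins. Fitting
goes through `glmnet`; betas enter unstandardized (they already share the
[0, 1] scale), and this choice is recorded in the model metadata.

Two response transforms $g$ are supported:

* **identity** — age in years, the form used for single-species clocks;
* **relative age** — age divided by the species maximum lifespan (rat
  3.8 years, human 122.5 years). Relative age maps both species onto
  [0, 1], so one model can serve species whose lifespans differ by a
  factor of 30 without the short-lived species' ages being crushed into a
  corner of the response range. Predictions are mapped back to years by
  multiplying with the lifespan of each sample's species. Ages beyond the
  nominal maximum give relative ages above 1 and a warning, not an error.

The log-linear juvenile transform used by some human clocks is
deliberately absent: nothing in the target design calls for it, and the
menu is kept to the two transforms that are actually exercised.

Small-sample behaviour: the internal cross-validation reduces its fold
count to the training-set size when fewer samples than folds are
available (leave-one-out internally), erroring only below three samples.
This keeps fully nested leave-one-out cross-validation well-defined on
small panels, where each outer fold must still select its own $\lambda$.
A constant training response yields a degenerate clock — zero weights and
an intercept equal to the common transformed age — rather than an error
deep inside the penalized fit.

Cross-validation (`cross_validate_clock()`) re-runs the *entire* fitting
procedure, including $\lambda$ selection, inside every fold, so the
held-out sample never influences any tuning decision. The report pools
held-out predictions and gives their Pearson correlation with
chronological age and the median absolute error in years. Negative
predicted ages are reported as-is; clipping them would bias the error
metrics.

## Quantifying rejuvenation

For a three-arm design (young control, old control, old treated), the
rejuvenation percentage of a tissue under a clock is

$$100 \cdot \frac{\bar a_{\text{old}} - \bar a_{\text{treated}}}{\bar a_{\text{old}}},$$

the fraction of the old-control mean epigenetic age removed by the
treatment: values above 50 mean the treatment more than halved the
epigenetic age. Group means are arithmetic means of per-sample DNAm ages.
The statistic is scale-invariant, so it does not depend on the units the
clock predicts in. A secondary, clearly labelled variant divides by the
old-minus-young gap instead (the fraction of the age *gap* closed); it is
reported alongside, never in place of, the primary definition. Per-tissue
summaries average the per-clock percentages (the alternative order —
ratio of clock-averaged means — is also reported), and the grand average
across tissues is unweighted.

Group comparisons (`group_stats()`) provide one-way ANOVA across all
arms, the classical equal-variance Student t-test restricted to old
control vs old treated (Welch's form behind a flag), and the two-sided
Kruskal-Wallis rank test, all through the base R implementations.

## EWAS with unwanted-variation correction

Each probe's response (beta values by default; logit-2 M-values behind a
flag for variance stabilization) is modelled by ordinary least squares on
a shared design: condition indicators without a global intercept
(`~ 0 + group + plate + column`), plus $k$ factors of unwanted variation.
The factors are the top right-singular vectors of the row-centred
submatrix of negative-control probes (default $k = 2$). Because the
panel has no designated control probes, empirical negatives are selected:
probes are ranked by absolute marginal correlation with age and by their
between-group variance fraction, and the `n_controls` (default 500)
probes with the smallest rank-sum are taken, with lexicographic probe-id
tie-breaking so the selection is deterministic. The control list is a
logged output of the stage, since the result depends on it. The
log-count transform used by count-based factor-analysis tools is
inapplicable to bounded beta fractions, so the factors are computed
directly on centred betas.

Residual variances are moderated by empirical Bayes: prior degrees of
freedom $d_0$ and prior variance $s_0^2$ are obtained by matching the
moments of $\log s^2$ to a scaled F distribution, with the trigamma
inversion solved by Newton iteration, and

$$\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d}.$$

When the observed variances show no excess dispersion beyond chi-square
sampling noise, $d_0 = \infty$ and every probe uses the common
(log-bias-corrected) prior. Probes with $s^2 = 0$ are offset by the
smallest positive $s^2 \times 10^{-8}$ before logs. The implementation is
cross-checked in the test suite against an independent moderated-t
implementation to $10^{-8}$ on both hyperparameters and statistics.

Two contrasts are built in: **Age** (old control − young control) and
**Elixir** (old treated − old control, the treatment effect in age-matched
animals). Moderated t-statistics on $d_0 + d$ degrees of freedom give
two-sided p-values, Benjamini-Hochberg adjusted within each contrast;
significance means $q < 0.05$. The reversal summary then asks, among
probes significant for Age, what fraction has a treatment estimate of
opposite sign, split by age-gain vs age-loss probes — a defined,
reproducible statistic for the "treatment reverses age-related methylation
change" claim. The null design without condition columns is available for
diagnostics only; inference follows the contrast path.

## IgG glycan analysis

Raw integrated areas are normalized to the total within each sample ×
IgG subclass (IgG2a/IgG2b/IgG2c), so glycoform abundances are relative
and sum to one per subclass. Before association analysis every
glycopeptide trait is transformed by the rank-based inverse-normal map
$x_i \mapsto \Phi^{-1}\!\big((r_i - 0.5)/n\big)$ with average ranks for
ties, which gives every trait unit variance and makes effects comparable
across glycoforms.

Cross-sectional age association is a linear model of the transformed
trait on chronological age in raw years (the coefficient unit is standard
deviations of the trait per year) with sex as a covariate, BH-corrected
across the panel. The longitudinal treatment analysis is a linear
mixed-effects model per glycoform — fixed time (baseline vs follow-up),
fixed time × treatment interaction, random per-subject intercept — fitted
by REML through `lme4`. Fixed-effect p-values use the normal
approximation to the Wald statistic; small-sample degrees-of-freedom
corrections are out of scope and the approximation is documented
precisely so its anticonservatism at very small n is not mistaken for a
stronger guarantee. Non-convergence is reported per glycoform without
failing the remaining panel. Per-subject follow-up-minus-baseline changes
are exported as a plotting convenience, not used for inference.

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the rest of the package is evaluated under.

For age-informative probe $i$ and sample $j$,

$$\beta_{ij} = \mathrm{clip}_{[0,1]}\Big(\mathrm{logit}^{-1}\big(b_{0i} + s_i\, \tfrac{\mathrm{age}_j}{L} + u_{i,t(j)} + v_{i,b(j)}\big) + \varepsilon_{ij}\Big),$$

with $L$ the species lifespan, $u$ per-probe-per-tissue offsets, $v$
per-probe-per-plate offsets and $\varepsilon \sim N(0, \sigma)$ on the
beta scale. Linearity in logit space keeps betas bounded and makes both
the elastic-net recovery and a shared cross-species relative-age signal
well-posed. Defaults: 2,000 probes, 200 age probes with slope magnitudes
$|N(4, 1)|$ (half gaining, half losing methylation, so reversal
statistics are exercised in both directions), four tissues × 60 rat
samples with ages uniform on 0.04–2.3 years, noise sd 0.03, baseline
logits $N(0, 0.8)$, tissue offsets sd 0.3 and plate effects sd 0.1 in
logit units. The batch and tissue offset scales are acknowledged
guesses — no inter-cohort effect-size information exists to calibrate
them. Age-probe baselines are centred at $-s_i$ times the mid relative
age, so each planted trajectory traverses the detectable mid-beta range
instead of saturating near 0 or 1: an array probe whose trait is pinned
at the rail cannot register age drift, and the centring is what makes the
generator's own recovery contract (per-probe least squares on logit-beta
recovers planted slopes) attainable; a flag disables it for closed-form
test constructions. All randomness flows from a single integer seed
through a local RNG that never touches global state; probe-level
parameters depend only on the config seed, so independent cohorts can be
drawn from the same simulated "epigenome" — exactly what evaluating a
clock on an independently generated treatment study requires.

The treatment generator plants rejuvenation as a *reduced effective age*:
the treated arm's methylomes are generated at
$\text{old age} \times (1 - \rho/100)$ but annotated with the
chronological old age, so the planted percentage $\rho$ is exactly the
quantity the rejuvenation statistic estimates. Arm defaults follow the
emulated design: three arms of six animals, young at 0.58 years
(30 weeks), old at 2.1 years (109 weeks).

The glycan generator produces a two-arm, two-timepoint panel on the
per-subclass simplex with a per-subject random intercept, a
cross-sectional aging gradient (G0 rising, G2 falling with age), a
longitudinal drift in the control arm, and a planted treatment effect
reversing the drift in the treated arm. All shift vectors sum to zero
within a subclass, so simplex renormalization is the identity in
expectation and planted effects remain exactly interpretable; configured
shifts that would push expected proportions outside (0, 1) are rejected
up front.

What the generator does *not* emulate: probe-level chemistry artifacts
(dye bias, detection failures), cell-composition heterogeneity,
nonlinear or life-stage-specific aging trajectories, and realistic
inter-lab batch structure. Passing tests on this synthetic data
demonstrate that the pipeline's estimators recover the quantities they
claim to estimate under the stated generative model — they do not certify
accuracy on real arrays, where normalization quality and unmodelled
heterogeneity dominate.

## Quality control

Outlier screening ranks samples by mean pairwise Pearson correlation to
the rest of the cohort and flags those below a threshold (default 0.80).
This is a deterministic, testable proxy for dendrogram-based exclusion;
the corresponding average-linkage tree on distance $1 - r$ is available
via `outlier_dendrogram()` for visual inspection. The threshold is a
stated default, not an empirically derived value — no exclusion criterion
was available to calibrate against. A constant-valued sample has
undefined correlation; it is reported as degenerate rather than silently
dropped or spuriously flagged. Missing beta values are imputed by the
per-probe mean — simple, deterministic and idempotent; probes with no
observed values at all are an error.

## Numerical and interface choices

* Ages are always stored in years; sheet parsing performs no unit
  conversion.
* Beta matrices live in TSV with probes in rows (an orientation flag
  reads the transpose); sample sheets in CSV; clock coefficients in a
  `term,weight` CSV whose weights are written with 17 significant digits
  so a save/load round-trip is bit-exact, with a JSON sidecar carrying
  the transform, lifespans, $\alpha$, $\lambda$, seed and training
  metadata.
* Probe intersection returns the shared set in sorted order, making the
  operation symmetric in content.
* Pipeline stages (`run_simulate()`, `run_train()`, `run_cv()`,
  `run_predict()`, `run_rejuvenate()`, `run_ewas_stage()`,
  `run_glycan()`) are driven by a YAML-or-list config that must name an
  explicit seed; each stage writes a run-manifest JSON sufficient to
  re-execute it.

## Problem sizes used in the shipped checks

The packaged test-and-acceptance workload uses the default 240 × 2,000
panel for the nested leave-one-out evaluation of the pan-tissue clock, a
150 + 150 two-species panel for the relative-age clock, four 40-sample
single-tissue training panels with 18-sample three-arm studies (five
seeds) for rejuvenation recovery, 10,000 simulated probes for
empirical-Bayes hyperparameter recovery, and 100–300 Monte-Carlo
replicates for the null-calibration checks. These sizes were chosen as
the smallest at which the estimators' behaviour is stable enough to
assert tight bounds; all of them run comfortably on a single CPU.

## Known limitations

* The empirical negative-control selection is a substitute for a curated
  control set, not a reconstruction of one; with signal on a large
  fraction of probes it can admit weakly age-associated controls.
* The mixed-model Wald p-values are anticonservative for very few
  subjects; with the default arm sizes the type-I error is close to
  nominal (checked by simulation), but users with n < 6 per arm should
  prefer a likelihood-ratio or parametric-bootstrap test.
* The rejuvenation statistic presumes a positive old-control mean
  epigenetic age; clocks that predict near-zero or negative mean ages
  for old controls (badly mis-calibrated transfers) make the percentage
  meaningless, and the function refuses them.
* Elastic-net prediction shrinks toward the training mean, so estimated
  rejuvenation carries a small attenuation bias (assessed at well under
  two percentage points at the default signal-to-noise).
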