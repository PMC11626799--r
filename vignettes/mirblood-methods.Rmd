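---
title: "Models and methods in mirblood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mirblood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirblood)
```

`mirblood` couples two statistical workflows around one biological
question: how much of a transition-period dairy cow's blood metabolic
state is visible without drawing blood? This vignette documents the
models, the tunable parameters, the numerical choices, and — because the
package ships its own data generator — exactly what the passing test suite
does and does not demonstrate about real herds.

## The phenotypic-variance model

Each plasma trait is analysed with a linear mixed model

$$y = \mu + P_i + D_l + (P \times D)_{il} + M_k + H_m + e,$$

where $P_i$ is parity class ($1, 2, \ge 3$), $D_l$ the days-in-milk class
(3–8, 9–14, 15–20, 21–38 d), $M_k$ the sampling season (May–Jun, Jul–Aug,
Sep–Oct), $H_m \sim N(0, \sigma^2_H)$ a random herd intercept and
$e \sim N(0, \sigma^2_e)$ the residual. The model assumes Gaussian
residuals, which is why the six right-skewed traits (blood BHB, NEFA, AST,
GGT, CK, cortisol) are log₁₀-transformed first, and why values more than
3 SD from a trait's mean are set missing beforehand. Editing is a single
pass — mean and SD are computed once on the raw vector — and is applied
*before* the log transform; this ordering matters for heavy-tailed traits
(a CK value of 6,500 U/L inflates the raw SD enough to shield smaller
extremes) and follows the order in which field protocols state the two
steps.

### REML by variance-ratio profiling

With one random effect the covariance is
$V = \sigma^2_e (I + \lambda Z Z^\top)$, $\lambda = \sigma^2_H /
\sigma^2_e$. For fixed $\lambda$ the GLS fixed effects and the REML
residual variance are closed-form, so the restricted likelihood is
maximised by a one-dimensional search over $\log \lambda$ on $[-15, 8]$
(`optimize()`, unimodal in practice), with $V^{-1}$ applied through the
Woodbury identity — $Z^\top Z$ is diagonal for a grouping factor, so each
evaluation is $O(n)$. The boundary $\sigma^2_H = 0$ is evaluated
explicitly and reported with a flag rather than as a tiny positive ratio.
The test suite checks this engine against `lme4::lmer` on 20 random small
datasets (agreement to 1e-4 in the variance components) and verifies
recovery of $(\sigma^2_H, \sigma^2_e) = (4, 1)$ from 200 simulated
14-herd × 25-cow designs to within 10% on the mean.

### Inference conventions

Factors enter with sum-to-zero contrasts, so the Wald F on a term's
coefficients is the type-III test. Denominator degrees of freedom are
$n - \mathrm{rank}(X)$: the source analyses do not state a
Kenward–Roger/Satterthwaite choice, and the residual-df convention is the
reproducible default. Least-squares means average the model prediction
over the full factor grid; all pairwise contrasts within a factor are
Bonferroni-adjusted, $p_{adj} = \min(1, m\,p)$ with $m$ the number of
pairs, and summarised as compact letters (maximal cliques of the
not-significantly-different graph, letters ordered from the highest LSM).
For log traits the LSM are back-transformed as $10^{\mathrm{LSM}}$, which
in the balanced case is the geometric mean — a property the suite asserts.

Total bilirubin is often censored at the assay's detection limit, so it is
modelled as a binary trait (> 4 µmol/L) by logistic regression via
`glm` — iteratively reweighted least squares — with herd as a *fixed*
effect: a true random-intercept logistic model requires numerical
quadrature the original analysis does not describe, and with 14 herds the
fixed-effect version is estimable and transparent. Odds ratios per factor
level carry Wald 95% CIs (exponentiated log-odds scale); a level is
significant when its CI excludes 1, and complete separation (diverging
coefficient) is flagged with an unbounded CI rather than a spurious one.
The interaction term is omitted from the logistic mean structure: odds
ratios are reported per main-effect level, and with ~350 binary outcomes
the 12-cell interaction routinely separates.

## The spectral pipeline

Transmittance is converted to absorbance, $A = \log_{10}(1/T)$. The
wavenumber grid is linear and descending with both endpoints included —
the instrument's true grid is not published, and a linear grid is the only
reproducible convention. Water-region masking keeps the closed intervals
945.5–1,585.6, 1,716.8–1,929.0 and 2,507.7–2,970.7 cm⁻¹; on the
1,060-point grid this retains **340** points. Published analyses of the
same windows report 338 retained wavelengths; the two-point discrepancy is
a property of the unpublished instrument grid, so the package reports the
computed count rather than forcing 338.

Anomalous spectra are flagged by a PCA score rule: first 5 components of
the centered retained-absorbance matrix, flag if any score is more than
3 SD from that score's mean, one pass with no refitting. Published
workflows state only the outcome of this screen, not the rule; 5 PCs/3 SD
is the common chemometric default and the parameters are exposed.

SNV standardises each spectrum to mean 0, SD 1 (sample SD, $n-1$
denominator, stated so tests are bit-reproducible) over the retained
points. Two properties found during development are worth knowing:

* **Closure**: for a *single*-analyte spectrum over a flat baseline, SNV
  divides out the concentration magnitude itself — the spectrum's SD *is*
  the signal. The noiseless construction tests therefore run without SNV.
* **When SNV pays off**: with only additive tilt and offset scatter, a
  linear PLS can exploit the flat baseline as an internal reference and
  SNV's composition-dependent normalisation can even cost accuracy. SNV
  wins consistently once per-sample *multiplicative* scatter dominates,
  which is the regime the paired SNV-on/off test simulates
  (gain SD 0.5).

## PLS, cross-validation and external validation

The regression engine is NIPALS PLS1 with component-wise deflation —
numerically transparent, and its per-component structure matches the
"components capped at 20" semantics. For a univariate response each
component is a single pass (no inner iteration); extraction stops early if
the residual covariance vanishes. Coefficients for any $a$ components are
$B = W (P^\top W)^{-1} q$, returned on the original predictor scale.
Correctness is anchored to two independent oracles: at full rank PLS
equals ordinary least squares (1e-8), and at $a < \mathrm{rank}$ it equals
a Krylov-subspace construction coded separately in the test helpers.

Leave-one-out cross-validation refits everything inside each fold —
centering, scaling, and component extraction never see the held-out sample
— and the suite verifies each fold against the oracle. The component count
is $\arg\min$ cross-validated RMSE with ties to fewer components
(parsimony). R² is the squared Pearson correlation of observed and
predicted — the convention of the standard chemometrics training workflow
— rather than $1 - SSE/SST$; the residuals are returned so users can
compute the other variant. RMSE uses the $n$ denominator.

Samples whose standardised leave-one-out residual exceeds 3 are dropped
once (no iterate-and-refit): published removal rates of 0.6–4.6% are
consistent with a ~3-SD rule, and a single pass keeps the estimator
well-defined.

External validation draws a stratified 70/30 split within
herd × parity × DIM-class strata. Allocation uses largest-remainder
rounding (calibration size exact to ±1 sample), every stratum with ≥2
members feeds both sets, and single-member strata go wholly to calibration
with a warning. Candidate splits are redrawn (up to 200 tries) until
calibration and validation match in mean and SD of the target trait to
within 0.1 overall SD each — the published goal is "similar mean and SD"
with no numeric rule, so the 0.1·SD/200-tries pair is the package's
choice, and the best candidate is returned with a warning when the
constraint is unattainable. "Iterated over different portions of cows" is
implemented as different seeds per iteration: disjoint validation thirds
are possible but unstated, and seeded resampling is the reproducible
reading. Reported statistics are the arithmetic means over iterations,
with per-iteration values kept for audit.

PLS-DA is PLS1 on the 0/1 risk indicator with a 0.5 score cutoff — the
standard two-class construction — and its component count is chosen by
leave-one-out *balanced accuracy*, not RMSE, because the objective is
classification. No class re-balancing is applied: published performance is
reported at natural prevalence, so the generator supports imbalance
instead. Confusion-matrix ratios with zero denominators are reported as
missing, never as 0. Rounding happens only at report time, half away from
zero at 2 decimals; note that published balanced accuracies can disagree
with the mean of the *printed* sensitivity/specificity by up to one print
unit, because those inputs are themselves rounded.

The R² interpretation bands — ≥0.91 punctual prediction, 0.82–0.90
quantitative screening, 0.66–0.81 approximate screening, 0.50–0.65 extreme
detection, otherwise insufficient — are closed at their printed
boundaries; values in the unprinted gaps (e.g. 0.905) fall to the band
below the next closed edge.

## The synthetic generator

`synth_config()` defaults *are* the study conditions: 14 herds, 349 cows
sampled once at 3–38 DIM (exponentially decaying DIM distribution, mean
≈ 15 d), three two-month seasons, parity classes ≈ 35/30/35%. Marginal
means and SDs are the published pre-editing descriptive statistics
(e.g. blood BHB 0.71 ± 0.54 mmol/L, NEFA 0.52 ± 0.34, urea 4.19 ± 1.31);
the six skewed traits get log-normal marginals matched to those moments,
milk BHB is specified directly on the log₁₀ scale (−0.99 ± 0.24), and
total bilirubin's log-normal is parameterised so ~28% of cows exceed the
4 µmol/L cutoff. Under these marginals the BHB > 1.2 mmol/L share comes
out near 13% — the generator reproduces the published 22.3% only
qualitatively, as the published marginal moments and the published
prevalence are not jointly consistent with any two-parameter log-normal.

Correlations come from a Gaussian copula: target Spearman values (milk–
blood urea 0.89, milk–blood BHB 0.53, NEFA–urea 0.40, BHB–glucose −0.39,
Na–Cl 0.76, CK–AST 0.49, and the other published pairs) are converted to
latent Pearson correlations by $r = 2\sin(\pi\rho/6)$, exact for the
bivariate normal and invariant under the monotone marginal transforms.
Unspecified pairs are completed by transitive path products before the PSD
check — zero-filling makes the stated targets mutually inconsistent
(minimum eigenvalue −0.16) — and `Matrix::nearPD` remains as a logged
fallback for user-supplied targets. A fraction `herd_var_frac` (default
0.10) of latent variance is shared within herd; note this leaves only 14
effective draws behind that fraction, so empirical correlations at very
large *n* are measured with the herd share off.

Spectra are Beer–Lambert-style: absorbance = baseline + Σ (standardised
concentration × fixed Gaussian-bump signature, centers inside the retained
windows) for eight spectrally visible analytes, times a per-sample
multiplicative gain (log-SD `scatter_gain_sd`, default 0.1), plus tilt and
offset, plus i.i.d. noise inflated 50× inside the discarded water
intervals — so masking demonstrably matters. Transmittance is
$10^{-A}$ clipped into $(0, 1]$.

**What passing tests show — and do not.** The generator encodes analytes
*linearly* with smooth synthetic signatures; real milk spectra carry
collinear, overlapping bands, fat-globule scattering that is not affine,
instrument drift between farms, and blood–milk time lags. Green tests
demonstrate that the pipeline's statistics are implemented correctly and
that it recovers structure it is designed to see; they do not certify the
published accuracy figures, which depend on a private 349-cow dataset.
Accordingly the synthetic urea R² (~0.91) is *better* than the published
0.86, and no test asserts equality with published Table-level values.

## Problem sizes and runtime choices

The unit suite runs small designs (n = 12–150) chosen so each oracle
comparison is exhaustive; the end-to-end checks use the full study design
(349 cows, LV cap 20, 3 iterations), 200 REML replicates, and a 100,000-row
copula draw — the scales at which the recovery criteria are meaningful.
The whole suite completes in under a minute on one CPU; `scripts/acceptance.R`
in about a minute.

## Known limitations

* The logistic model treats herd as fixed; with rare outcomes and small
  herds its odds ratios are conditional on herd in a way a random-effects
  fit would shrink.
* Type-III F tests use residual df; with 14 herds the herd-level df are
  few enough that Satterthwaite-style corrections would be somewhat more
  conservative for season-like contrasts.
* `stratified_split()` warns rather than fails when the moment constraint
  is unattainable (common below ~100 cows, where herd × parity × DIM
  strata are mostly singletons).
* The spectral outlier rule flags by leading-score distance only; a
  residual-distance (Q-statistic) complement is out of scope.
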