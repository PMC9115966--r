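---
title: "Kinetic modelling of dynamic FDG-PET and gene-set association analysis with fluxgsea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of dynamic FDG-PET and gene-set association analysis with fluxgsea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxgsea)
```

# The analysis

`fluxgsea` implements a radiogenomic pipeline for dynamic
[18F]-fluorodeoxyglucose (FDG) PET of solid tumours. The pipeline has two
halves. The kinetic half turns a patient's arterial input function (AIF)
and tumour time-activity curve (TAC) into flux-constants — rates of
irreversible FDG trapping per unit steady blood concentration — and
static uptake measures (SUV, TBR). The genomic half ranks genes by the
correlation of their log2 expression with each imaging measure and asks,
via gene-set enrichment analysis (GSEA) with gene-wise permutation
nulls, which pathways track each measure, together with the
false-positive and bootstrap machinery needed to interpret the counts of
associated pathways.

Because no patient data ship with the package, a synthetic-cohort
generator is a first-class, tested module: it produces AIFs, TACs,
static-uptake inputs and expression matrices with known ground truth, so
every downstream stage can be exercised and calibrated end to end.

# Kinetic models

## Input function

The AIF is modelled with the standard three-exponential (Feng-type)
bolus form with an appearance delay $\tau$:

$$\mathrm{AIF}(t) = \bigl(A_1 u - A_2 - A_3\bigr) e^{-\mu_1 u}
  + A_2 e^{-\mu_2 u} + A_3 e^{-\mu_3 u}, \qquad u = t - \tau,$$

zero for $t \le \tau$, with $\mu_1 > \mu_2 > \mu_3 > 0$. The ordering is
enforced structurally during fitting (positive rate gaps), and a
3×3×3 multi-start grid over rate decades guards against local minima.
The cited literature does not pin down the exact parameterisation; the
Feng form is the field's standard choice and is a design decision here.

## Frame weights

All curve fits are weighted by

$$w_i = \frac{\Delta T_i}{A_i}\, e^{-\lambda t_i},$$

where $\Delta T_i$ is the duration of frame $i$, $A_i$ its measured
activity concentration, $t_i$ its mid-time post-injection and $\lambda =
\ln 2 / 109.77\ \mathrm{min}^{-1}$ the 18F decay constant. Frames with
non-positive activity (including the pre-injection frame) are excluded
and flagged. The supplied decay-corrected concentrations are used for
$A_i$ as written; weights are relative, so their absolute scale is
inert.

## Compartment models and residue functions

Tumour TACs follow the convolution model

$$\mathrm{TAC}(t) = K_1 \int_0^t \mathrm{AIF}(s)\, R(t-s)\, ds
  + V_b\, \mathrm{AIF}(t),$$

where $R(t)$ is the residue function (fraction of tracer delivered at
time 0 still in tissue at $t$; $R(0) = 1$) and $V_b$ the fractional
blood volume; the blood term is added to the tissue term exactly as
written (no $1 - V_b$ factor). Supported models:

* **2C3K** — irreversible two-tissue, parameters $K_1, k_2, k_3, V_b$,
  residue $R(t) = \frac{k_3}{k_2+k_3} + \frac{k_2}{k_2+k_3}
  e^{-(k_2+k_3)t}$ and flux $k_\mathrm{flux} = K_1 k_3/(k_2+k_3)$.
* **2C4K** — reversible two-tissue ($+k_4$). Its asymptotic flux is
  zero, so the operational value $K_1 R(T_\mathrm{scan})$ is reported.
* **3C5K** — irreversible three-tissue. The wiring used here is
  plasma $\to$ free (efflux $k_2$), free $\leftrightarrow$ bound
  ($k_3$, $k_4$) and bound $\to$ trapped ($k_5$), giving
  $k_\mathrm{flux} = K_1 k_3 k_5 / \bigl(k_2 (k_4+k_5) + k_3
  k_5\bigr)$. Several three-tissue wirings appear in the literature;
  this one is the package's documented choice, and the identity
  $k_\mathrm{flux} = K_1 R(\infty)$ — which holds for any irreversible
  wiring — is what the tests assert.
* **Patlak** — ordinary least squares of $\mathrm{TAC}/\mathrm{AIF}$
  against $\int_0^t \mathrm{AIF}/\mathrm{AIF}$ over frames with mid-time
  $\ge t^*$; the slope is the flux estimate. $t^* = 10$ min by default and
  configurable; only late time-points belong in the linear regime, and
  the cut-point is a free analysis choice.
* **Spline residue** — nonparametric $R(t)$, below.

Residue functions of compartment models are evaluated by
eigen-decomposition of the tissue rate matrix, giving
$R(t) = \sum_j c_j e^{-\beta_j t}$; convolution with the Feng AIF is
then fully analytic. Each exponential convolution is factored so that
every exponential argument is non-positive, which keeps the closed forms
finite at arbitrarily late times and stable when two rates nearly
coincide (series expansions take over below $|\delta u| \approx
10^{-4}$). Model curves are averaged over each acquisition frame
(composite Simpson rule on an 11-point subgrid) rather than evaluated at
mid-times, mimicking how scanner frames integrate activity. A
quadrature-based convolution path agrees with the analytic one to
$10^{-6}$ relative and serves as the oracle in tests.

Compartment fits are box-bounded weighted least squares
(Levenberg–Marquardt) with rates in $[0, 5]$ min$^{-1}$ and $V_b \in
[0, 0.5]$, multi-started from 8 seeded log-uniform draws; the lowest
weighted RSS wins, ties to the earliest start.

## The spline-residue model

$R(t)$ is a clamped cubic B-spline expansion on $[0, T_\mathrm{scan}]$
with (by default) 6 interior knots geometrically spaced on the scan
span, constrained to $R(0)=1$, $R' \le 0$, $R \ge 0$. Rather than
imposing the shape constraints at a collocation grid, the package uses
the sufficient coefficient condition: non-increasing, non-negative
B-spline coefficients yield a non-increasing, non-negative spline
everywhere. Writing the coefficient decrements as new parameters turns
the whole fit — including $K_1$ (the leading coefficient) and $V_b$ —
into one exact non-negative least-squares problem, solved by the
Lawson–Hanson algorithm. Two consequences are worth noting: the
constraints hold on the whole interval, not just at grid points, and
knot-insertion preserves feasibility, so refining the knot grid can
never increase the weighted RSS (a property the tests exercise). The
condition is slightly conservative — there exist monotone splines with
non-monotone coefficients — but at six interior knots the flexibility
loss is negligible against frame noise. $V_b$ is capped at 0.5; if the
unconstrained solution exceeds the cap, the fit is re-solved with $V_b$
fixed there.

The spline basis convolutions with the AIF are computed once per fit by
FFT convolution on a half-second grid with a trapezoid end correction,
then frame-averaged; the approximation error is far below the fit's
statistical uncertainty.

## Simulated noise

Synthetic TACs receive zero-mean Gaussian frame noise with variance
$\sigma_i^2 = s^2 / w_i$ — exactly the inverse of the fitting weights —
so that weighted least squares is the matched inverse-variance
estimator. The default scale $s = 1.5$ (concentrations in kBq/mL) gives
roughly 3–5% noise on late 300-s frames and ~10% at the early 5-s
frames around the bolus peak, a realistic regime for tumour-ROI dynamic
PET. AIF samples receive flat Gaussian noise (default 0.5 kBq/mL,
about 1% of the bolus peak).

# Model assessment

**Leave-one-frame-out cross-validation.** For each post-injection frame
the model is refitted without it (warm-started from the full-data
optimum) and the held-out frame predicted; the score is $\sum_i w_i
(\hat y_{-i} - y_i)^2$. Frames, not patients, are left out — the fits
are per-patient curve fits, so patient-level deletion would be
meaningless. One caveat the synthetic studies expose: when the data are
generated by the simpler model, the box-bounded over-parameterised fit
(3C5K on 2C3K truth) collapses onto the simpler solution, so its LOOCV
penalty is second-order and the two models' scores are statistically
indistinguishable. A clear LOOCV separation between them should
therefore be read as evidence of model mismatch in real data rather
than as something synthetic nested-truth data will reproduce.

**Runs test.** Serial structure in residuals is tested with the
Wald–Wolfowitz runs test on residual signs (zeros dropped). For small
samples ($n \le 50$ — every dynamic fit here) the two-sided p-value
comes from the exact conditional runs distribution (doubled smaller
tail, capped at 1); the continuity-corrected normal z-score is always
reported alongside. The normal approximation alone is badly calibrated
at these sizes — for unbalanced sign counts it can be off by more than
0.2 — which is why the exact distribution is the default.

**Profile likelihood.** Parameter uncertainties scale the weighted RSS
by $s = \mathrm{dof}/\mathrm{WSS}$ of the best model's fit (degrees of
freedom = usable frames minus parameters), then profile $s \cdot
\mathrm{WSS}(\theta)$, re-optimising all other parameters at each step;
1-SD bounds sit where the profile rises 1.0 above its minimum (the
chi-square 1-dof convention — the scaling makes the objective an
approximate chi-square, and the threshold is our documented choice).
Crossings are refined by monotone interpolation on the square-root
scale, exact for locally quadratic profiles; profiles that hit a box
bound are censored there and flagged. For the 2C3K model the derived
flux-constant is profiled directly through the reparameterisation
$(k_\mathrm{flux}, k_2, k_3, V_b)$ with $K_1 =
k_\mathrm{flux}(k_2+k_3)/k_3$. On weighted linear regression recast in
this machinery the bounds reproduce the closed-form standard errors to
1%, and on synthetic cohorts the 1-SD intervals cover the true flux in
about two-thirds of replicates.

# Gene-set enrichment

Genes are ranked by Pearson or Spearman correlation with an imaging
measure; exact ties are permuted uniformly at random under a dedicated
tie-break seed (independent of the permutation stream). Zero-variance
genes are dropped with a warning. The enrichment score is the classic
weighted Kolmogorov–Smirnov running sum with weight exponent $p = 1$
(the named algorithm's default; configurable): set members increment
the walk by $|r|^p / \sum_\mathrm{set} |r|^p$, non-members decrement it
by $1/(N - N_H)$, and the ES is the walk's extremum, ties resolved to
the earlier list position. Leading-edge genes are the members at or
before a positive extremum (at or after a negative one).

Nulls are gene-wise permutations — uniformly drawn same-size gene sets
scored against the fixed ranking, shared across sets of equal size and
computed by a vectorised walk evaluated only at hit positions, which is
what makes 10,000-permutation studies desk-scale. A known caveat of
gene-wise permutation is that it can overstate significance relative
to phenotype permutation; users should read the flags accordingly. p-values and the normalised enrichment score are
sign-stratified: positive scores are compared with positive nulls
(NES = ES / mean |same-sign null ES|), with the add-one convention, so
$p \ge 1/(\#\mathrm{same\text{-}sign\ nulls} + 1)$ and p is never zero.

Significance uses the nominal Bonferroni-style cut-off $0.035/N$, $N$
being the post-filter collection size (size filter 15–500 by default).
One arithmetic consequence deserves emphasis: with $N = 100$ sets the
threshold is $3.5 \times 10^{-4}$, below the p-value floor of any run
with fewer than roughly 5,700 permutations (sign-stratified). Runs at
1,000 or 2,000 permutations therefore cannot flag anything at this
threshold, whatever the data. The package default is accordingly
10,000 permutations, the smallest round count that makes the
threshold attainable at KEGG-scale collections; analyses wanting fewer
permutations should shrink the collection (raising $0.035/N$) rather
than lower the permutation count.

Cohort-level machinery: `permutedPhenotypeStudy()` permutes the measure
across patients and counts significant sets per permuted dataset
(median, range and 95th percentile summarise the false-positive
behaviour); `bootstrapCountDifference()` draws patients with
replacement (expression columns and measure values jointly, duplicates
kept — the standard nonparametric bootstrap), reruns the GSEA for two
measures per resample and applies the paired t-test to the
per-resample significant-set counts, pairing by resample index;
`correlationHeatmapTable()` and `wilcoxonCompare()` provide the
gene-by-measure correlation matrices and their paired signed-rank
comparisons, with a configurable mean-log2 floor (default 1.0) standing
in for the low-count exclusion. Tie-break randomisation is re-derived
per resample from the stage seed.

# The synthetic cohort

`simulateCohort()` emulates a window-of-opportunity dynamic-imaging
cohort: 30 patients by default, per-patient Feng AIFs (log-normal scatter around a bolus
peaking near 40 kBq/mL), 2C3K kinetic truth with $K_1$ around 0.1
min$^{-1}$, $k_2$ 0.35, $k_3$ 0.08, $V_b$ 3–12%, giving flux-constants
around 0.02 min$^{-1}$ — typical breast-tumour FDG values. The
default acquisition protocol is the 40-frame, 45-min dynamic schedule
with injection 30 s into the first frame (2700 s total, 44.5 min
post-injection). Static inputs are derived from the same kinetics —
blood and tumour concentrations extrapolated to 60 min, dose 3 MBq/kg
(capped at 400 MBq), weight ~N(70, 12) kg — so SUV and TBR correlate
with the true flux by construction rather than being sampled
independently.

`simulateExpression()` plants pathway genes as $x = \rho z +
\sqrt{1-\rho^2}\,\varepsilon$ on standardised scales ($z$ the
standardised measure), so the population gene–measure correlation
equals the requested effect size; the construction's bias is below 0.02
at $n = 30$. Filler genes are iid Gaussian on the log2 scale (default
2,000 genes, configurable up to the ~17,000 of a filtered RNA-seq
panel; 2,000 keeps 10,000-permutation studies fast). What the generator
does **not** emulate: gene–gene correlation structure,
heteroscedastic counts, batch effects, scanner and reconstruction
effects, and ROI-delineation variability. Passing tests therefore
certify the statistical machinery under its stated assumptions, not
performance on real data.

## Identifiability caveats the synthetic studies expose

* The slowest AIF washout rate $\mu_3$ is weakly identified on a 45-min
  window: fits with $\mu_3$ near zero can beat the generating
  parameters' weighted RSS. The fitted curve and its running integral —
  what the kinetic models actually consume — remain accurate to a few
  percent, which is how AIF fit quality is asserted.
* Micro-parameters are recovered far less precisely than the
  flux-constants they combine into (typically 12–35% versus ~4% RMS at
  the default noise), the precision ordering the analysis machinery is
  designed around.

# Problem sizes and reproducibility

Every generator and analysis stage is seeded; a master seed fans out to
per-stage sub-seeds through a fixed integer map, so `runAll()` under one
configuration reproduces every numeric table byte for byte, and each
table carries the configuration hash in a comment header. The test
suite runs the recovery study at 100 noisy fits, the coverage study at
200 replicates, null calibration at 200 sets × 2,000 permutations, the
planted-power study at 20 replicates × 10,000 permutations and the
false-positive study at 100 datasets × 10,000 permutations; these sizes
make the binomial/KS margins decisive while keeping the suite a
few-minute run, and `scripts/acceptance.R` re-derives the same
quantities from scratch at the same sizes.

# Known limitations

Beyond the synthetic-data caveats above: profile uncertainties are
implemented for compartment models (including derived 2C3K flux), not
for the spline model; the Patlak intercept is reported but unused
downstream; no dispersion/delay correction between AIF and tumour is
applied; reversible graphical analysis (Logan), AIC/BIC selection,
voxelwise imaging and gene-identifier mapping are out of scope. Figure
rendering is intentionally thin: the package emits the tables behind
heatmaps and CDF plots rather than styled graphics.
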