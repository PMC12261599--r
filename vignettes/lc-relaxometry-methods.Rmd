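---
title: "Quantitative relaxometry of the locus coeruleus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative relaxometry of the locus coeruleus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcrelax)
```

# Scope

`lcrelax` implements a complete quantitative MR relaxometry analysis of the
locus coeruleus (LC): simulation of multi-flip-angle SPGR, phase-cycled bSSFP
and double-angle B1 acquisitions; voxel-wise estimation of R1 (DESPOT1), R2
(DESPOT2) and the myelin water fraction (Bayesian Monte-Carlo two-pool
estimation); rostro-caudal topographic profiling of the LC; and the
cross-sectional and longitudinal statistical models linking LC microstructure
to age and cognition. Because raw in-vivo data of this kind are not freely
redistributable, the package ships a synthetic-data module — an LC-like
digital phantom and a generative longitudinal cohort — so that every stage is
testable offline against known ground truth.

# Signal models

## SPGR

The spoiled gradient-echo steady state is
$$S = M_0\,(1 - E_1)\frac{\sin(\kappa\alpha)}{1 - E_1\cos(\kappa\alpha)},
\qquad E_1 = e^{-TR/T_1},$$
where $\kappa$ is the per-voxel flip-angle (B1) scale. TE decay multiplies
every flip angle by the same constant and is therefore folded into $M_0$; no
estimator in this pipeline depends on that scale.

## bSSFP

The balanced steady state is obtained by solving the $3\times 3$ linear
fixed point of one TR's propagation — rotation by $\kappa\alpha$ about $x$,
relaxation, and free precession by
$$\beta = 2\pi\,\Delta f\,TR - \Delta\phi$$
about $z$ — in closed form (Cramer's rule), with the magnitude read out at
TE, where transverse decay $e^{-TE/T_2}$ applies and the residual precession
only rotates the phase. The sign convention for $\beta$ above is a package
choice (the two acquired phase increments, $0$ and $\pi$, are what matters
downstream; magnitude signals are even in $\beta$). When the effective per-TR
precession is $\pi$, the solution reduces to the familiar
$S = M_0\sin\alpha\,(1-E_1)/(1-(E_1-E_2)\cos\alpha - E_1E_2)$, which the test
suite checks against both the matrix solution and a brute-force Bloch
iteration.

## Two-pool model and DAM

The two-component non-exchanging model assigns a fraction `mwf` of the signal
to a short-$T_1$/short-$T_2$ pool (water trapped within myelin sheets) and
the rest to a long pool (intra/extra-cellular water); both pools share $M_0$,
off-resonance and $\kappa$, and every sequence signal is the corresponding
linear mixture. The double-angle method (DAM) pair is modelled as
$(c\sin\kappa\alpha,\; c\sin 2\kappa\alpha)$ under the long-TR assumption of
complete T1 recovery, so $\kappa = \arccos(S_2/2S_1)/\alpha$.

# Estimation

## DESPOT1 / DESPOT2

DESPOT1 is the classic unweighted linearised fit of
$S/\sin(\kappa\alpha)$ on $S/\tan(\kappa\alpha)$; the slope is $E_1$. A slope
outside $(0,1)$ marks the voxel failed rather than propagating NaN. DESPOT2
has two paths:

* **joint** (default): bounded nonlinear least squares over both phase
  cycles for $(T_2, \Delta f)$ with the amplitude profiled analytically,
  multi-started at three $\Delta f$ seeds; bounds $T_2 \in (1, 500]$ ms,
  $\Delta f \in [-1/2TR,\, 1/2TR]$. Because the acquired magnitudes are even
  functions of the precession angle, $+\Delta f$ and $-\Delta f$ produce
  identical data and the fit returns $|\Delta f|$ up to sign.
* **linearized**: the single-cycle estimator on the $\pi$ cycle
  ($E_2 = (E_1 - m)/(1 - mE_1)$), exact on resonance and used as the
  independent oracle path in tests.

Which combination of phase cycles an acquisition site uses varies in
practice, so the choice is a config flag; both paths agree on resonance.

## Bayesian Monte-Carlo MWF

The MWF estimator is posterior averaging under independent uniform priors on
(MWF, short/long $T_1$, short/long $T_2$, $\Delta f$), with defaults from the
multicomponent-relaxometry literature: MWF $[0, 0.4]$, $T_{1s}$ $[150, 600]$
ms, $T_{1l}$ $[600, 2500]$ ms, $T_{2s}$ $[5, 40]$ ms, $T_{2l}$ $[40, 150]$
ms, $\Delta f$ within the bSSFP band. Signals are normalised per sequence by
their mean over flip angles (removing inter-sequence $M_0$/TE scales), a
global amplitude is profiled analytically, and each sampled parameter vector
receives likelihood weight $\exp(-RSS/2\sigma^2)$.

A design point discovered during development and worth recording: the
profiled-RSS surface of this model has a long, shallow ridge along which MWF
trades off against the pool relaxation times (on mean-normalised signals,
moving MWF by 0.05 with re-optimised nuisances raises RSS by only a few
$10^{-4}$). A single-stage sampler drawing uniformly over the 6-D prior
cannot place samples densely enough near the mode at any realistic budget —
the best of $10^6$ flat draws typically sits at RSS $\sim 5\times10^{-4}$
*anywhere along the ridge*, so its MWF is almost uninformative. The default
estimator therefore localises the basin first (a vectorised coarse scan plus
multi-start bounded L-BFGS on the profiled RSS) and then draws the
Monte-Carlo samples from an equal mixture of the uniform prior and a uniform
box around the located minimum, dividing each weight by its exact proposal
density. This importance correction means the estimator targets *the same
posterior* as the flat sampler — including the shrinkage of the posterior
mean towards the prior midpoint as $\sigma$ grows — but with usable variance.
The flat sampler remains available (`proposal = "prior"`) and is what the
determinism, bounds and shrinkage property tests exercise.

$\sigma$ is by default estimated from the best sample,
$\hat\sigma = \sqrt{RSS_{\min}/(n_{sig} - 7)}$; a fixed-$\sigma$ mode exists
for tests (the suite uses $\sigma = 0.1$ on normalised signals where it needs
smooth, diffuse weights, e.g. for the $n^{-1/2}$ Monte-Carlo error check).
The reported effective sample size $(\sum w)^2/\sum w^2$ flags
low-confidence voxels (< 10).

# The phantom and the synthetic cohort

The phantom is two parallel circular cylinders (default length 14.5 mm,
diameter 2.5 mm — the nominal dimensions of the adult LC) aligned with the
rostro-caudal grid axis in a 0.5 mm isotropic grid, embedded in homogeneous
background. Tube parameters interpolate linearly from the rostral to the
caudal end; voxels belong to a tube when their centre falls inside the
analytic cylinder (so a 14.5 mm tube spans exactly 29 slices at 0.5 mm). The
published figures for this kind of analysis do not report numeric in-vivo LC
R1/R2/MWF ranges, so the default tissue values (background $T_1$ 1200 ms,
$T_2$ 80 ms, MWF 0.15; LC rostral $T_1$ 900 ms, $T_2$ 60 ms, MWF 0.10;
caudal $T_1$ 950 ms, $T_2$ 70 ms, MWF 0.05) are plausible brainstem numbers
chosen for simulation and are explicitly *not* reference values.

Acquisition noise is additive Gaussian on magnitude signals — the high-SNR
limit of Rician noise, which keeps the ratio-based estimators unbiased in
tests; a full Rician option exists. The simulator does not model
registration error, motion, slice profiles or scanner reconstruction, so
passing phantom round trips demonstrate correctness of the estimators, not
robustness to those real-data effects.

The cohort generator is the generative twin of the longitudinal model:
uniform ages over 22–94 years (which reproduces the target cohort's age SD
of about 21 years), sex/race/education per the reference demographics,
per-metric qMRI age models (R2 declining linearly with age, R1 with a mild
inverted-U, MWF flat — matching the qualitative in-vivo pattern), truncated
Poisson visit counts (mean 3, minimum 1) at 1.5-year spacing ending at the
MRI date (time 0), and cognition built from the full fixed-effect structure
up to the age × qMRI × time interaction plus a participant random intercept
and i.i.d. residuals. Age and the driving qMRI metric enter the linear
predictor mean-centred over the realised cohort — exactly the convention the
fitting routine uses — so fitted coefficients estimate the generating ones
without reparameterisation bookkeeping. The default three-way coefficient is
*positive* (+0.003 z-units/year per unit R2 per year of age): with centred
age and centred qMRI, a positive coefficient is what produces "lower rostral
R2 → steeper cognitive decline at older ages".

# Topography

Slice profiles average each metric over ok-status mask voxels per slice
along the rostro-caudal axis; slice $k$ of $n$ (k = 0 most rostral) gets the
midpoint percentile $100(k+0.5)/n$. The midpoint rule decides boundary
slices (a slice belongs to rostral-middle iff its midpoint percentile is
below 66) — it avoids double-counting the boundary slice and makes the
profile flip-symmetric. Left and right LC are pooled by default. Subregion
means are voxel-count-weighted, so the whole-LC mean is exactly the weighted
combination of the subregion means. The finer bands (rostral 0–44, restricted
caudal 86–100) are reported alongside.

The sensitivity masks reproduce the logic of mask-specificity checks: a
shell (3 iterations of 6-connected dilation, minus the LC) and ±1.5 mm
lateral translations (integer voxels on the grid; voxels that would overlap
the original mask are removed and counted). The 6-connected structuring
element is fixed and documented so shells are reproducible.

# Statistical models

Four families, with race dummy-coded against the largest category:

1. metric ~ age + sex + race + education (OLS; age slope of interest);
2. metric ~ centred age + centred age² + covariates (inverted-U test);
3. domain z-score at MRI ~ age + covariates + metric (cross-sectional);
4. longitudinal domain z-scores with fixed effects up to age × metric × time
   and a participant random intercept, fitted by REML (ML available), with
   Satterthwaite p-values. The metric is mean-centred; age is mean-centred
   by default as well (a pure reparameterisation that stabilises the
   three-way term; flag to disable). REML is a package choice — the
   estimation method is not pinned down by the source analysis.

Cognitive domains are memory (CVLT immediate/delayed), attention (TMT-A,
digit span forward), executive (TMT-B, digit span backward), verbal fluency
(category/letter) and processing speed (TMT-A, DSST). TMT times are
$-\log(t)$-transformed (natural log; the base cancels in z-scoring) before
z-scoring against the mean/SD of participants' first assessments, so all
domains are higher-is-better. A domain with a missing constituent is the
mean of the available tests, with a completeness flag — dropping whole
visits would discard information the mixed model can use.

BH-FDR is applied within the declared family (subregion variants × five
domains per metric and effect; `p.adjust(method = "BH")` behind the package
surface, cross-checked in the tests against a brute-force step-up oracle).
Slice-level age-model predictions at ages 40 and 75 hold sex and race at
their reference levels and education at the sample mean (the reference
choice is a package decision; predictions shift all slices equally under a
different choice, leaving the rostro-caudal pattern intact).

# Problem sizes and numerical choices

The test-suite and acceptance computations use, as package choices: a
24 × 24 × 40-voxel phantom at 0.5 mm (29 LC slices, ~930 LC voxels);
1,000-draw random-parameter grids against a 25,000-TR Bloch oracle at
$10^{-8}$; joint DESPOT2 on the LC plus a 150-voxel background sample;
BMC-MWF at $10^6$ samples for recovery and $10^3$–$10^5$ for Monte-Carlo
error scaling; 50 replicates at n = 300 for mixed-model coverage and 1,000
replicates at n = 120 for the type-I error of the cross-sectional qMRI
coefficient. Degenerate inputs (all-zero voxels, collinear designs, ratios
outside the arccos domain, singular mixed-model fits) are flagged with
status codes and excluded from ROI summaries; nothing silently becomes 1.0
or NaN.

# Known limitations

* No magnetisation-transfer, water exchange, finite-pulse or slice-profile
  effects in the signal models; these are out of scope by design.
* Masks and maps are assumed co-registered; registration to template space
  is outside the package.
* The joint DESPOT2 off-resonance estimate carries a sign ambiguity
  inherent to magnitude data.
* The BMC-MWF posterior is ridge-shaped; at realistic SNR the estimate's
  accuracy depends on the prior bounds, which are configuration, not
  physical constants.
* The synthetic cohort draws visit times on a regular grid before the scan;
  real assessment schedules are irregular and right of the scan date as
  well, which mainly affects power, not estimand definitions.
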