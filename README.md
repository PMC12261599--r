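# lcrelax

Quantitative MR relaxometry of the locus coeruleus (LC): simulation,
voxel-wise parameter estimation, rostro-caudal topography, and the
statistical models linking LC microstructure to age and cognition.

The LC is a small noradrenergic brainstem nucleus (~14.5 mm long, ~2.5 mm
thick) whose degeneration is implicated in aging and Alzheimer's disease.
Conventional neuromelanin-contrast measures of LC integrity are
scanner-dependent; multi-flip-angle relaxometry instead estimates the
physical tissue parameters R1 = 1/T1, R2 = 1/T2 and the myelin water
fraction (MWF) from SPGR and phase-cycled bSSFP acquisitions plus a
double-angle B1 map. This package is for imaging methodologists and
aging-cohort analysts who want a tested, fully synthetic-data-capable
implementation of that pipeline:

* **Forward models** — closed-form SPGR and bSSFP steady states (the bSSFP
  solution from the 3×3 fixed point of one TR's propagation,
  S = M0·sinα·(1−E1)/(1−(E1−E2)cosα−E1E2) in the π-precession limit), the
  double-angle pair (c·sin κα, c·sin 2κα), and their two-pool non-exchanging
  mixtures.
* **Fitting** — DESPOT1 (linearised variable-flip-angle T1), DESPOT2 (joint
  two-phase-cycle nonlinear or linearised single-cycle T2), double-angle B1
  with trilinear upsampling, and Bayesian Monte-Carlo two-pool MWF
  estimation (uniform priors, analytic amplitude profiling, importance
  weights exp(−RSS/2σ²), posterior-mean MWF).
* **Topography** — rostro-caudal slice profiles with midpoint percentiles,
  the rostral-middle (0–66th percentile) / caudal (66–100th) split plus the
  finer 0–44 and 86–100 bands, and the sensitivity-analysis masks (3-voxel
  dilated shell, ±1.5 mm lateral shifts).
* **Statistics** — linear and quadratic age models, cross-sectional
  cognition models, random-intercept mixed models with the full
  age × qMRI × time interaction (REML, Satterthwaite p-values),
  Benjamini–Hochberg FDR within the declared family, and slice-level
  predictions at reference ages.
* **Synthetic data** — an LC phantom with ground-truth rostro-caudal
  parameter gradients and a generative longitudinal cohort matching the
  statistical models' structure, so the entire pipeline runs and is tested
  offline.

## Worked example

```r
library(lcrelax)

## a bilateral LC phantom: two 14.5 x 2.5 mm tubes in a 0.5 mm grid
spec <- PhantomSpec()
ph <- generatePhantom(spec)
ph$mask
#> LcMask: 928 voxels on 24x24x40 grid, rostro-caudal axis 3 (first end rostral)

## simulate the acquisitions and fit R1/R2 maps inside the mask
stacks <- simulateAcquisition(ph$params, AcquisitionProtocol(), seed = 1,
                              voxelSize = 0.5)
maps <- fitVolume(stacks, mask = ph$mask, despot2Path = "linearized")

## rostro-caudal profile and subregion summary
prof <- sliceProfile(maps, ph$mask)
head(prof@profile, 3)
#>   slice percentile nVoxels nOk       r1       r2 mwf
#> 1     6   1.724138      32  32 1.111111 16.66667  NA
#> 2     7   5.172414      32  32 1.108987 16.57143  NA
#> 3     8   8.620690      32  32 1.106870 16.47727  NA
subset(splitSubregions(prof)@summary, metric == "r2")
#>              region metric     mean nVoxels nSlices
#> 2           wholeLC     r2 15.45619     928      29
#> 5     rostralMiddle     r2 15.86121     608      19
#> 8            caudal     r2 14.68665     320      10
#> 11          rostral     r2 16.11808     416      13
#> 14 restrictedCaudal     r2 14.46429     128       4
```

The fitted rostral-middle R2 (15.86 1/s) exceeds the caudal value
(14.69 1/s), recovering the planted rostro-caudal gradient (rostral T2
60 ms → caudal 70 ms), and the whole-LC mean is exactly the voxel-weighted
combination of the subregions.

```r
## a synthetic 120-participant cohort with longitudinal cognition, and the
## mixed model for the age-moderated effect of rostral R2 on decline
cc <- generateCohort(CohortGenSpec(seed = 1))
fit <- fitLongitudinal(cc$cohort, cc$visits, "rostralR2")
fit@coefficients[fit@coefficients$term %in%
                   c("rostralR2:time", "age:rostralR2:time"), ]
#>                  term    estimate           se            p
#> 11     rostralR2:time 0.032592040 0.0118542639 6.363818e-03
#> 12 age:rostralR2:time 0.002750991 0.0006007011 7.041796e-06
```

The three-way interaction (0.00275, p ≈ 7e-6) recovers the generating
coefficient (0.003): with age and R2 mean-centred, a positive value means
lower rostral R2 predicts steeper cognitive decline at older ages.

A stage-wise runner with manifests is available via `runPipeline()` /
`runStage()` (and the thin CLI wrapper in `inst/scripts/lc_relaxo.R`).

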