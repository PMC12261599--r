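## Central S4 classes of the package. All image-like objects store their voxel
## data as plain numeric/logical vectors in column-major order together with a
## `dim` (grid shape) and `voxelSize` (mm), so that every map, mask and signal
## stack shares one geometry convention.

## ---------------------------------------------------------------------------
## AcquisitionProtocol
## ---------------------------------------------------------------------------

#' Acquisition protocol for the multi-flip-angle relaxometry experiment
#'
#' Holds the sequence timing and flip-angle schedule of the three acquisitions
#' the pipeline models: a multi-flip-angle SPGR series, two phase-cycled bSSFP
#' series, and a two-angle fast-spin-echo pair for double-angle B1 mapping.
#' Defaults follow a 3T brain protocol: SPGR TE/TR 1.48/5 ms with flip angles
#' 2--20 degrees, bSSFP TE/TR 2.8/5.9 ms with flip angles 2--60 degrees and RF
#' phase increments 0 and pi, and a 45/90 degree fast-spin-echo pair
#' (TE/TR 102/3000 ms) for B1.
#'
#' @slot spgrTeTr,bssfpTeTr,damTeTr numeric(2), TE and TR in ms.
#' @slot spgrFlipAngles,bssfpFlipAngles numeric, nominal flip angles (degrees),
#'   strictly increasing.
#' @slot bssfpPhaseIncrements numeric, RF phase increments (radians).
#' @slot damFlipAngles numeric(2), the double-angle pair; the second angle must
#'   be exactly twice the first.
#' @slot noiseSd numeric(1), standard deviation of the acquisition noise in
#'   signal units (0 = noiseless).
#' @export
setClass("AcquisitionProtocol", representation(
  spgrTeTr = "numeric", spgrFlipAngles = "numeric",
  bssfpTeTr = "numeric", bssfpFlipAngles = "numeric",
  bssfpPhaseIncrements = "numeric",
  damFlipAngles = "numeric", damTeTr = "numeric",
  noiseSd = "numeric"))

setValidity("AcquisitionProtocol", function(object) {
  msgs <- character()
  for (nm in c("spgrTeTr", "bssfpTeTr", "damTeTr")) {
    tetr <- slot(object, nm)
    if (length(tetr) != 2L || !(tetr[2] > tetr[1] && tetr[1] > 0))
      msgs <- c(msgs, sprintf("%s must satisfy TR > TE > 0", nm))
  }
  fa <- object@spgrFlipAngles
  if (length(fa) < 1L || any(diff(fa) <= 0) || any(fa <= 0) || any(fa > 90))
    msgs <- c(msgs, "spgrFlipAngles must be strictly increasing in (0, 90]")
  fb <- object@bssfpFlipAngles
  if (length(fb) < 1L || any(diff(fb) <= 0) || any(fb <= 0) || any(fb >= 180))
    msgs <- c(msgs, "bssfpFlipAngles must be strictly increasing in (0, 180)")
  da <- object@damFlipAngles
  if (length(da) != 2L || any(da <= 0) || da[1] > 90 ||
      abs(da[2] - 2 * da[1]) > 1e-9)
    msgs <- c(msgs, "damFlipAngles must be (alpha, 2*alpha) with alpha in (0, 90]")
  if (length(object@bssfpPhaseIncrements) < 1L)
    msgs <- c(msgs, "at least one bSSFP phase increment is required")
  if (length(object@noiseSd) != 1L || object@noiseSd < 0)
    msgs <- c(msgs, "noiseSd must be a single value >= 0")
  if (length(msgs)) msgs else TRUE
})

#' @param spgrTeTr,spgrFlipAngles,bssfpTeTr,bssfpFlipAngles,bssfpPhaseIncrements,damFlipAngles,damTeTr,noiseSd
#'   see slots.
#' @return An \code{AcquisitionProtocol} object.
#' @examples
#' AcquisitionProtocol()
#' @rdname AcquisitionProtocol-class
#' @export
AcquisitionProtocol <- function(spgrTeTr = c(1.48, 5),
                                spgrFlipAngles = c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20),
                                bssfpTeTr = c(2.8, 5.9),
                                bssfpFlipAngles = c(2, 4, 7, 11, 16, 24, 32, 40, 50, 60),
                                bssfpPhaseIncrements = c(0, pi),
                                damFlipAngles = c(45, 90),
                                damTeTr = c(102, 3000),
                                noiseSd = 0) {
  new("AcquisitionProtocol", spgrTeTr = spgrTeTr, spgrFlipAngles = spgrFlipAngles,
      bssfpTeTr = bssfpTeTr, bssfpFlipAngles = bssfpFlipAngles,
      bssfpPhaseIncrements = bssfpPhaseIncrements,
      damFlipAngles = damFlipAngles, damTeTr = damTeTr, noiseSd = noiseSd)
}

setMethod("show", "AcquisitionProtocol", function(object) {
  cat("AcquisitionProtocol\n")
  cat(sprintf("  SPGR : TE/TR %.2f/%.2f ms, %d flip angles (%g..%g deg)\n",
              object@spgrTeTr[1], object@spgrTeTr[2],
              length(object@spgrFlipAngles),
              min(object@spgrFlipAngles), max(object@spgrFlipAngles)))
  cat(sprintf("  bSSFP: TE/TR %.2f/%.2f ms, %d flip angles, phase increments %s\n",
              object@bssfpTeTr[1], object@bssfpTeTr[2],
              length(object@bssfpFlipAngles),
              paste(sprintf("%.3g", object@bssfpPhaseIncrements), collapse = ", ")))
  cat(sprintf("  DAM  : TE/TR %.0f/%.0f ms, angles %g/%g deg\n",
              object@damTeTr[1], object@damTeTr[2],
              object@damFlipAngles[1], object@damFlipAngles[2]))
  cat(sprintf("  noise SD: %g\n", object@noiseSd))
})

## ---------------------------------------------------------------------------
## TissueParameters
## ---------------------------------------------------------------------------

#' Tissue relaxation and myelin-water parameters (scalar voxel or volume)
#'
#' Per-voxel ground-truth or estimated relaxation quantities. Each field is a
#' numeric vector of length 1 (a single voxel, or a spatially constant value)
#' or \code{prod(dim(object))} in column-major voxel order. The single-pool
#' parameterisation (\code{t1}, \code{t2}) drives the single-component forward
#' models; the two-pool parameterisation (\code{mwf}, short/long T1 and T2)
#' drives the non-exchanging two-component models, where the short pool stands
#' for water trapped within myelin sheets and the long pool for
#' intra/extra-cellular water. Relaxation rates are the reciprocals
#' R1 = 1/T1, R2 = 1/T2.
#'
#' @slot m0 equilibrium signal (arbitrary units).
#' @slot t1,t2 single-component relaxation times, ms.
#' @slot mwf myelin water fraction in [0, 1].
#' @slot t1Short,t1Long,t2Short,t2Long two-pool relaxation times, ms;
#'   short < long elementwise.
#' @slot offResonance off-resonance frequency, Hz.
#' @slot b1Scale dimensionless multiplicative flip-angle factor kappa (> 0).
#' @slot dim integer grid shape; \code{integer(0)} for a single voxel.
#' @export
setClass("TissueParameters", representation(
  m0 = "numeric", t1 = "numeric", t2 = "numeric", mwf = "numeric",
  t1Short = "numeric", t1Long = "numeric",
  t2Short = "numeric", t2Long = "numeric",
  offResonance = "numeric", b1Scale = "numeric", dim = "integer"))

setValidity("TissueParameters", function(object) {
  msgs <- character()
  nVox <- if (length(object@dim)) prod(object@dim) else 1L
  for (nm in c("m0", "t1", "t2", "mwf", "t1Short", "t1Long", "t2Short",
               "t2Long", "offResonance", "b1Scale")) {
    len <- length(slot(object, nm))
    if (!(len == 1L || len == nVox))
      msgs <- c(msgs, sprintf("field %s has length %d, expected 1 or %d",
                              nm, len, nVox))
  }
  for (nm in c("t1", "t2", "t1Short", "t1Long", "t2Short", "t2Long"))
    if (any(slot(object, nm) <= 0))
      msgs <- c(msgs, sprintf("%s must be > 0", nm))
  if (any(object@mwf < 0 | object@mwf > 1))
    msgs <- c(msgs, "mwf must lie in [0, 1]")
  if (any(recycleField(object@t1Short, nVox) >= recycleField(object@t1Long, nVox)))
    msgs <- c(msgs, "t1Short must be < t1Long")
  if (any(recycleField(object@t2Short, nVox) >= recycleField(object@t2Long, nVox)))
    msgs <- c(msgs, "t2Short must be < t2Long")
  if (any(object@b1Scale <= 0))
    msgs <- c(msgs, "b1Scale must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' @param m0,t1,t2,mwf,t1Short,t1Long,t2Short,t2Long,offResonance,b1Scale see
#'   slots.
#' @param dim integer grid shape, or \code{integer(0)} for a scalar voxel.
#' @return A \code{TissueParameters} object.
#' @examples
#' TissueParameters(t1 = 1000, t2 = 80)
#' @rdname TissueParameters-class
#' @export
TissueParameters <- function(m0 = 1, t1 = 1000, t2 = 80, mwf = 0,
                             t1Short = pmin(350, t1 / 2), t1Long = t1,
                             t2Short = pmin(20, t2 / 2), t2Long = t2,
                             offResonance = 0, b1Scale = 1,
                             dim = integer(0)) {
  new("TissueParameters", m0 = as.numeric(m0), t1 = as.numeric(t1),
      t2 = as.numeric(t2), mwf = as.numeric(mwf),
      t1Short = as.numeric(t1Short), t1Long = as.numeric(t1Long),
      t2Short = as.numeric(t2Short), t2Long = as.numeric(t2Long),
      offResonance = as.numeric(offResonance), b1Scale = as.numeric(b1Scale),
      dim = as.integer(dim))
}

#' Number of voxels represented by a TissueParameters object
#' @param params a \code{TissueParameters} object.
#' @return integer voxel count (1 for a scalar voxel).
#' @export
nVoxels <- function(params) {
  if (length(params@dim)) prod(params@dim) else 1L
}

setMethod("show", "TissueParameters", function(object) {
  nv <- nVoxels(object)
  cat(sprintf("TissueParameters: %s\n",
              if (nv == 1L) "single voxel"
              else sprintf("%s grid (%d voxels)",
                           paste(object@dim, collapse = "x"), nv)))
  fmt <- function(x) if (length(x) == 1L) sprintf("%g", x)
    else sprintf("[%g .. %g]", min(x), max(x))
  cat(sprintf("  T1 %s ms, T2 %s ms, MWF %s, M0 %s, B1 %s\n",
              fmt(object@t1), fmt(object@t2), fmt(object@mwf),
              fmt(object@m0), fmt(object@b1Scale)))
})

## ---------------------------------------------------------------------------
## SignalStackSet
## ---------------------------------------------------------------------------

#' Simulated or measured multi-flip-angle signal stacks
#'
#' Magnitude signals of the three acquisitions on a common grid. Voxels are
#' stored rowwise in column-major grid order: \code{spgr} is voxels x flip
#' angles, \code{bssfp} is voxels x flip angles x phase cycles, \code{dam} is
#' voxels x 2.
#'
#' @slot spgr numeric matrix.
#' @slot bssfp numeric 3-D array.
#' @slot dam numeric matrix.
#' @slot dim integer(3) grid shape.
#' @slot voxelSize numeric(3) voxel size, mm.
#' @slot protocol the \code{AcquisitionProtocol} the stacks follow.
#' @export
setClass("SignalStackSet", representation(
  spgr = "matrix", bssfp = "array", dam = "matrix",
  dim = "integer", voxelSize = "numeric", protocol = "AcquisitionProtocol"))

setValidity("SignalStackSet", function(object) {
  msgs <- character()
  nVox <- prod(object@dim)
  if (length(object@dim) != 3L) msgs <- c(msgs, "dim must have length 3")
  if (nrow(object@spgr) != nVox || nrow(object@dam) != nVox ||
      dim(object@bssfp)[1] != nVox)
    msgs <- c(msgs, "stack rows must equal prod(dim)")
  if (ncol(object@spgr) != length(object@protocol@spgrFlipAngles))
    msgs <- c(msgs, "spgr columns must match protocol flip angles")
  if (!all(dim(object@bssfp)[2:3] ==
           c(length(object@protocol@bssfpFlipAngles),
             length(object@protocol@bssfpPhaseIncrements))))
    msgs <- c(msgs, "bssfp dims must match protocol flip angles and cycles")
  if (ncol(object@dam) != 2L) msgs <- c(msgs, "dam must have two columns")
  if (any(object@spgr < 0) || any(object@bssfp < 0) || any(object@dam < 0))
    msgs <- c(msgs, "magnitude signals must be >= 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SignalStackSet", function(object) {
  cat(sprintf("SignalStackSet: %s grid, voxel %s mm\n",
              paste(object@dim, collapse = "x"),
              paste(object@voxelSize, collapse = "x")))
  cat(sprintf("  SPGR %d angles | bSSFP %d angles x %d cycles | DAM pair\n",
              ncol(object@spgr), dim(object@bssfp)[2], dim(object@bssfp)[3]))
})

## ---------------------------------------------------------------------------
## B1Map
## ---------------------------------------------------------------------------

#' Flip-angle scale (B1) field
#'
#' Per-voxel dimensionless flip-angle scale kappa estimated by the
#' double-angle method. Voxels where the estimate is undefined (zero signal)
#' are flagged in \code{defined} rather than silently set to 1.
#'
#' @slot kappa numeric vector, per-voxel kappa.
#' @slot defined logical vector, whether kappa is defined at each voxel.
#' @slot dim integer(3); @slot voxelSize numeric(3) mm.
#' @slot interpolated logical(1), whether this map was resampled from a
#'   lower-resolution acquisition grid.
#' @export
setClass("B1Map", representation(
  kappa = "numeric", defined = "logical", dim = "integer",
  voxelSize = "numeric", interpolated = "logical"))

setValidity("B1Map", function(object) {
  msgs <- character()
  nVox <- prod(object@dim)
  if (length(object@kappa) != nVox || length(object@defined) != nVox)
    msgs <- c(msgs, "kappa/defined length must equal prod(dim)")
  if (any(object@kappa[object@defined] < 0))
    msgs <- c(msgs, "kappa must be >= 0 where defined")
  if (length(msgs)) msgs else TRUE
})

#' @param kappa,defined,dim,voxelSize,interpolated see slots.
#' @return A \code{B1Map}.
#' @rdname B1Map-class
#' @export
B1Map <- function(kappa, dim, voxelSize, defined = rep(TRUE, length(kappa)),
                  interpolated = FALSE) {
  new("B1Map", kappa = as.numeric(kappa), defined = defined,
      dim = as.integer(dim),
      voxelSize = rep(as.numeric(voxelSize), length.out = 3),
      interpolated = interpolated)
}

setMethod("show", "B1Map", function(object) {
  cat(sprintf("B1Map: %s grid, kappa in [%.4g, %.4g], %d undefined voxel(s)%s\n",
              paste(object@dim, collapse = "x"),
              min(object@kappa[object@defined]), max(object@kappa[object@defined]),
              sum(!object@defined),
              if (object@interpolated) " (interpolated)" else ""))
})

## ---------------------------------------------------------------------------
## QmriMapSet
## ---------------------------------------------------------------------------

#' Co-registered quantitative MRI maps (R1, R2, MWF)
#'
#' Voxel-wise relaxation-rate and myelin-water-fraction maps sharing one grid,
#' with per-voxel fit diagnostics. Rates are stored in 1/s. Voxels whose fit
#' failed carry a non-"ok" status and are excluded from all ROI summaries
#' downstream.
#'
#' @slot r1,r2 numeric, relaxation rates (1/s); NA where the fit failed.
#' @slot mwf numeric, myelin water fraction in [0, 1]; NA where not estimated.
#' @slot m0 numeric, fitted equilibrium-signal scale.
#' @slot status character, per-voxel status code: "ok", "clamped",
#'   "non-converged", "degenerate" or "failed".
#' @slot resNorm numeric, per-voxel residual norm of the fit.
#' @slot dim integer(3); @slot voxelSize numeric(3) mm.
#' @export
setClass("QmriMapSet", representation(
  r1 = "numeric", r2 = "numeric", mwf = "numeric", m0 = "numeric",
  status = "character", resNorm = "numeric",
  dim = "integer", voxelSize = "numeric"))

setValidity("QmriMapSet", function(object) {
  msgs <- character()
  nVox <- prod(object@dim)
  for (nm in c("r1", "r2", "mwf", "m0", "status", "resNorm"))
    if (length(slot(object, nm)) != nVox)
      msgs <- c(msgs, sprintf("%s length must equal prod(dim)", nm))
  ok <- object@status == "ok"
  if (any(ok & (is.na(object@r1) | object@r1 <= 0), na.rm = TRUE) ||
      any(ok & (is.na(object@r2) | object@r2 <= 0), na.rm = TRUE))
    msgs <- c(msgs, "r1 and r2 must be > 0 where status is ok")
  if (any(object@mwf < 0 | object@mwf > 1, na.rm = TRUE))
    msgs <- c(msgs, "mwf must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' @param r1,r2,mwf,m0,status,resNorm,dim,voxelSize see slots.
#' @return A \code{QmriMapSet}.
#' @rdname QmriMapSet-class
#' @export
QmriMapSet <- function(r1, r2, mwf, m0, status, resNorm, dim, voxelSize) {
  nVox <- prod(dim)
  if (missing(mwf)) mwf <- rep(NA_real_, nVox)
  if (missing(m0)) m0 <- rep(NA_real_, nVox)
  if (missing(status)) status <- rep("ok", nVox)
  if (missing(resNorm)) resNorm <- rep(0, nVox)
  new("QmriMapSet", r1 = as.numeric(r1), r2 = as.numeric(r2),
      mwf = as.numeric(mwf), m0 = as.numeric(m0), status = status,
      resNorm = as.numeric(resNorm), dim = as.integer(dim),
      voxelSize = rep(as.numeric(voxelSize), length.out = 3))
}

setMethod("show", "QmriMapSet", function(object) {
  ok <- object@status == "ok"
  cat(sprintf("QmriMapSet: %s grid, %d/%d voxels ok\n",
              paste(object@dim, collapse = "x"), sum(ok), length(ok)))
  if (any(ok))
    cat(sprintf("  R1 [%.3g, %.3g] 1/s | R2 [%.3g, %.3g] 1/s | MWF [%.3g, %.3g]\n",
                min(object@r1[ok]), max(object@r1[ok]),
                min(object@r2[ok]), max(object@r2[ok]),
                suppressWarnings(min(object@mwf[ok], na.rm = TRUE)),
                suppressWarnings(max(object@mwf[ok], na.rm = TRUE))))
})

#' Ground-truth parameter volume as a QmriMapSet
#'
#' Converts a \code{TissueParameters} volume to rate maps (R1 = 1000/T1,
#' R2 = 1000/T2, both in 1/s) with all-ok status, e.g. to feed topography
#' operations with ground truth instead of fitted maps.
#'
#' @param params a \code{TissueParameters} volume.
#' @param voxelSize numeric voxel size (mm), recycled to length 3.
#' @return A \code{QmriMapSet}.
#' @export
asQmriMapSet <- function(params, voxelSize) {
  stopIfNot(length(params@dim) == 3L, "params must carry a 3-D grid")
  nVox <- nVoxels(params)
  QmriMapSet(r1 = 1000 / recycleField(params@t1, nVox),
             r2 = 1000 / recycleField(params@t2, nVox),
             mwf = recycleField(params@mwf, nVox),
             m0 = recycleField(params@m0, nVox),
             status = rep("ok", nVox), resNorm = rep(0, nVox),
             dim = params@dim, voxelSize = rep(voxelSize, length.out = 3))
}

## ---------------------------------------------------------------------------
## LcMask
## ---------------------------------------------------------------------------

#' Binary locus coeruleus region-of-interest mask
#'
#' A binary ROI on the map grid together with the rostro-caudal axis
#' convention: \code{rostrocaudalAxis} names the grid axis running along the
#' nucleus, and \code{rostralDirection} is +1 if the first slice along that
#' axis is the rostral end, -1 if the last slice is.
#'
#' @slot mask logical vector, column-major voxel order.
#' @slot dim integer(3); @slot voxelSize numeric(3) mm.
#' @slot rostrocaudalAxis integer in 1..3.
#' @slot rostralDirection integer, +1 or -1.
#' @slot diagnostics list, operation-specific bookkeeping (e.g. voxels removed
#'   by overlap stripping in \code{\link{shiftedMask}}).
#' @export
setClass("LcMask", representation(
  mask = "logical", dim = "integer", voxelSize = "numeric",
  rostrocaudalAxis = "integer", rostralDirection = "integer",
  diagnostics = "list"))

setValidity("LcMask", function(object) {
  msgs <- character()
  if (length(object@mask) != prod(object@dim))
    msgs <- c(msgs, "mask length must equal prod(dim)")
  if (!(object@rostrocaudalAxis %in% 1:3))
    msgs <- c(msgs, "rostrocaudalAxis must be 1, 2 or 3")
  if (!(object@rostralDirection %in% c(-1L, 1L)))
    msgs <- c(msgs, "rostralDirection must be +1 or -1")
  if (length(msgs)) msgs else TRUE
})

#' @param mask,dim,voxelSize,rostrocaudalAxis,rostralDirection,diagnostics see
#'   slots.
#' @return An \code{LcMask}.
#' @rdname LcMask-class
#' @export
LcMask <- function(mask, dim, voxelSize, rostrocaudalAxis = 3L,
                   rostralDirection = 1L, diagnostics = list()) {
  new("LcMask", mask = as.logical(mask), dim = as.integer(dim),
      voxelSize = rep(as.numeric(voxelSize), length.out = 3),
      rostrocaudalAxis = as.integer(rostrocaudalAxis),
      rostralDirection = as.integer(rostralDirection),
      diagnostics = diagnostics)
}

setMethod("show", "LcMask", function(object) {
  cat(sprintf("LcMask: %d voxels on %s grid, rostro-caudal axis %d (%s end rostral)\n",
              sum(object@mask), paste(object@dim, collapse = "x"),
              object@rostrocaudalAxis,
              if (object@rostralDirection == 1L) "first" else "last"))
})

## ---------------------------------------------------------------------------
## SliceProfile / SubregionSummary
## ---------------------------------------------------------------------------

#' Rostro-caudal slice profile of qMRI metrics
#'
#' Per-slice means of each metric over ok-status mask voxels, ordered rostral
#' to caudal, with midpoint rostro-caudal percentiles: slice k of n (k = 0 most
#' rostral) is assigned percentile 100 (k + 0.5) / n.
#'
#' @slot profile data.frame with columns \code{slice} (grid slice index),
#'   \code{percentile}, \code{nVoxels}, \code{nOk}, \code{r1}, \code{r2},
#'   \code{mwf}.
#' @slot rostrocaudalAxis,rostralDirection the mask's axis convention.
#' @export
setClass("SliceProfile", representation(
  profile = "data.frame", rostrocaudalAxis = "integer",
  rostralDirection = "integer"))

setValidity("SliceProfile", function(object) {
  p <- object@profile$percentile
  if (is.null(p) || any(p < 0 | p > 100) || any(diff(p) <= 0))
    "percentiles must be strictly increasing within [0, 100]" else TRUE
})

setMethod("show", "SliceProfile", function(object) {
  cat(sprintf("SliceProfile: %d slices (rostral -> caudal)\n",
              nrow(object@profile)))
  print(head(object@profile, 4))
  if (nrow(object@profile) > 4) cat("  ...\n")
})

#' Whole-LC and subregion summary of qMRI metrics
#'
#' Voxel-weighted metric means for the whole LC and its rostro-caudal
#' subregions (rostral-middle: percentile < 66; caudal: >= 66; plus the finer
#' rostral 0--44 and restricted caudal 86--100 bands).
#'
#' @slot summary data.frame with columns \code{region}, \code{metric},
#'   \code{mean}, \code{nVoxels}, \code{nSlices}.
#' @export
setClass("SubregionSummary", representation(summary = "data.frame"))

setMethod("show", "SubregionSummary", function(object) {
  cat("SubregionSummary:\n"); print(object@summary)
})

## ---------------------------------------------------------------------------
## PhantomSpec
## ---------------------------------------------------------------------------

#' Specification of the bilateral LC phantom
#'
#' Defines a digital phantom: two parallel circular cylinders (left/right LC,
#' default 14.5 mm long, 2.5 mm thick) aligned with the rostro-caudal grid
#' axis, embedded in homogeneous background tissue, with tube parameters
#' linearly interpolated from \code{lcParamsRostral} at the rostral end to
#' \code{lcParamsCaudal} at the caudal end. Voxels belong to a tube when their
#' centre falls inside the analytic cylinder.
#'
#' @slot gridShape integer(3) voxels; @slot voxelSize numeric(1) mm (isotropic).
#' @slot lcLength,lcThickness numeric(1) mm.
#' @slot lcCenterOffsets numeric(2), lateral (axis-1) offsets of the two tube
#'   centres from the grid centre, mm.
#' @slot backgroundParams,lcParamsRostral,lcParamsCaudal scalar
#'   \code{TissueParameters}.
#' @slot rostrocaudalAxis integer in 1..3; @slot rostralDirection +1/-1 (+1:
#'   first slice along the axis is rostral).
#' @slot seed integer.
#' @export
setClass("PhantomSpec", representation(
  gridShape = "integer", voxelSize = "numeric",
  lcLength = "numeric", lcThickness = "numeric", lcCenterOffsets = "numeric",
  backgroundParams = "TissueParameters",
  lcParamsRostral = "TissueParameters", lcParamsCaudal = "TissueParameters",
  rostrocaudalAxis = "integer", rostralDirection = "integer",
  seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1))
    msgs <- c(msgs, "gridShape must be a positive integer triple")
  if (object@voxelSize <= 0) msgs <- c(msgs, "voxelSize must be > 0")
  if (object@lcLength / object@voxelSize < 3)
    msgs <- c(msgs, "lcLength must span at least 3 slices")
  if (object@lcThickness <= 0) msgs <- c(msgs, "lcThickness must be > 0")
  for (nm in c("backgroundParams", "lcParamsRostral", "lcParamsCaudal"))
    if (nVoxels(slot(object, nm)) != 1L)
      msgs <- c(msgs, sprintf("%s must be a scalar TissueParameters", nm))
  if (!(object@rostrocaudalAxis %in% 1:3))
    msgs <- c(msgs, "rostrocaudalAxis must be 1, 2 or 3")
  if (length(msgs)) msgs else TRUE
})

#' @param gridShape,voxelSize,lcLength,lcThickness,lcCenterOffsets,backgroundParams,lcParamsRostral,lcParamsCaudal,rostrocaudalAxis,rostralDirection,seed
#'   see slots. Default tissue values are plausible brainstem/LC numbers chosen
#'   for simulation and are not in-vivo reference values.
#' @return A \code{PhantomSpec}.
#' @examples
#' spec <- PhantomSpec()
#' @rdname PhantomSpec-class
#' @export
PhantomSpec <- function(gridShape = c(24L, 24L, 40L), voxelSize = 0.5,
                        lcLength = 14.5, lcThickness = 2.5,
                        lcCenterOffsets = c(-2.5, 2.5),
                        backgroundParams = TissueParameters(
                          m0 = 100, t1 = 1200, t2 = 80, mwf = 0.15,
                          t1Short = 350, t1Long = 1300, t2Short = 20, t2Long = 90),
                        lcParamsRostral = TissueParameters(
                          m0 = 100, t1 = 900, t2 = 60, mwf = 0.10,
                          t1Short = 350, t1Long = 1000, t2Short = 20, t2Long = 70),
                        lcParamsCaudal = TissueParameters(
                          m0 = 100, t1 = 950, t2 = 70, mwf = 0.05,
                          t1Short = 350, t1Long = 1050, t2Short = 20, t2Long = 80),
                        rostrocaudalAxis = 3L, rostralDirection = 1L,
                        seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = voxelSize, lcLength = lcLength, lcThickness = lcThickness,
      lcCenterOffsets = lcCenterOffsets, backgroundParams = backgroundParams,
      lcParamsRostral = lcParamsRostral, lcParamsCaudal = lcParamsCaudal,
      rostrocaudalAxis = as.integer(rostrocaudalAxis),
      rostralDirection = as.integer(rostralDirection), seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s grid @ %g mm, LC %g x %g mm, axis %d\n",
              paste(object@gridShape, collapse = "x"), object@voxelSize,
              object@lcLength, object@lcThickness, object@rostrocaudalAxis))
})

## ---------------------------------------------------------------------------
## CohortGenSpec
## ---------------------------------------------------------------------------

#' Specification of the synthetic longitudinal cohort
#'
#' Generative twin of the statistical models: participant covariates, qMRI
#' summaries drawn from per-metric age models, and longitudinal cognition
#' generated from the mixed-model structure (fixed effects up to the
#' age x qMRI x time three-way interaction, a participant random intercept and
#' i.i.d. residuals). Defaults emulate a cognitively normal aging cohort of
#' 120 adults aged 22--94 (age mean ~56, SD ~21; 53% male; 68% White / 19%
#' Black; education 16.3 (2.7) years; ~3 cognitive assessments per person).
#'
#' @slot nParticipants integer >= 2.
#' @slot ageRange numeric(2) years; ages are drawn uniformly.
#' @slot sexProb probability of male.
#' @slot raceProbs named probability vector summing to 1.
#' @slot edyMeanSd numeric(2), years of education mean and SD.
#' @slot qmriAgeModel named list; per metric a list with elements
#'   \code{intercept}, \code{age}, \code{age2} (coefficients on centred age)
#'   and \code{sd} (residual SD).
#' @slot cognitionDriver name of the qMRI metric entering the cognition model.
#' @slot cognitionBetas named numeric: \code{intercept, age, sex, raceBlack,
#'   raceOther, edy, time, qmri, ageTime, qmriAge, qmriTime, qmriTimeAge}.
#'   Age and qMRI enter mean-centred (over the realised cohort).
#' @slot randomInterceptSd,residualSd z-units, >= 0.
#' @slot visitMean mean of the truncated-Poisson (minimum 1) visit count.
#' @slot visitSpacing years between consecutive assessments; visit times are
#'   0, -spacing, -2 spacing, ... (0 = MRI date).
#' @slot seed integer.
#' @export
setClass("CohortGenSpec", representation(
  nParticipants = "integer", ageRange = "numeric", sexProb = "numeric",
  raceProbs = "numeric", edyMeanSd = "numeric", qmriAgeModel = "list",
  cognitionDriver = "character", cognitionBetas = "numeric",
  randomInterceptSd = "numeric", residualSd = "numeric",
  visitMean = "numeric", visitSpacing = "numeric", seed = "integer"))

setValidity("CohortGenSpec", function(object) {
  msgs <- character()
  if (object@nParticipants < 2L) msgs <- c(msgs, "nParticipants must be >= 2")
  if (abs(sum(object@raceProbs) - 1) > 1e-8)
    msgs <- c(msgs, "raceProbs must sum to 1")
  if (object@sexProb < 0 || object@sexProb > 1)
    msgs <- c(msgs, "sexProb must be a probability")
  if (object@randomInterceptSd < 0 || object@residualSd < 0)
    msgs <- c(msgs, "residual SDs must be >= 0")
  if (any(vapply(object@qmriAgeModel, function(m) m$sd < 0, logical(1))))
    msgs <- c(msgs, "qmriAgeModel residual SDs must be >= 0")
  if (!(object@cognitionDriver %in% names(object@qmriAgeModel)))
    msgs <- c(msgs, "cognitionDriver must name a qmriAgeModel metric")
  need <- c("intercept", "age", "sex", "raceBlack", "raceOther", "edy", "time",
            "qmri", "ageTime", "qmriAge", "qmriTime", "qmriTimeAge")
  if (!all(need %in% names(object@cognitionBetas)))
    msgs <- c(msgs, paste("cognitionBetas must name:",
                          paste(need, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @param nParticipants,ageRange,sexProb,raceProbs,edyMeanSd,qmriAgeModel,cognitionDriver,cognitionBetas,randomInterceptSd,residualSd,visitMean,visitSpacing,seed
#'   see slots.
#' @return A \code{CohortGenSpec}.
#' @examples
#' spec <- CohortGenSpec(nParticipants = 50)
#' @rdname CohortGenSpec-class
#' @export
CohortGenSpec <- function(nParticipants = 120L, ageRange = c(22, 94),
                          sexProb = 0.533,
                          raceProbs = c(White = 0.683, Black = 0.192, Other = 0.125),
                          edyMeanSd = c(16.3, 2.7),
                          qmriAgeModel = list(
                            lcR1 = list(intercept = 1.05, age = 0, age2 = -5e-5, sd = 0.05),
                            lcR2 = list(intercept = 14.5, age = -0.015, age2 = 0, sd = 0.6),
                            lcMwf = list(intercept = 0.08, age = 0, age2 = 0, sd = 0.02),
                            rostralR2 = list(intercept = 15.0, age = -0.02, age2 = 0, sd = 0.6),
                            caudalR2 = list(intercept = 14.0, age = -0.008, age2 = 0, sd = 0.6)),
                          cognitionDriver = "rostralR2",
                          cognitionBetas = c(intercept = 0.2, age = -0.015,
                                             sex = 0.1, raceBlack = -0.05,
                                             raceOther = 0, edy = 0.02,
                                             time = -0.03, qmri = 0.3,
                                             ageTime = -0.002, qmriAge = 0.005,
                                             qmriTime = 0.05, qmriTimeAge = 0.003),
                          randomInterceptSd = 0.5, residualSd = 0.3,
                          visitMean = 3, visitSpacing = 1.5, seed = 1L) {
  new("CohortGenSpec", nParticipants = as.integer(nParticipants),
      ageRange = ageRange, sexProb = sexProb, raceProbs = raceProbs,
      edyMeanSd = edyMeanSd, qmriAgeModel = qmriAgeModel,
      cognitionDriver = cognitionDriver, cognitionBetas = cognitionBetas,
      randomInterceptSd = randomInterceptSd, residualSd = residualSd,
      visitMean = visitMean, visitSpacing = visitSpacing,
      seed = as.integer(seed))
}

setMethod("show", "CohortGenSpec", function(object) {
  cat(sprintf("CohortGenSpec: n = %d, ages %g-%g, %d qMRI metrics, driver %s\n",
              object@nParticipants, object@ageRange[1], object@ageRange[2],
              length(object@qmriAgeModel), object@cognitionDriver))
})

## ---------------------------------------------------------------------------
## BmcConfig
## ---------------------------------------------------------------------------

#' Configuration of the Bayesian Monte-Carlo MWF estimator
#'
#' Uniform prior bounds and sampling budget for posterior-mean estimation of
#' the two-pool model. Default bounds follow the multicomponent relaxometry
#' literature: MWF [0, 0.4], short T1 [150, 600] ms, long T1 [600, 2500] ms,
#' short T2 [5, 40] ms, long T2 [40, 150] ms, off-resonance within the bSSFP
#' band +/- 1/(2 TR).
#'
#' @slot nSamples integer >= 100 (default 1e5).
#' @slot priorBounds named list of c(lo, hi): \code{mwf, t1Short, t1Long,
#'   t2Short, t2Long, offResonance}.
#' @slot noiseSigmaMode "fixed" or "estimated" (from the best-sample residual).
#' @slot sigma numeric, noise SD on mean-normalised signals (used when fixed).
#' @slot proposal "adaptive" (optimisation-localised mixture proposal,
#'   default) or "prior" (flat proposal equal to the prior).
#' @slot nStarts integer, optimisation starts for the adaptive proposal.
#' @slot seed integer.
#' @export
setClass("BmcConfig", representation(
  nSamples = "integer", priorBounds = "list", noiseSigmaMode = "character",
  sigma = "numeric", proposal = "character", nStarts = "integer",
  seed = "integer"))

setValidity("BmcConfig", function(object) {
  msgs <- character()
  if (object@nSamples < 100L) msgs <- c(msgs, "nSamples must be >= 100")
  need <- c("mwf", "t1Short", "t1Long", "t2Short", "t2Long", "offResonance")
  if (!all(need %in% names(object@priorBounds)))
    msgs <- c(msgs, paste("priorBounds must name:", paste(need, collapse = ", ")))
  else {
    pb <- object@priorBounds
    if (any(vapply(pb, function(b) b[2] <= b[1], logical(1))))
      msgs <- c(msgs, "each prior bound must satisfy hi > lo")
    if (pb$t1Short[2] > pb$t1Long[1] || pb$t2Short[2] > pb$t2Long[1])
      msgs <- c(msgs, "short-pool ranges must lie entirely below long-pool ranges")
  }
  if (!(object@noiseSigmaMode %in% c("fixed", "estimated")))
    msgs <- c(msgs, "noiseSigmaMode must be 'fixed' or 'estimated'")
  if (!(object@proposal %in% c("adaptive", "prior")))
    msgs <- c(msgs, "proposal must be 'adaptive' or 'prior'")
  if (object@nStarts < 1L) msgs <- c(msgs, "nStarts must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' @param nSamples,priorBounds,noiseSigmaMode,sigma,proposal,nStarts,seed see
#'   slots.
#' @param trMs bSSFP TR in ms, used for the default off-resonance bound.
#' @return A \code{BmcConfig}.
#' @examples
#' BmcConfig(nSamples = 1000)
#' @rdname BmcConfig-class
#' @export
BmcConfig <- function(nSamples = 1e5, trMs = 5.9,
                      priorBounds = list(
                        mwf = c(0, 0.4), t1Short = c(150, 600),
                        t1Long = c(600, 2500), t2Short = c(5, 40),
                        t2Long = c(40, 150),
                        offResonance = c(-500 / trMs, 500 / trMs)),
                      noiseSigmaMode = "estimated", sigma = 0.01,
                      proposal = "adaptive", nStarts = 10L, seed = 1L) {
  new("BmcConfig", nSamples = as.integer(nSamples), priorBounds = priorBounds,
      noiseSigmaMode = noiseSigmaMode, sigma = sigma, proposal = proposal,
      nStarts = as.integer(nStarts), seed = as.integer(seed))
}

setMethod("show", "BmcConfig", function(object) {
  cat(sprintf("BmcConfig: %d samples, sigma %s (%g), MWF prior [%g, %g]\n",
              object@nSamples, object@noiseSigmaMode, object@sigma,
              object@priorBounds$mwf[1], object@priorBounds$mwf[2]))
})

## ---------------------------------------------------------------------------
## ModelFit / FdrResult
## ---------------------------------------------------------------------------

#' Fitted statistical model summary
#'
#' Uniform container for the OLS and mixed-model fits: a coefficient table
#' (estimate, SE, p per term), the model family tag, sample size, convergence
#' status and (for mixed models) variance components.
#'
#' @slot coefficients data.frame with columns \code{term}, \code{estimate},
#'   \code{se}, \code{p}.
#' @slot family character tag ("linear_age", "quadratic_age",
#'   "cross_sectional", "longitudinal").
#' @slot n integer observations used.
#' @slot converged logical.
#' @slot varcomp list; mixed models report \code{randomInterceptSd} and
#'   \code{residualSd}.
#' @slot fit the underlying \code{lm}/\code{lmerMod} object.
#' @export
setClass("ModelFit", representation(
  coefficients = "data.frame", family = "character", n = "integer",
  converged = "logical", varcomp = "list", fit = "ANY"))

setValidity("ModelFit", function(object) {
  cf <- object@coefficients
  msgs <- character()
  if (!all(c("term", "estimate", "se", "p") %in% names(cf)))
    msgs <- c(msgs, "coefficients must have term/estimate/se/p columns")
  if (any(cf$se <= 0, na.rm = TRUE)) msgs <- c(msgs, "SEs must be > 0")
  if (any(cf$p <= 0 | cf$p > 1, na.rm = TRUE))
    msgs <- c(msgs, "p-values must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit [%s], n = %d%s\n", object@family, object@n,
              if (object@converged) "" else " (NOT converged)"))
  print(object@coefficients, digits = 4, row.names = FALSE)
  if (length(object@varcomp))
    cat(sprintf("  random intercept SD %.4g, residual SD %.4g\n",
                object@varcomp$randomInterceptSd, object@varcomp$residualSd))
})

#' Benjamini-Hochberg FDR correction result
#'
#' @slot table data.frame with columns \code{p}, \code{pAdj},
#'   \code{rejected}, in the input order.
#' @slot q the FDR level.
#' @slot family character, description of the test family corrected together.
#' @export
setClass("FdrResult", representation(
  table = "data.frame", q = "numeric", family = "character"))

setMethod("show", "FdrResult", function(object) {
  cat(sprintf("FdrResult: %d tests, q = %g, %d rejected (family: %s)\n",
              nrow(object@table), object@q, sum(object@table$rejected),
              object@family))
})
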