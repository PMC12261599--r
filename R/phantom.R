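## Synthetic LC phantom: two parallel circular cylinders aligned with the
## rostro-caudal grid axis, with tube parameters linearly interpolated along
## that axis, and simulated acquisitions of the full protocol.

#' Generate the bilateral LC phantom
#'
#' Builds a per-voxel \code{\link{TissueParameters}} volume and the matching
#' binary mask from a \code{\link{PhantomSpec}}. Voxels whose centre falls
#' inside one of the two analytic cylinders carry tube parameters linearly
#' interpolated along the rostro-caudal axis between \code{lcParamsRostral}
#' (interpolation weight 0 at the rostral tube end) and \code{lcParamsCaudal}
#' (weight 1 at the caudal end); all other voxels carry
#' \code{backgroundParams}. The tubes are centred along the axis; an error
#' names the offending dimension if a tube would not fit in the grid.
#'
#' @param spec a \code{\link{PhantomSpec}}.
#' @return list with elements \code{params} (a \code{TissueParameters} volume)
#'   and \code{mask} (an \code{\link{LcMask}} of exactly the tube voxels).
#' @examples
#' ph <- generatePhantom(PhantomSpec())
#' sum(ph$mask@mask)
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  gs <- spec@gridShape; vs <- spec@voxelSize
  ax <- spec@rostrocaudalAxis
  lateral <- setdiff(1:3, ax)
  extent <- gs * vs

  ## tube must fit: axially and laterally (centre offsets +/- radius)
  if (spec@lcLength > extent[ax])
    stop(sprintf("LC tube (%.1f mm) exceeds the grid along axis %d (%.1f mm)",
                 spec@lcLength, ax, extent[ax]), call. = FALSE)
  rad <- spec@lcThickness / 2
  halfW <- extent[lateral[1]] / 2
  if (any(abs(spec@lcCenterOffsets) + rad > halfW))
    stop(sprintf("LC tube exceeds the grid along axis %d (lateral)", lateral[1]),
         call. = FALSE)
  if (rad > extent[lateral[2]] / 2)
    stop(sprintf("LC tube exceeds the grid along axis %d (lateral)", lateral[2]),
         call. = FALSE)

  ## voxel-centre coordinates per axis (mm)
  coords <- lapply(1:3, function(k) voxelCentres(gs[k], vs))
  idx <- arrayInd(seq_len(prod(gs)), gs)
  x1 <- coords[[lateral[1]]][idx[, lateral[1]]]   # offset axis
  x2 <- coords[[lateral[2]]][idx[, lateral[2]]]
  z  <- coords[[ax]][idx[, ax]]

  z0 <- (extent[ax] - spec@lcLength) / 2          # tube start, mm
  inAxial <- z >= z0 & z < z0 + spec@lcLength
  c2 <- extent[lateral[2]] / 2
  inTube <- rep(FALSE, prod(gs))
  for (off in spec@lcCenterOffsets) {
    c1 <- extent[lateral[1]] / 2 + off
    inTube <- inTube | (inAxial & ((x1 - c1)^2 + (x2 - c2)^2 <= rad^2))
  }
  if (!any(inTube)) stop("phantom mask is empty; check spec geometry",
                         call. = FALSE)

  ## rostro-caudal interpolation weight: 0 at the rostral tube end, 1 caudal
  tFrac <- (z - z0) / spec@lcLength
  if (spec@rostralDirection == -1L) tFrac <- 1 - tFrac
  tFrac <- pmin(pmax(tFrac, 0), 1)

  fields <- c("m0", "t1", "t2", "mwf", "t1Short", "t1Long", "t2Short",
              "t2Long", "offResonance", "b1Scale")
  vals <- lapply(fields, function(nm) {
    bg <- slot(spec@backgroundParams, nm)
    ro <- slot(spec@lcParamsRostral, nm)
    ca <- slot(spec@lcParamsCaudal, nm)
    v <- rep(bg, prod(gs))
    v[inTube] <- ro + tFrac[inTube] * (ca - ro)   # exact when ca == ro
    v
  })
  names(vals) <- fields
  params <- do.call(TissueParameters, c(vals, list(dim = gs)))
  mask <- LcMask(inTube, dim = gs, voxelSize = vs,
                 rostrocaudalAxis = ax, rostralDirection = spec@rostralDirection)
  list(params = params, mask = mask)
}

#' Simulate the multi-flip-angle acquisitions of a parameter volume
#'
#' Evaluates the forward models of the protocol for every voxel and flip
#' angle, applying the voxel's B1 scale (optionally overridden by an explicit
#' B1 field), then adds acquisition noise. The default noise model is additive
#' Gaussian on magnitude signals (the high-SNR limit of Rician noise, which
#' keeps the ratio-based estimators unbiased); \code{noiseModel = "rician"}
#' applies the full Rician model
#' \eqn{\sqrt{(S + n_1)^2 + n_2^2}}, \eqn{n_i \sim N(0, \sigma^2)}. With
#' \code{noiseSd = 0} the stacks equal the forward model exactly, and the same
#' seed reproduces bit-identical stacks.
#'
#' @param params a \code{\link{TissueParameters}} volume (or scalar voxel).
#' @param protocol an \code{\link{AcquisitionProtocol}}; its \code{noiseSd} is
#'   the noise SD in signal units.
#' @param seed integer seed for the noise draws.
#' @param model "single" (use the single-pool t1/t2 fields) or "two"
#'   (two-pool mixture via \code{\link{twoComponentSignal}}).
#' @param b1Field optional numeric vector/array of per-voxel flip-angle scales
#'   multiplying \code{params@b1Scale}; must match the volume shape.
#' @param noiseModel "gaussian" or "rician".
#' @param voxelSize voxel size in mm recorded in the stack geometry.
#' @return A \code{\link{SignalStackSet}}.
#' @examples
#' ph <- generatePhantom(PhantomSpec(gridShape = c(8, 8, 12)))
#' st <- simulateAcquisition(ph$params, AcquisitionProtocol(), seed = 1)
#' @export
simulateAcquisition <- function(params, protocol = AcquisitionProtocol(),
                                seed = 1L, model = c("single", "two"),
                                b1Field = NULL,
                                noiseModel = c("gaussian", "rician"),
                                voxelSize = 1) {
  model <- match.arg(model)
  noiseModel <- match.arg(noiseModel)
  stopIfNot(protocol@noiseSd >= 0, "noise SD must be >= 0")
  nv <- nVoxels(params)
  if (!is.null(b1Field)) {
    if (length(b1Field) != nv)
      stop(sprintf("B1 field has %d voxels but the parameter volume has %d",
                   length(b1Field), nv), call. = FALSE)
    params@b1Scale <- recycleField(params@b1Scale, nv) * as.numeric(b1Field)
  }
  if (model == "two") {
    stacks <- twoComponentSignal(params, protocol, voxelSize = voxelSize)
  } else {
    spgr <- spgrSignal(params, protocol@spgrFlipAngles, protocol@spgrTeTr)
    nCyc <- length(protocol@bssfpPhaseIncrements)
    bssfp <- array(0, c(nv, length(protocol@bssfpFlipAngles), nCyc))
    for (ci in seq_len(nCyc))
      bssfp[, , ci] <- bssfpSignal(params, protocol@bssfpFlipAngles,
                                   protocol@bssfpPhaseIncrements[ci],
                                   protocol@bssfpTeTr)
    dam <- damSignalPair(params, protocol@damFlipAngles)
    gdim <- if (length(params@dim) == 3L) params@dim else c(1L, 1L, 1L)
    stacks <- new("SignalStackSet", spgr = spgr, bssfp = bssfp, dam = dam,
                  dim = gdim, voxelSize = rep(voxelSize, length.out = 3),
                  protocol = protocol)
  }
  sdN <- protocol@noiseSd
  if (sdN > 0) {
    withSeed(seed, {
      addNoise <- function(s) {
        if (noiseModel == "gaussian")
          pmax(s + rnorm(length(s), 0, sdN), 0)
        else
          sqrt((s + rnorm(length(s), 0, sdN))^2 + rnorm(length(s), 0, sdN)^2)
      }
      stacks@spgr[] <- addNoise(stacks@spgr)
      stacks@bssfp[] <- addNoise(stacks@bssfp)
      stacks@dam[] <- addNoise(stacks@dam)
    })
  }
  validObject(stacks)
  stacks
}
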