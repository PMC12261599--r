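## Sampling of qMRI maps within the LC mask: rostro-caudal slice profiles,
## percentile-based subregion splits, and the sensitivity-analysis masks
## (dilated shell, lateral shifts).

## Slice indices along the rostro-caudal axis ordered rostral -> caudal.
.slicesRostralOrder <- function(mask) {
  arr <- array(mask@mask, mask@dim)
  counts <- apply(arr, mask@rostrocaudalAxis, sum)
  slices <- which(counts > 0)
  if (mask@rostralDirection == -1L) slices <- rev(slices)
  slices
}

#' Rostro-caudal slice profile of qMRI metrics within a mask
#'
#' For every slice along the mask's rostro-caudal axis that intersects the
#' mask, computes the mean of each metric over mask voxels with ok fit
#' status. Slices are ordered rostral to caudal and slice k of n (k = 0 most
#' rostral) gets the midpoint percentile \eqn{100 (k + 0.5)/n}. A slice whose
#' mask voxels all failed yields NA means and is recorded as such.
#'
#' @param maps a \code{\link{QmriMapSet}}.
#' @param mask an \code{\link{LcMask}} on the same grid.
#' @return A \code{\link{SliceProfile}}.
#' @examples
#' ph <- generatePhantom(PhantomSpec())
#' sliceProfile(asQmriMapSet(ph$params, 0.5), ph$mask)
#' @export
sliceProfile <- function(maps, mask) {
  if (!identical(maps@dim, mask@dim))
    stop("maps and mask are on different grids", call. = FALSE)
  if (!any(mask@mask)) stop("empty mask", call. = FALSE)
  ax <- mask@rostrocaudalAxis
  slices <- .slicesRostralOrder(mask)
  n <- length(slices)
  idx <- arrayInd(seq_len(prod(mask@dim)), mask@dim)
  axIdx <- idx[, ax]
  ok <- maps@status == "ok"
  rows <- lapply(seq_along(slices), function(k) {
    inSlice <- mask@mask & axIdx == slices[k]
    sel <- inSlice & ok
    mn <- function(x) if (any(sel)) mean(x[sel]) else NA_real_
    data.frame(slice = slices[k], percentile = 100 * (k - 0.5) / n,
               nVoxels = sum(inSlice), nOk = sum(sel),
               r1 = mn(maps@r1), r2 = mn(maps@r2), mwf = mn(maps@mwf))
  })
  new("SliceProfile", profile = do.call(rbind, rows),
      rostrocaudalAxis = mask@rostrocaudalAxis,
      rostralDirection = mask@rostralDirection)
}

#' Split a slice profile into rostro-caudal subregions
#'
#' Assigns slices with midpoint percentile < \code{cut} (default 66) to the
#' rostral-middle subregion and the rest to the caudal subregion, and computes
#' voxel-count-weighted metric means per subregion plus the whole-LC mean (so
#' the whole-LC mean is exactly the weighted combination of the subregion
#' means). The finer bands used for slice-level age effects -- rostral
#' (percentile < 44) and restricted caudal (>= 86) -- are reported as well.
#' A subregion with no slices (e.g. a single-slice profile has no caudal
#' slices) gets NA means and zero counts.
#'
#' @param profile a \code{\link{SliceProfile}}.
#' @param cut main percentile cut (default 66).
#' @param finerCuts numeric(2), the rostral and restricted-caudal cuts
#'   (default c(44, 86)).
#' @return A \code{\link{SubregionSummary}}.
#' @export
splitSubregions <- function(profile, cut = 66, finerCuts = c(44, 86)) {
  pf <- profile@profile
  stopIfNot(nrow(pf) > 0, "empty profile")
  summarise <- function(sel, region) {
    sub <- pf[sel, , drop = FALSE]
    res <- lapply(c("r1", "r2", "mwf"), function(m) {
      w <- sub$nOk; v <- sub[[m]]
      use <- w > 0 & !is.na(v)
      data.frame(region = region, metric = m,
                 mean = if (any(use)) sum(w[use] * v[use]) / sum(w[use])
                        else NA_real_,
                 nVoxels = sum(w[use]), nSlices = nrow(sub))
    })
    do.call(rbind, res)
  }
  out <- rbind(
    summarise(rep(TRUE, nrow(pf)), "wholeLC"),
    summarise(pf$percentile < cut, "rostralMiddle"),
    summarise(pf$percentile >= cut, "caudal"),
    summarise(pf$percentile < finerCuts[1], "rostral"),
    summarise(pf$percentile >= finerCuts[2], "restrictedCaudal"))
  new("SubregionSummary", summary = out)
}

## Shift a logical volume by one voxel along `axis` in direction `dir`
## (+1/-1), zero-filling at the border.
.shiftLogical <- function(arr, axis, dir) {
  d <- dim(arr)
  out <- array(FALSE, d)
  src <- dst <- lapply(d, seq_len)
  if (dir > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  if (d[axis] < 2) return(out)
  out_idx <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(arr), src, list(drop = FALSE))))))
  out_idx
}

#' Dilated shell mask for the sensitivity analysis
#'
#' Morphological dilation of the mask by \code{radius} iterations of the
#' 6-connected (face-neighbour) structuring element, minus the original mask.
#' The shell is therefore always disjoint from the original ROI. Dilation is
#' clipped at the grid boundary with a warning when the dilated set touches
#' it.
#'
#' @param mask an \code{\link{LcMask}}.
#' @param radius integer >= 1, number of dilation iterations (default 3).
#' @return An \code{\link{LcMask}} of the shell, inheriting the axis
#'   convention.
#' @export
dilatedShellMask <- function(mask, radius = 3) {
  stopIfNot(radius >= 1, "radius must be >= 1")
  arr <- array(mask@mask, mask@dim)
  dil <- arr
  for (i in seq_len(radius)) {
    grown <- dil
    for (axis in 1:3) for (dir in c(-1, 1))
      grown <- grown | .shiftLogical(dil, axis, dir)
    dil <- grown
  }
  border <- array(FALSE, mask@dim)
  for (axis in 1:3) {
    ix <- lapply(mask@dim, seq_len)
    ix[[axis]] <- c(1L, mask@dim[axis])
    border <- do.call(`[<-`, c(list(border), ix, list(TRUE)))
  }
  if (any(dil & border))
    warning("dilation reaches the grid boundary; shell clipped")
  shell <- dil & !arr
  LcMask(as.logical(shell), dim = mask@dim, voxelSize = mask@voxelSize,
         rostrocaudalAxis = mask@rostrocaudalAxis,
         rostralDirection = mask@rostralDirection,
         diagnostics = list(radius = radius, nShell = sum(shell)))
}

#' Laterally shifted mask for the sensitivity analysis
#'
#' Translates the mask by a signed number of millimetres along a lateral grid
#' axis (the shift must be an integer number of voxels on the mask grid,
#' otherwise an error instructs resampling first). Voxels of the shifted mask
#' that overlap the original are removed and counted in the diagnostics, so
#' the returned mask never overlaps the original ROI; voxels shifted outside
#' the grid are dropped.
#'
#' @param mask an \code{\link{LcMask}}.
#' @param shiftMm signed shift in mm (e.g. +/- 1.5).
#' @param axis grid axis along which to shift (default 1, left-right).
#' @return An \code{\link{LcMask}} with \code{diagnostics$nOverlapRemoved} and
#'   \code{diagnostics$nOutOfGrid}.
#' @export
shiftedMask <- function(mask, shiftMm, axis = 1L) {
  vs <- mask@voxelSize[axis]
  nv <- shiftMm / vs
  if (abs(nv - round(nv)) > 1e-8)
    stop(sprintf(paste("shift of %g mm is not an integer number of voxels",
                       "(voxel size %g mm); resample the mask first"),
                 shiftMm, vs), call. = FALSE)
  nv <- as.integer(round(nv))
  arr <- array(mask@mask, mask@dim)
  shifted <- arr
  for (i in seq_len(abs(nv)))
    shifted <- .shiftLogical(shifted, axis, sign(nv))
  nOut <- sum(arr) - sum(shifted)
  overlap <- shifted & arr
  shifted <- shifted & !arr
  LcMask(as.logical(shifted), dim = mask@dim, voxelSize = mask@voxelSize,
         rostrocaudalAxis = mask@rostrocaudalAxis,
         rostralDirection = mask@rostralDirection,
         diagnostics = list(shiftMm = shiftMm, axis = axis,
                            nOverlapRemoved = sum(overlap),
                            nOutOfGrid = nOut))
}

#' Whole-mask metric means over ok voxels
#'
#' Convenience sampler: the mean of each metric over ok-status voxels of a
#' mask, as used for whole-LC, shell and shifted-mask summaries.
#'
#' @param maps a \code{\link{QmriMapSet}}.
#' @param mask an \code{\link{LcMask}} on the same grid.
#' @return named numeric: r1, r2, mwf (NA when no ok voxel), plus nOk.
#' @export
maskMeans <- function(maps, mask) {
  if (!identical(maps@dim, mask@dim))
    stop("maps and mask are on different grids", call. = FALSE)
  sel <- mask@mask & maps@status == "ok"
  if (!any(sel))
    stop("no ok-status voxels inside the mask; nothing to average",
         call. = FALSE)
  c(r1 = mean(maps@r1[sel]), r2 = mean(maps@r2[sel]),
    mwf = mean(maps@mwf[sel]), nOk = sum(sel))
}
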