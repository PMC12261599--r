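## Voxel-wise estimation of kappa (double-angle method), T1 (DESPOT1) and T2
## (DESPOT2) from the signal stacks. DESPOT1 and the DAM inversion are fully
## vectorised across voxels; the joint two-cycle DESPOT2 solves a bounded 1-2
## parameter least-squares problem per voxel with the amplitude profiled
## analytically.

#' Double-angle B1 inversion
#'
#' Recovers the flip-angle scale \eqn{\kappa} from a fast-spin-echo pair
#' acquired at \eqn{\alpha} and \eqn{2\alpha}:
#' \eqn{\kappa = \arccos(\mathrm{clamp}(S_2 / 2 S_1, -1, 1)) / \alpha}.
#' Clamping (a noise ratio outside the arccos domain) is recorded in the
#' status; zero first-angle signal yields an undefined voxel rather than a
#' crash.
#'
#' @param s1,s2 numeric vectors of signals at the nominal angle and at twice
#'   the nominal angle.
#' @param nominalAngle nominal first angle, degrees.
#' @return list with \code{kappa} (NA where undefined) and \code{status}
#'   ("ok", "clamped", "undefined") per voxel.
#' @examples
#' fitDamB1(sin(pi / 4), sin(pi / 2), 45)  # kappa = 1
#' @export
fitDamB1 <- function(s1, s2, nominalAngle = 45) {
  status <- rep("ok", length(s1))
  kappa <- rep(NA_real_, length(s1))
  bad <- !(s1 > 0) | is.na(s1) | is.na(s2)
  status[bad] <- "undefined"
  ratio <- s2[!bad] / (2 * s1[!bad])
  clamped <- ratio < -1 | ratio > 1
  status[!bad][clamped] <- "clamped"
  kappa[!bad] <- acos(pmin(pmax(ratio, -1), 1)) / (nominalAngle * DEG2RAD)
  list(kappa = kappa, status = status)
}

#' Estimate a B1 map from the DAM stack of a SignalStackSet
#'
#' @param stacks a \code{\link{SignalStackSet}}.
#' @return A \code{\link{B1Map}} on the stack grid.
#' @export
fitDamB1Map <- function(stacks) {
  f <- fitDamB1(stacks@dam[, 1], stacks@dam[, 2],
                stacks@protocol@damFlipAngles[1])
  B1Map(kappa = ifelse(is.na(f$kappa), 0, f$kappa),
        dim = stacks@dim, voxelSize = stacks@voxelSize,
        defined = f$status != "undefined", interpolated = FALSE)
}

#' Trilinear interpolation of a B1 map onto a target grid
#'
#' Resamples a (typically low-resolution) kappa field onto the map grid by
#' trilinear interpolation of voxel centres, with nearest-edge extension
#' outside the source centre lattice. Both grids are assumed to share their
#' corner origin. Constant fields map to constant fields and affine fields are
#' reproduced exactly at interior points.
#'
#' @param b1 a \code{\link{B1Map}}.
#' @param targetDim integer(3) target grid shape.
#' @param targetVoxelSize numeric voxel size of the target grid, mm (recycled
#'   to length 3).
#' @return A \code{\link{B1Map}} on the target grid with
#'   \code{interpolated = TRUE}.
#' @export
interpolateB1 <- function(b1, targetDim, targetVoxelSize) {
  targetVoxelSize <- rep(targetVoxelSize, length.out = 3)
  srcExtent <- b1@dim * b1@voxelSize
  tgtExtent <- targetDim * targetVoxelSize
  if (any(pmin(srcExtent, tgtExtent) <= 0) ||
      all(targetVoxelSize * 0.5 > srcExtent))
    stop("disjoint grids: target does not overlap the B1 field", call. = FALSE)
  if (identical(as.integer(targetDim), b1@dim) &&
      isTRUE(all.equal(targetVoxelSize, b1@voxelSize))) {
    out <- b1; out@interpolated <- TRUE
    return(out)
  }
  src <- array(b1@kappa, b1@dim)
  n <- as.integer(targetDim)
  idx <- arrayInd(seq_len(prod(n)), n)
  ## fractional source index of each target voxel centre
  u <- lapply(1:3, function(k) {
    x <- voxelCentres(n[k], targetVoxelSize[k])
    pmin(pmax(x / b1@voxelSize[k] - 0.5, 0), b1@dim[k] - 1)
  })
  i0 <- lapply(1:3, function(k) pmin(floor(u[[k]][idx[, k]]), b1@dim[k] - 2))
  i0 <- lapply(1:3, function(k) pmax(i0[[k]], 0))
  fr <- lapply(1:3, function(k) u[[k]][idx[, k]] - i0[[k]])
  ## handle degenerate single-slice source axes
  for (k in 1:3) if (b1@dim[k] == 1L) { i0[[k]][] <- 0; fr[[k]][] <- 0 }
  gather <- function(dx, dy, dz) {
    ii <- pmin(i0[[1]] + dx, b1@dim[1] - 1)
    jj <- pmin(i0[[2]] + dy, b1@dim[2] - 1)
    kk <- pmin(i0[[3]] + dz, b1@dim[3] - 1)
    src[1 + ii + b1@dim[1] * (jj + b1@dim[2] * kk)]
  }
  w <- function(f, d) if (d == 0) 1 - f else f
  out <- numeric(prod(n))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    out <- out + w(fr[[1]], dx) * w(fr[[2]], dy) * w(fr[[3]], dz) *
      gather(dx, dy, dz)
  B1Map(kappa = out, dim = n, voxelSize = targetVoxelSize,
        defined = rep(TRUE, prod(n)), interpolated = TRUE)
}

#' DESPOT1: linearised variable-flip-angle T1 estimation
#'
#' Ordinary (unweighted) least squares on the linearised SPGR model:
#' \eqn{S/\sin(\kappa\alpha) = E_1 \, S/\tan(\kappa\alpha) + M_0(1 - E_1)},
#' so the slope is \eqn{E_1 = \exp(-TR/T_1)} and the intercept gives
#' \eqn{M_0}. A slope outside (0, 1) or a degenerate design yields a failed
#' status, never a crash. Vectorised across voxels.
#'
#' @param spgr numeric vector (one voxel) or matrix (voxels x angles) of SPGR
#'   signals.
#' @param protocol an \code{\link{AcquisitionProtocol}}.
#' @param kappa per-voxel flip-angle scale (recycled).
#' @return list of per-voxel vectors: \code{t1} (ms), \code{m0},
#'   \code{status} ("ok", "failed", "degenerate"), \code{resNorm}.
#' @examples
#' p <- TissueParameters(t1 = 1000, m0 = 500)
#' s <- spgrSignal(p, AcquisitionProtocol()@spgrFlipAngles)
#' fitDespot1(s, AcquisitionProtocol())$t1
#' @export
fitDespot1 <- function(spgr, protocol = AcquisitionProtocol(), kappa = 1) {
  if (is.null(dim(spgr))) spgr <- matrix(spgr, nrow = 1)
  angles <- protocol@spgrFlipAngles
  stopIfNot(ncol(spgr) == length(angles) && length(angles) >= 2,
            "need >= 2 flip angles matching the protocol")
  nVox <- nrow(spgr)
  kappa <- recycleField(kappa, nVox)
  stopIfNot(all(kappa > 0 | is.na(kappa)), "kappa must be > 0")
  tr <- protocol@spgrTeTr[2]
  a <- outer(kappa, angles * DEG2RAD)     # voxels x angles
  y <- spgr / sin(a)
  x <- spgr / tan(a)
  nA <- length(angles)
  mx <- rowMeans(x); my <- rowMeans(y)
  sxx <- rowMeans(x * x) - mx^2
  sxy <- rowMeans(x * y) - mx * my
  status <- rep("ok", nVox)
  degen <- !is.finite(sxx) | sxx < .Machine$double.eps * pmax(mx^2, 1)
  slope <- ifelse(degen, NA_real_, sxy / sxx)
  icpt <- my - slope * mx
  bad <- !degen & (!is.finite(slope) | slope <= 0 | slope >= 1)
  status[degen] <- "degenerate"
  status[bad] <- "failed"
  t1 <- rep(NA_real_, nVox); m0 <- rep(NA_real_, nVox)
  ok <- status == "ok"
  t1[ok] <- -tr / log(slope[ok])
  m0[ok] <- icpt[ok] / (1 - slope[ok])
  res <- y - (slope * x + icpt)
  resNorm <- sqrt(rowMeans(res^2) * nA)
  resNorm[!ok] <- NA_real_
  list(t1 = t1, m0 = m0, status = status, resNorm = resNorm)
}

## Unit-amplitude two-cycle bSSFP model for one voxel, concatenated over
## cycles; used by the joint DESPOT2 objective.
.bssfpModelVec <- function(t1, t2, offHz, protocol, kappa) {
  unlist(lapply(protocol@bssfpPhaseIncrements, function(dphi)
    .bssfp(1, t1, t2, offHz, protocol@bssfpFlipAngles, dphi,
           protocol@bssfpTeTr[1], protocol@bssfpTeTr[2], kappa)))
}

#' DESPOT2: T2 estimation from phase-cycled bSSFP given T1
#'
#' Default path ("joint"): bounded nonlinear least squares over both phase
#' cycles for (T2, off-resonance) with the amplitude profiled analytically,
#' multi-started at three off-resonance seeds to avoid the periodic bSSFP
#' ambiguity; bounds T2 in (1, 500] ms, off-resonance within +/- 1/(2 TR).
#' Alternate path ("linearized"): classic single-cycle DESPOT2 on the pi
#' cycle, \eqn{S/\sin = m\, S/\tan + b} with
#' \eqn{m = (E_1 - E_2)/(1 - E_1 E_2)}, hence
#' \eqn{E_2 = (E_1 - m)/(1 - m E_1)}; exact on resonance, biased off
#' resonance. The two paths agree on-resonance.
#'
#' @param bssfp numeric matrix (angles x cycles) for one voxel, or 3-D array
#'   (voxels x angles x cycles).
#' @param protocol an \code{\link{AcquisitionProtocol}}.
#' @param kappa flip-angle scale (per voxel, recycled).
#' @param t1 T1 in ms from \code{\link{fitDespot1}} (per voxel, recycled).
#' @param path "joint" or "linearized".
#' @return list of per-voxel vectors: \code{t2} (ms), \code{m0},
#'   \code{offResonance} (Hz; 0 for the linearised path), \code{status},
#'   \code{resNorm}.
#' @export
fitDespot2 <- function(bssfp, protocol = AcquisitionProtocol(), kappa = 1,
                       t1, path = c("joint", "linearized")) {
  path <- match.arg(path)
  if (length(dim(bssfp)) == 2L)
    bssfp <- array(bssfp, c(1L, dim(bssfp)))
  nVox <- dim(bssfp)[1]
  angles <- protocol@bssfpFlipAngles
  stopIfNot(dim(bssfp)[2] == length(angles) && length(angles) >= 2,
            "need >= 2 flip angles matching the protocol")
  kappa <- recycleField(kappa, nVox)
  t1 <- recycleField(t1, nVox)
  tr <- protocol@bssfpTeTr[2]
  if (path == "linearized") return(.despot2Linear(bssfp, protocol, kappa, t1))

  fmax <- 1000 / (2 * tr)               # Hz
  lin <- .despot2Linear(bssfp, protocol, kappa, t1)
  t2v <- numeric(nVox); m0v <- numeric(nVox); dfv <- numeric(nVox)
  status <- rep("ok", nVox); resNorm <- numeric(nVox)
  for (v in seq_len(nVox)) {
    dat <- as.numeric(bssfp[v, , ])
    if (all(dat == 0) || any(!is.finite(dat)) || !is.finite(t1[v])) {
      status[v] <- "failed"; t2v[v] <- NA; m0v[v] <- NA; dfv[v] <- NA
      next
    }
    obj <- function(par) {
      mod <- .bssfpModelVec(t1[v], par[1], par[2], protocol, kappa[v])
      mm <- sum(mod * mod)
      if (mm == 0) return(sum(dat^2))
      sum(dat^2) - sum(mod * dat)^2 / mm
    }
    t2start <- if (is.finite(lin$t2[v]) && lin$t2[v] > 1 && lin$t2[v] <= 500)
      lin$t2[v] else 80
    best <- NULL
    for (df0 in c(-0.6, 0, 0.6) * fmax) {
      o <- tryCatch(
        optim(c(t2start, df0), obj, method = "L-BFGS-B",
              lower = c(1.0001, -fmax), upper = c(500, fmax),
              control = list(factr = 1e7, maxit = 500)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) {
      status[v] <- "non-converged"; t2v[v] <- NA; m0v[v] <- NA; dfv[v] <- NA
      next
    }
    if (best$convergence != 0) {
      ## L-BFGS can stop with a line-search code at a machine-precision
      ## minimum; restart once and accept if the objective is stationary
      o <- tryCatch(
        optim(best$par, obj, method = "L-BFGS-B",
              lower = c(1.0001, -fmax), upper = c(500, fmax),
              control = list(factr = 1e7, maxit = 500)),
        error = function(e) best)
      stationary <- (best$value - o$value) <= 1e-10 * sum(dat^2)
      if (o$value < best$value) best <- o
      if (!(stationary || best$convergence == 0))
        status[v] <- "non-converged"
    }
    mod <- .bssfpModelVec(t1[v], best$par[1], best$par[2], protocol, kappa[v])
    m0v[v] <- sum(mod * dat) / sum(mod * mod)
    t2v[v] <- best$par[1]; dfv[v] <- best$par[2]
    resNorm[v] <- sqrt(max(best$value, 0))
  }
  list(t2 = t2v, m0 = m0v, offResonance = dfv, status = status,
       resNorm = resNorm)
}

## Linearised single-cycle DESPOT2 on the pi phase cycle, vectorised.
.despot2Linear <- function(bssfp, protocol, kappa, t1) {
  cyc <- which.min(abs(protocol@bssfpPhaseIncrements - pi))
  if (abs(protocol@bssfpPhaseIncrements[cyc] - pi) > 1e-6)
    stop("linearized DESPOT2 requires a pi phase-cycle in the protocol",
         call. = FALSE)
  s <- bssfp[, , cyc, drop = FALSE]; dim(s) <- dim(bssfp)[1:2]
  angles <- protocol@bssfpFlipAngles
  tr <- protocol@bssfpTeTr[2]
  nVox <- nrow(s)
  a <- outer(kappa, angles * DEG2RAD)
  y <- s / sin(a); x <- s / tan(a)
  mx <- rowMeans(x); my <- rowMeans(y)
  sxx <- rowMeans(x * x) - mx^2
  sxy <- rowMeans(x * y) - mx * my
  status <- rep("ok", nVox)
  degen <- !is.finite(sxx) | sxx < .Machine$double.eps * pmax(mx^2, 1)
  m <- ifelse(degen, NA_real_, sxy / sxx)
  b <- my - m * mx
  e1 <- exp(-tr / t1)
  e2 <- (e1 - m) / (1 - m * e1)
  bad <- !degen & (!is.finite(e2) | e2 <= 0 | e2 >= 1)
  status[degen] <- "degenerate"; status[bad] <- "failed"
  ok <- status == "ok"
  t2 <- rep(NA_real_, nVox); m0 <- rep(NA_real_, nVox)
  t2[ok] <- -tr / log(e2[ok])
  m0[ok] <- b[ok] * (1 - e1[ok] * e2[ok]) / (1 - e1[ok])
  res <- y - (m * x + b)
  resNorm <- sqrt(rowMeans(res^2) * length(angles))
  resNorm[!ok] <- NA_real_
  list(t2 = t2, m0 = m0, offResonance = rep(0, nVox), status = status,
       resNorm = resNorm)
}

#' Voxel-wise relaxometry of a whole signal stack
#'
#' Applies \code{\link{fitDespot1}} and \code{\link{fitDespot2}} (and
#' optionally the Bayesian Monte-Carlo MWF estimator) to every voxel (or to a
#' mask subset), producing co-registered R1/R2/MWF maps with per-voxel status
#' codes. Voxels are fitted independently, so results do not depend on
#' processing order or on which other voxels are present. Failed voxels carry
#' their status and NA estimates; they are excluded from ROI summaries
#' downstream.
#'
#' @param stacks a \code{\link{SignalStackSet}}.
#' @param b1 a \code{\link{B1Map}} on the same grid (default: constant 1).
#' @param mask optional \code{\link{LcMask}} or logical vector restricting the
#'   fit; unfitted voxels get status "failed" and NA maps.
#' @param despot2Path "joint" or "linearized" (see \code{\link{fitDespot2}}).
#' @param estimateMwf logical; run \code{\link{fitMwf}} per voxel (slow;
#'   typically used on mask voxels only).
#' @param bmcConfig a \code{\link{BmcConfig}} when \code{estimateMwf} is TRUE.
#' @return A \code{\link{QmriMapSet}} (rates in 1/s).
#' @export
fitVolume <- function(stacks, b1 = NULL, mask = NULL,
                      despot2Path = c("joint", "linearized"),
                      estimateMwf = FALSE, bmcConfig = NULL) {
  despot2Path <- match.arg(despot2Path)
  nVox <- prod(stacks@dim)
  if (is.null(b1)) {
    kappa <- rep(1, nVox); kdef <- rep(TRUE, nVox)
  } else {
    if (!identical(b1@dim, stacks@dim))
      stop("grid mismatch between B1 map and signal stacks", call. = FALSE)
    kappa <- b1@kappa; kdef <- b1@defined
  }
  sel <- if (is.null(mask)) rep(TRUE, nVox) else {
    m <- if (is(mask, "LcMask")) {
      if (!identical(mask@dim, stacks@dim))
        stop("grid mismatch between mask and signal stacks", call. = FALSE)
      mask@mask
    } else as.logical(mask)
    stopIfNot(length(m) == nVox, "mask length must equal the voxel count")
    m
  }
  sel <- sel & kdef & kappa > 0
  r1 <- r2 <- mwf <- m0 <- resNorm <- rep(NA_real_, nVox)
  status <- rep("failed", nVox)
  if (any(sel)) {
    d1 <- fitDespot1(stacks@spgr[sel, , drop = FALSE], stacks@protocol,
                     kappa[sel])
    d2 <- fitDespot2(stacks@bssfp[sel, , , drop = FALSE], stacks@protocol,
                     kappa[sel], d1$t1, path = despot2Path)
    st <- ifelse(d1$status == "ok", d2$status, d1$status)
    r1[sel] <- 1000 / d1$t1
    r2[sel] <- 1000 / d2$t2
    m0[sel] <- d1$m0
    resNorm[sel] <- sqrt(ifelse(is.na(d1$resNorm), 0, d1$resNorm)^2 +
                           ifelse(is.na(d2$resNorm), 0, d2$resNorm)^2)
    status[sel] <- st
    if (estimateMwf) {
      if (is.null(bmcConfig)) bmcConfig <- BmcConfig()
      widx <- which(sel)
      for (v in widx) {
        fm <- fitMwf(list(spgr = stacks@spgr[v, ],
                          bssfp = stacks@bssfp[v, , ]),
                     stacks@protocol, kappa[v], bmcConfig)
        mwf[v] <- fm$mwf
      }
    }
  }
  ## invalidate rate estimates on non-ok voxels so the map invariants hold
  bad <- status != "ok"
  r1[bad] <- NA_real_; r2[bad] <- NA_real_
  QmriMapSet(r1 = r1, r2 = r2, mwf = mwf, m0 = m0, status = status,
             resNorm = ifelse(is.na(resNorm), 0, resNorm),
             dim = stacks@dim, voxelSize = stacks@voxelSize)
}
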