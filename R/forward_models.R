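## Steady-state signal models. All public functions take flip angles in
## degrees; conversion to radians happens once, here. Internal workhorses
## (.spgr, .bssfp, .dam) operate on plain numeric vectors with recycling so
## that phantom volumes and Monte-Carlo parameter samples evaluate in a single
## vectorised pass.

## SPGR steady state: S = M0 (1 - E1) sin(k a) / (1 - E1 cos(k a)).
## TE decay is a pure scale common to all flip angles and is folded into M0.
.spgr <- function(m0, t1, alphaDeg, trMs, kappa = 1) {
  a <- kappa * alphaDeg * DEG2RAD
  e1 <- exp(-trMs / t1)
  m0 * (1 - e1) * sin(a) / (1 - e1 * cos(a))
}

## bSSFP steady state from the 3x3 linear fixed point of one TR's propagation
## M = Rz(beta) E Rx(k a) M + (1 - E1) M0 z, solved in closed form via
## Cramer's rule. beta = 2 pi df TR - dphi (sign convention documented in the
## vignette). The magnitude is evaluated at TE: transverse decay exp(-TE/T2)
## applies; precession up to TE changes only the phase, not the magnitude.
.bssfp <- function(m0, t1, t2, offHz, alphaDeg, dphi, teMs, trMs, kappa = 1) {
  a <- kappa * alphaDeg * DEG2RAD
  ca <- cos(a); sa <- sin(a)
  e1 <- exp(-trMs / t1); e2 <- exp(-trMs / t2)
  beta <- 2 * pi * offHz * trMs / 1000 - dphi
  cb <- cos(beta); sb <- sin(beta)
  ## A = I - Rz(beta) diag(E2,E2,E1) Rx(a)
  a11 <- 1 - cb * e2; a12 <- sb * e2 * ca; a13 <- -sb * e2 * sa
  a21 <- -sb * e2;    a22 <- 1 - cb * e2 * ca; a23 <- cb * e2 * sa
  a32 <- -e1 * sa;    a33 <- 1 - e1 * ca
  c31 <- a12 * a23 - a13 * a22
  c32 <- -(a11 * a23 - a13 * a21)
  c33 <- a11 * a22 - a12 * a21
  det <- a32 * c32 + a33 * c33          # a31 = 0
  if (any(abs(det) < 1e-300))
    stop("singular bSSFP fixed-point system (pathological parameters)")
  bz <- (1 - e1) * m0
  mx <- c31 * bz / det
  my <- c32 * bz / det
  mz <- c33 * bz / det
  ## after-pulse magnetisation: Rx(a) applied to the pre-pulse steady state
  myp <- ca * my - sa * mz
  exp(-teMs / t2) * sqrt(mx^2 + myp^2)
}

## Ideal double-angle fast-spin-echo pair (long-TR limit: full T1 recovery
## between excitations): (c sin(k a), c sin(2 k a)) for a common scale c.
.dam <- function(m0, alphaDeg, kappa = 1) {
  a <- kappa * alphaDeg * DEG2RAD
  cbind(abs(m0 * sin(a)), abs(m0 * sin(2 * a)))
}

#' SPGR steady-state signal
#'
#' Noiseless spoiled gradient-echo magnitude
#' \eqn{S = M_0 (1 - E_1)\sin(\kappa\alpha)/(1 - E_1\cos(\kappa\alpha))} with
#' \eqn{E_1 = \exp(-TR/T_1)}. TE decay is a constant factor across flip angles
#' and is absorbed into \eqn{M_0}; it cancels from all ratio-based estimators.
#'
#' @param params a \code{\link{TissueParameters}} object (single-pool fields
#'   \code{m0}, \code{t1}, \code{b1Scale} are used).
#' @param flipAngles nominal flip angles, degrees, each in (0, 90].
#' @param teTr numeric(2) TE/TR in ms.
#' @return numeric matrix, voxels x flip angles.
#' @examples
#' spgrSignal(TissueParameters(t1 = 1000), flipAngles = c(5, 10), teTr = c(1.48, 5))
#' @export
spgrSignal <- function(params, flipAngles, teTr = c(1.48, 5)) {
  stopIfNot(all(flipAngles > 0) && all(flipAngles <= 90),
            "flip angles must lie in (0, 90] degrees")
  nv <- nVoxels(params)
  vapplyAngles(flipAngles, function(a)
    .spgr(params@m0, params@t1, a, teTr[2], params@b1Scale), nv)
}

#' Phase-cycled bSSFP steady-state signal
#'
#' Magnitude of the balanced steady-state free-precession signal, obtained in
#' closed form from the 3x3 linear fixed point of one TR's propagation
#' (rotation by \eqn{\kappa\alpha}, free precession by
#' \eqn{\beta = 2\pi \Delta f \, TR - \Delta\phi}, relaxation
#' \eqn{E_1, E_2}), evaluated at TE with transverse decay applied. When the
#' effective per-TR precession is \eqn{\pi} this reduces to the classic
#' on-resonance form
#' \eqn{S = M_0 \sin\alpha (1 - E_1) / (1 - (E_1 - E_2)\cos\alpha - E_1 E_2)}
#' up to the TE-decay factor.
#'
#' @param params a \code{\link{TissueParameters}} object (single-pool fields).
#' @param flipAngles nominal flip angles, degrees, in (0, 180).
#' @param phaseIncrement RF phase increment, radians.
#' @param teTr numeric(2) TE/TR in ms.
#' @return numeric matrix, voxels x flip angles.
#' @examples
#' bssfpSignal(TissueParameters(), flipAngles = c(16, 32), phaseIncrement = pi)
#' @export
bssfpSignal <- function(params, flipAngles, phaseIncrement = pi,
                        teTr = c(2.8, 5.9)) {
  stopIfNot(all(flipAngles > 0) && all(flipAngles < 180),
            "flip angles must lie in (0, 180) degrees")
  nv <- nVoxels(params)
  vapplyAngles(flipAngles, function(a)
    .bssfp(params@m0, params@t1, params@t2, params@offResonance, a,
           phaseIncrement, teTr[1], teTr[2], params@b1Scale), nv)
}

#' Double-angle fast-spin-echo signal pair
#'
#' Long-TR fast-spin-echo pair \eqn{(c\sin(\kappa\alpha), c\sin(2\kappa\alpha))}
#' used for B1 mapping; T1 recovery is assumed complete between excitations so
#' the common scale c carries no flip-angle dependence.
#'
#' @param params a \code{\link{TissueParameters}} object.
#' @param damAngles numeric(2), nominal angles; the second must equal twice the
#'   first.
#' @return numeric matrix, voxels x 2.
#' @examples
#' damSignalPair(TissueParameters(), c(45, 90))
#' @export
damSignalPair <- function(params, damAngles = c(45, 90)) {
  stopIfNot(length(damAngles) == 2 && abs(damAngles[2] - 2 * damAngles[1]) < 1e-9,
            "damAngles must satisfy the double-angle relation (alpha, 2 alpha)")
  s <- .dam(params@m0, damAngles[1], params@b1Scale)
  if (nrow(s) == 1L && nVoxels(params) > 1L)
    s <- s[rep(1L, nVoxels(params)), , drop = FALSE]
  s
}

#' Two-component (non-exchanging) signal stacks for one protocol
#'
#' Evaluates every sequence of the protocol under the two-pool non-exchanging
#' model: each signal is \code{mwf} times the single-component signal with the
#' short-pool T1/T2 plus \code{1 - mwf} times the long-pool signal; both pools
#' share M0, off-resonance and the B1 scale.
#'
#' @param params a \code{\link{TissueParameters}} object with the two-pool
#'   fields set.
#' @param protocol an \code{\link{AcquisitionProtocol}}.
#' @param voxelSize voxel size in mm (geometry bookkeeping for the stack).
#' @return A \code{\link{SignalStackSet}} (dim c(1,1,1) for a scalar voxel).
#' @examples
#' st <- twoComponentSignal(TissueParameters(mwf = 0.15, t1Long = 1000,
#'                                           t2Long = 80), AcquisitionProtocol())
#' @export
twoComponentSignal <- function(params, protocol = AcquisitionProtocol(),
                               voxelSize = 1) {
  stopIfNot(all(params@mwf >= 0 & params@mwf <= 1), "mwf must lie in [0, 1]")
  nv <- nVoxels(params)
  short <- TissueParameters(m0 = params@m0, t1 = params@t1Short,
                            t2 = params@t2Short,
                            t1Short = params@t1Short, t1Long = params@t1Short + 1,
                            t2Short = params@t2Short, t2Long = params@t2Short + 1,
                            offResonance = params@offResonance,
                            b1Scale = params@b1Scale, dim = params@dim)
  long <- TissueParameters(m0 = params@m0, t1 = params@t1Long,
                           t2 = params@t2Long,
                           t1Short = params@t1Long - 1, t1Long = params@t1Long,
                           t2Short = params@t2Long - 1, t2Long = params@t2Long,
                           offResonance = params@offResonance,
                           b1Scale = params@b1Scale, dim = params@dim)
  f <- recycleField(params@mwf, nv)
  mix <- function(a, b) f * a + (1 - f) * b
  spgr <- mix(spgrSignal(short, protocol@spgrFlipAngles, protocol@spgrTeTr),
              spgrSignal(long, protocol@spgrFlipAngles, protocol@spgrTeTr))
  nCyc <- length(protocol@bssfpPhaseIncrements)
  bssfp <- array(0, c(nv, length(protocol@bssfpFlipAngles), nCyc))
  for (ci in seq_len(nCyc))
    bssfp[, , ci] <- mix(
      bssfpSignal(short, protocol@bssfpFlipAngles,
                  protocol@bssfpPhaseIncrements[ci], protocol@bssfpTeTr),
      bssfpSignal(long, protocol@bssfpFlipAngles,
                  protocol@bssfpPhaseIncrements[ci], protocol@bssfpTeTr))
  dam <- mix(damSignalPair(short, protocol@damFlipAngles),
             damSignalPair(long, protocol@damFlipAngles))
  gdim <- if (length(params@dim) == 3L) params@dim else c(1L, 1L, 1L)
  new("SignalStackSet", spgr = spgr, bssfp = bssfp, dam = dam,
      dim = gdim, voxelSize = rep(voxelSize, length.out = 3),
      protocol = protocol)
}

## Evaluate a per-angle closure over a flip-angle list into a voxels x angles
## matrix.
vapplyAngles <- function(angles, f, nVox) {
  out <- matrix(0, nVox, length(angles))
  for (j in seq_along(angles)) out[, j] <- f(angles[j])
  out
}
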