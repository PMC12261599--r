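pr <- AcquisitionProtocol()

test_that("double-angle inversion recovers kappa and flags degeneracies", {
  f <- fitDamB1(sin(pi / 4), sin(pi / 2), 45)
  expect_equal(f$kappa, 1, tolerance = 1e-6)
  expect_equal(f$status, "ok")

  ## equal signals: ratio 1/2, arccos = 60 deg, kappa = 60/45
  f2 <- fitDamB1(1, 1, 45)
  expect_equal(f2$kappa, 60 / 45, tolerance = 1e-12)

  ## noise ratio beyond the arccos domain clamps to kappa = 0 and is flagged
  f3 <- fitDamB1(1, 2.5, 45)
  expect_equal(f3$kappa, 0)
  expect_equal(f3$status, "clamped")

  f4 <- fitDamB1(c(0, 1), c(0.1, 1.2), 45)
  expect_equal(f4$status[1], "undefined")
  expect_true(is.na(f4$kappa[1]))

  ## round trip through the forward model at several kappas
  for (k in c(0.7, 1, 1.25)) {
    s <- damSignalPair(TissueParameters(b1Scale = k), c(45, 90))
    expect_equal(fitDamB1(s[1, 1], s[1, 2], 45)$kappa, k, tolerance = 1e-10)
  }
})

test_that("B1 interpolation preserves constants and affine fields", {
  src <- B1Map(rep(1.1, 4 * 4 * 4), dim = c(4, 4, 4), voxelSize = 2)
  out <- interpolateB1(src, c(8, 8, 8), 1)
  expect_true(all(abs(out@kappa - 1.1) < 1e-12))
  expect_true(out@interpolated)

  ## affine ramp along x reproduced exactly at interior target points
  idx <- arrayInd(1:64, c(4, 4, 4))
  x <- (idx[, 1] - 0.5) * 2
  ramp <- B1Map(0.9 + 0.01 * x, dim = c(4, 4, 4), voxelSize = 2)
  tgt <- interpolateB1(ramp, c(8, 8, 8), 1)
  ti <- arrayInd(1:512, c(8, 8, 8))
  tx <- (ti[, 1] - 0.5) * 1
  interior <- tx >= 1 & tx <= 7 &
    ti[, 2] >= 2 & ti[, 2] <= 7 & ti[, 3] >= 2 & ti[, 3] <= 7
  expect_true(all(abs(tgt@kappa[interior] - (0.9 + 0.01 * tx[interior])) < 1e-12))

  ## identity when target equals source
  same <- interpolateB1(ramp, c(4, 4, 4), 2)
  expect_equal(same@kappa, ramp@kappa)
})

test_that("DESPOT1 recovers T1 and M0 from noiseless SPGR", {
  p <- TissueParameters(t1 = 1000, m0 = 500)
  s <- spgrSignal(p, pr@spgrFlipAngles, pr@spgrTeTr)
  f <- fitDespot1(s, pr)
  expect_lt(abs(f$t1 - 1000) / 1000, 1e-6)
  expect_lt(abs(f$m0 - 500) / 500, 1e-6)
  expect_equal(f$status, "ok")

  ## correct kappa gives identical recovery; forcing kappa = 1 on data
  ## acquired at kappa = 0.8 biases T1 (why DAM mapping matters)
  p8 <- TissueParameters(t1 = 1000, m0 = 500, b1Scale = 0.8)
  s8 <- spgrSignal(p8, pr@spgrFlipAngles, pr@spgrTeTr)
  fGood <- fitDespot1(s8, pr, kappa = 0.8)
  fBad <- fitDespot1(s8, pr, kappa = 1)
  expect_lt(abs(fGood$t1 - 1000) / 1000, 1e-6)
  expect_gt(abs(fBad$t1 - 1000) / 1000, 0.2)

  ## two exact points determine the line exactly
  pr2 <- AcquisitionProtocol(spgrFlipAngles = c(4, 18))
  s2 <- spgrSignal(p, c(4, 18), pr2@spgrTeTr)
  f2 <- fitDespot1(s2, pr2)
  expect_lt(abs(f2$t1 - 1000) / 1000, 1e-9)

  ## degenerate input never crashes
  fz <- fitDespot1(rep(0, 10), pr)
  expect_true(fz$status %in% c("degenerate", "failed"))
  expect_true(is.na(fz$t1))
})

test_that("DESPOT2 paths recover T2 and agree on resonance", {
  mkStack <- function(t1, t2, df = 0, m0 = 500) {
    p <- TissueParameters(t1 = t1, t2 = t2, m0 = m0, offResonance = df)
    bs <- array(0, c(1, length(pr@bssfpFlipAngles), 2))
    for (ci in 1:2)
      bs[1, , ci] <- bssfpSignal(p, pr@bssfpFlipAngles,
                                 pr@bssfpPhaseIncrements[ci], pr@bssfpTeTr)
    bs
  }
  bs <- mkStack(1000, 80)
  lin <- fitDespot2(bs, pr, 1, 1000, path = "linearized")
  expect_lt(abs(lin$t2 - 80) / 80, 1e-6)
  joint <- fitDespot2(bs, pr, 1, 1000, path = "joint")
  expect_lt(abs(joint$t2 - 80) / 80, 1e-4)

  ## off-resonance: joint path recovers T2 and |df| (magnitude data cannot
  ## distinguish the precession sign); linearised path is biased
  bs20 <- mkStack(1000, 80, df = 20)
  j20 <- fitDespot2(bs20, pr, 1, 1000, path = "joint")
  expect_lt(abs(j20$t2 - 80) / 80, 1e-3)
  expect_lt(abs(abs(j20$offResonance) - 20) / 20, 1e-3)
  l20 <- fitDespot2(bs20, pr, 1, 1000, path = "linearized")
  expect_gt(abs(l20$t2 - 80) / 80, 0.01)

  ## T1 = T2 makes E2 = E1: the linearised slope on the pi cycle is zero
  bsEq <- mkStack(500, 500)
  s <- bsEq[1, , 2]
  a <- pr@bssfpFlipAngles * pi / 180
  slope <- coef(lm(I(s / sin(a)) ~ I(s / tan(a))))[2]
  expect_lt(abs(slope), 1e-10)
})

test_that("volume fitting round-trips the phantom and is voxel-independent", {
  spec <- PhantomSpec(gridShape = c(12, 12, 18), lcLength = 6,
                      lcCenterOffsets = c(-1.5, 1.5))
  ph <- generatePhantom(spec)
  stacks <- simulateAcquisition(ph$params, pr, seed = 1,
                                voxelSize = spec@voxelSize)
  maps <- fitVolume(stacks, despot2Path = "linearized")
  nv <- prod(spec@gridShape)
  tpT1 <- rep(ph$params@t1, length.out = nv)
  tpT2 <- rep(ph$params@t2, length.out = nv)
  ok <- maps@status == "ok"
  expect_true(all(ok))
  expect_lt(max(abs(1000 / maps@r1 - tpT1) / tpT1), 1e-3)
  expect_lt(max(abs(1000 / maps@r2 - tpT2) / tpT2), 1e-3)

  ## restricting to a 10-voxel mask reproduces the whole-volume values
  sel <- rep(FALSE, nv); sel[which(ph$mask@mask)[1:10]] <- TRUE
  sub <- fitVolume(stacks, mask = sel, despot2Path = "linearized")
  expect_equal(sub@r1[sel], maps@r1[sel], tolerance = 1e-12)
  expect_equal(sub@r2[sel], maps@r2[sel], tolerance = 1e-12)
  expect_true(all(sub@status[!sel] == "failed"))

  ## all-zero input: every voxel fails, ROI means refuse to average
  zero <- stacks
  zero@spgr[] <- 0; zero@bssfp[] <- 0; zero@dam[] <- 0
  mz <- fitVolume(zero, despot2Path = "linearized")
  expect_true(all(mz@status != "ok"))
  expect_error(maskMeans(mz, ph$mask), "no ok-status voxels")
})

test_that("DESPOT1 is unbiased under Gaussian noise at high SNR", {
  ## one voxel, many noise realisations, fitted in a single vectorised call
  p <- TissueParameters(t1 = 1000, m0 = 500)
  s <- as.numeric(spgrSignal(p, pr@spgrFlipAngles, pr@spgrTeTr))
  snr <- 200
  sigma <- max(s) / snr
  set.seed(99)
  n <- 10000
  noisy <- matrix(rep(s, each = n), n) +
    matrix(rnorm(n * length(s), 0, sigma), n)
  f <- fitDespot1(noisy, pr)
  ok <- f$status == "ok"
  expect_gt(mean(ok), 0.99)
  bias <- mean(f$t1[ok]) - 1000
  mcErr <- sd(f$t1[ok]) / sqrt(sum(ok))
  expect_lt(abs(bias), 4 * mcErr + 1)   # unbiased within Monte-Carlo error
})
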