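## A small rectangular mask on a 6x6xN grid for controlled profiles.
barMask <- function(nSlices, dim = c(6L, 6L, as.integer(nSlices) + 2L),
                    rostralDirection = 1L) {
  arr <- array(FALSE, dim)
  arr[3:4, 3:4, 2:(nSlices + 1)] <- TRUE
  LcMask(as.logical(arr), dim = dim, voxelSize = 1,
         rostrocaudalAxis = 3L, rostralDirection = rostralDirection)
}

constMaps <- function(dim, r1 = 1, r2 = 14, mwf = 0.1) {
  nv <- prod(dim)
  QmriMapSet(r1 = rep(r1, nv), r2 = rep(r2, nv), mwf = rep(mwf, nv),
             m0 = rep(1, nv), status = rep("ok", nv), resNorm = rep(0, nv),
             dim = dim, voxelSize = c(1, 1, 1))
}

test_that("slice profiles follow the midpoint percentile rule", {
  m <- barMask(1)
  prof <- sliceProfile(constMaps(m@dim), m)
  expect_equal(nrow(prof@profile), 1L)
  expect_equal(prof@profile$percentile, 50)

  m9 <- barMask(9)
  p9 <- sliceProfile(constMaps(m9@dim), m9)
  expect_equal(p9@profile$percentile, 100 * (0:8 + 0.5) / 9)

  ## constant maps give constant slice means
  expect_true(all(p9@profile$r2 == 14))
  expect_true(all(p9@profile$nVoxels == 4))

  ## empty mask errors
  empty <- LcMask(rep(FALSE, prod(m@dim)), m@dim, 1)
  expect_error(sliceProfile(constMaps(m@dim), empty), "empty mask")
})

test_that("subregion splits match hand enumeration for 1..12 slices", {
  ## midpoint percentile < 66 -> rostral-middle; >= 66 -> caudal
  handCounts <- function(n) {
    pct <- 100 * (seq_len(n) - 0.5) / n
    c(sum(pct < 66), sum(pct >= 66))
  }
  for (n in 1:12) {
    m <- barMask(n)
    subs <- splitSubregions(sliceProfile(constMaps(m@dim), m))
    s <- subs@summary
    got <- c(s$nSlices[s$region == "rostralMiddle" & s$metric == "r1"],
             s$nSlices[s$region == "caudal" & s$metric == "r1"])
    expect_equal(got, handCounts(n), info = sprintf("n = %d", n))
  }
  ## the worked cases: 9 slices -> 6 + 3, 3 slices -> 2 + 1
  expect_equal(handCounts(9), c(6, 3))
  expect_equal(handCounts(3), c(2, 1))

  ## single slice: caudal subregion empty, flagged by NA mean
  s1 <- splitSubregions(sliceProfile(constMaps(barMask(1)@dim), barMask(1)))
  cau <- s1@summary[s1@summary$region == "caudal", ]
  expect_true(all(is.na(cau$mean)))
  expect_true(all(cau$nVoxels == 0))
})

test_that("subregion means reconstruct the whole-LC mean exactly", {
  set.seed(8)
  m <- barMask(11)
  nv <- prod(m@dim)
  maps <- QmriMapSet(r1 = runif(nv, 0.8, 1.2), r2 = runif(nv, 12, 16),
                     mwf = runif(nv, 0, 0.3), m0 = rep(1, nv),
                     status = rep("ok", nv), resNorm = rep(0, nv),
                     dim = m@dim, voxelSize = c(1, 1, 1))
  subs <- splitSubregions(sliceProfile(maps, m))@summary
  for (metric in c("r1", "r2", "mwf")) {
    s <- subs[subs$metric == metric, ]
    whole <- s$mean[s$region == "wholeLC"]
    parts <- s[s$region %in% c("rostralMiddle", "caudal"), ]
    recon <- sum(parts$mean * parts$nVoxels) / sum(parts$nVoxels)
    expect_lt(abs(recon - whole), 1e-12)
    ## and the direct voxel mean agrees
    expect_lt(abs(whole - mean(slot(maps, metric)[m@mask])), 1e-12)
  }
})

test_that("profiles are equivariant under flipping the rostral direction", {
  set.seed(3)
  m <- barMask(8)
  nv <- prod(m@dim)
  maps <- QmriMapSet(r1 = runif(nv), r2 = runif(nv), mwf = runif(nv),
                     m0 = rep(1, nv), status = rep("ok", nv),
                     resNorm = rep(0, nv), dim = m@dim, voxelSize = c(1, 1, 1))
  fwd <- sliceProfile(maps, m)@profile
  rev <- sliceProfile(maps, barMask(8, rostralDirection = -1L))@profile
  expect_equal(rev$r2, base::rev(fwd$r2))
  expect_equal(rev$percentile, 100 - base::rev(fwd$percentile))
})

test_that("dilated shell masks are disjoint 6-connected shells", {
  dim <- c(7L, 7L, 7L)
  arr <- array(FALSE, dim); arr[4, 4, 4] <- TRUE
  m <- LcMask(as.logical(arr), dim, 1)
  shell <- dilatedShellMask(m, 1)
  expect_equal(sum(shell@mask), 6L)          # face neighbours only
  expect_false(any(shell@mask & m@mask))
  ## radius 2: all voxels with Manhattan distance in {1, 2}
  shell2 <- dilatedShellMask(m, 2)
  idx <- arrayInd(seq_len(prod(dim)), dim)
  manh <- rowSums(abs(idx - matrix(4, nrow(idx), 3)))
  expect_equal(which(shell2@mask), which(manh >= 1 & manh <= 2))

  expect_error(dilatedShellMask(m, 0), "radius")
  ## dilation running into the grid edge warns
  expect_warning(dilatedShellMask(m, 4), "boundary")
})

test_that("shifted masks translate, stay disjoint and report overlap", {
  dim <- c(12L, 6L, 6L)
  arr <- array(FALSE, dim); arr[5:6, 3:4, 2:5] <- TRUE
  m <- LcMask(as.logical(arr), dim, voxelSize = 0.5)

  ## 1.5 mm = 3 voxels; a 2-voxel-wide mask lands disjoint from itself
  sh <- shiftedMask(m, 1.5, axis = 1)
  expect_equal(sum(sh@mask), sum(m@mask))
  expect_false(any(sh@mask & m@mask))
  expect_equal(sh@diagnostics$nOverlapRemoved, 0)

  ## shifting back recovers the original mask
  back <- shiftedMask(sh, -1.5, axis = 1)
  expect_equal(back@mask, m@mask)

  ## non-integer voxel shifts are rejected with advice
  expect_error(shiftedMask(m, 0.7, axis = 1), "resample")

  ## a whole-grid mask: the overlap is stripped and counted
  full <- LcMask(rep(TRUE, prod(dim)), dim, voxelSize = 0.5)
  shF <- shiftedMask(full, 1.5, axis = 1)
  expect_false(any(shF@mask & full@mask))
  expect_gt(shF@diagnostics$nOverlapRemoved, 0)
})

test_that("shell and shifted masks dilute a contrast confined to the LC", {
  ## phantom whose LC differs from background only in R2
  bg <- TissueParameters(m0 = 100, t1 = 1200, t2 = 80, mwf = 0.15,
                         t1Long = 1300, t2Long = 90)
  lcR <- TissueParameters(m0 = 100, t1 = 1200, t2 = 55, mwf = 0.15,
                          t1Long = 1300, t2Long = 90)
  spec <- PhantomSpec(backgroundParams = bg, lcParamsRostral = lcR,
                      lcParamsCaudal = lcR)
  ph <- generatePhantom(spec)
  maps <- asQmriMapSet(ph$params, spec@voxelSize)
  lcMean <- maskMeans(maps, ph$mask)["r2"]
  shellMean <- maskMeans(maps, dilatedShellMask(ph$mask, 3))["r2"]
  leftMean <- maskMeans(maps, shiftedMask(ph$mask, -1.5))["r2"]
  bgR2 <- 1000 / 80
  expect_gt(abs(lcMean - bgR2), 3)           # LC carries the contrast
  expect_lt(abs(shellMean - bgR2), 1e-9)     # surrounding tissue does not
  expect_lt(abs(leftMean - bgR2), 1e-9)
})
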