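test_that("phantom geometry matches its specification", {
  ph <- generatePhantom(PhantomSpec())
  ## a 14.5 mm tube sampled at 0.5 mm spans 29 slices
  arr <- array(ph$mask@mask, ph$mask@dim)
  expect_equal(sum(apply(arr, 3, any)), 29)
  expect_gt(sum(ph$mask@mask), 0)

  ## two bilateral tubes: every slice has voxels on both sides of the centre
  midX <- PhantomSpec()@gridShape[1] / 2
  idx <- arrayInd(which(ph$mask@mask), ph$mask@dim)
  expect_true(any(idx[, 1] <= midX) && any(idx[, 1] > midX))

  ## tube exceeding the grid errors naming the axis
  expect_error(generatePhantom(PhantomSpec(gridShape = c(24, 24, 20))),
               "axis 3")
  expect_error(generatePhantom(PhantomSpec(lcCenterOffsets = c(-8, 8))),
               "axis 1")
})

test_that("phantom parameters interpolate along the rostro-caudal axis", {
  ## degenerate constant gradient: every mask voxel identical
  lc <- TissueParameters(t1 = 900, t2 = 60, mwf = 0.1, t1Long = 1000,
                         t2Long = 70, m0 = 100)
  ph <- generatePhantom(PhantomSpec(lcParamsRostral = lc, lcParamsCaudal = lc))
  inside <- ph$mask@mask
  expect_equal(length(unique(ph$params@t1[inside])), 1L)
  expect_equal(unique(ph$params@mwf[inside]), 0.1)

  ## a rostral > caudal MWF gradient gives a monotone non-increasing profile
  ph2 <- generatePhantom(PhantomSpec())
  prof <- sliceProfile(asQmriMapSet(ph2$params, 0.5), ph2$mask)
  expect_true(all(diff(prof@profile$mwf) <= 1e-12))

  ## mask equals the set of voxels whose parameters differ from background
  differs <- ph2$params@t1 != PhantomSpec()@backgroundParams@t1
  expect_equal(which(differs), which(ph2$mask@mask))

  ## flipping the rostral direction mirrors the gradient direction
  ph3 <- generatePhantom(PhantomSpec(rostralDirection = -1L))
  prof3 <- sliceProfile(asQmriMapSet(ph3$params, 0.5), ph3$mask)
  expect_true(all(diff(prof3@profile$mwf) <= 1e-12))  # still rostral -> caudal
  arr3 <- array(ph3$params@mwf, ph3$mask@dim)
  arr2 <- array(ph2$params@mwf, ph2$mask@dim)
  ## along the raw grid axis the two gradients run in opposite directions
  m2 <- apply(array(ph2$mask@mask, ph2$mask@dim), 3, any)
  s2 <- apply(arr2, 3, mean)[m2]
  s3 <- apply(arr3, 3, mean)[m2]
  expect_true(all(diff(s2) <= 1e-12) && all(diff(s3) >= -1e-12))
})

test_that("acquisition simulation is exact when noiseless and seeded when not", {
  pr <- AcquisitionProtocol()
  p <- TissueParameters(t1 = 1000, t2 = 80, m0 = 100)
  st <- simulateAcquisition(p, pr, seed = 1)
  expect_equal(st@spgr[1, ],
               as.numeric(spgrSignal(p, pr@spgrFlipAngles, pr@spgrTeTr)),
               tolerance = 1e-14)
  expect_equal(st@bssfp[1, , 2],
               as.numeric(bssfpSignal(p, pr@bssfpFlipAngles, pi, pr@bssfpTeTr)),
               tolerance = 1e-14)

  prN <- AcquisitionProtocol(noiseSd = 0.5)
  a <- simulateAcquisition(p, prN, seed = 42)
  b <- simulateAcquisition(p, prN, seed = 42)
  expect_identical(a@spgr, b@spgr)
  expect_identical(a@bssfp, b@bssfp)
  c2 <- simulateAcquisition(p, prN, seed = 43)
  expect_false(identical(a@spgr, c2@spgr))

  ## B1-field shape mismatch errors
  expect_error(simulateAcquisition(p, pr, seed = 1, b1Field = c(1, 1)),
               "B1 field")
})

test_that("the injected noise has the requested standard deviation", {
  ## 10,000 copies of one voxel; per-angle sample SD within 10% of sigma
  ## m0 large enough that no magnitude signal is clipped at zero
  pv <- TissueParameters(t1 = 1000, t2 = 80, m0 = 2000, dim = c(25L, 20L, 20L))
  sigma <- 1.5
  prN <- AcquisitionProtocol(noiseSd = sigma)
  st <- simulateAcquisition(pv, prN, seed = 7)
  sds <- apply(st@spgr, 2, sd)
  expect_true(all(abs(sds - sigma) / sigma < 0.1))
  sdsB <- apply(st@bssfp[, , 2], 2, sd)   # pi cycle (on-resonance passband)
  expect_true(all(abs(sdsB - sigma) / sigma < 0.1))
  sdsD <- apply(st@dam, 2, sd)
  expect_true(all(abs(sdsD - sigma) / sigma < 0.1))
})

test_that("cohort generation honours its generative model", {
  ## null model: all betas and variances zero gives identically zero scores
  spec0 <- CohortGenSpec(nParticipants = 30,
                         cognitionBetas = c(intercept = 0, age = 0, sex = 0,
                                            raceBlack = 0, raceOther = 0,
                                            edy = 0, time = 0, qmri = 0,
                                            ageTime = 0, qmriAge = 0,
                                            qmriTime = 0, qmriTimeAge = 0),
                         randomInterceptSd = 0, residualSd = 0, seed = 2)
  cc0 <- generateCohort(spec0)
  expect_true(all(cc0$visits$cognition == 0))

  ## residual 0, random intercept only, no time effects: scores constant
  ## within participant
  b <- spec0@cognitionBetas; b["qmri"] <- 0.5; b["age"] <- -0.01
  spec1 <- CohortGenSpec(nParticipants = 30, cognitionBetas = b,
                         randomInterceptSd = 1, residualSd = 0, seed = 3)
  cc1 <- generateCohort(spec1)
  spread <- tapply(cc1$visits$cognition, cc1$visits$pid,
                   function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))

  ## every participant has a visit at time 0 (the MRI date)
  cc <- generateCohort(CohortGenSpec(nParticipants = 40, seed = 4))
  at0 <- tapply(cc$visits$time, cc$visits$pid, function(t) any(t == 0))
  expect_true(all(at0))
  expect_true(all(cc$visits$time <= 0))

  ## demographics track the spec
  big <- generateCohort(CohortGenSpec(nParticipants = 2000, seed = 5))$cohort
  expect_equal(mean(big$sex == "Male"), 0.533, tolerance = 0.05)
  expect_equal(mean(big$race == "White"), 0.683, tolerance = 0.05)
  expect_equal(mean(big$edy), 16.3, tolerance = 0.2)
  expect_equal(sd(big$age), (94 - 22) / sqrt(12), tolerance = 1)

  expect_error(generateCohort(CohortGenSpec(nParticipants = 1)), "2")
})

test_that("the generated time slope is recoverable by per-participant OLS", {
  b <- c(intercept = 0.2, age = 0, sex = 0, raceBlack = 0, raceOther = 0,
         edy = 0, time = -0.05, qmri = 0, ageTime = 0, qmriAge = 0,
         qmriTime = 0, qmriTimeAge = 0)
  spec <- CohortGenSpec(nParticipants = 500, cognitionBetas = b,
                        randomInterceptSd = 0.4, residualSd = 0.25,
                        visitMean = 5, seed = 11)
  cc <- generateCohort(spec)
  slopes <- unlist(lapply(split(cc$visits, cc$visits$pid), function(d) {
    if (nrow(d) < 2) return(NULL)
    cov(d$time, d$cognition) / var(d$time)
  }))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - (-0.05)), 3 * se)
})
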