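test_that("SPGR signal matches the Bloch-iteration steady state", {
  p <- TissueParameters(t1 = 1000, m0 = 1)
  s <- spgrSignal(p, 10, c(1.48, 5))
  oracle <- blochSpgr(1, 1000, 10, 5, nTr = 10000)
  expect_lt(abs(s - oracle) / oracle, 1e-9)

  ## B1 enters only through the product kappa * alpha
  p2 <- TissueParameters(t1 = 800, b1Scale = 2)
  expect_equal(as.numeric(spgrSignal(p2, 5)),
               as.numeric(spgrSignal(TissueParameters(t1 = 800), 10)))

  ## vanishing flip angle gives vanishing signal; non-positive angle errors
  expect_lt(spgrSignal(p, 1e-8), 1e-9)
  expect_error(spgrSignal(p, 0), "flip angles")
  expect_error(spgrSignal(p, -5), "flip angles")
})

test_that("bSSFP closed form equals an explicit 3x3 matrix solve", {
  matrixBssfp <- function(m0, t1, t2, df, a, dphi, te, tr, k = 1) {
    ar <- k * a * pi / 180
    b <- 2 * pi * df * tr / 1000 - dphi
    Rx <- matrix(c(1, 0, 0, 0, cos(ar), sin(ar), 0, -sin(ar), cos(ar)), 3, 3)
    Rz <- matrix(c(cos(b), sin(b), 0, -sin(b), cos(b), 0, 0, 0, 1), 3, 3)
    E <- diag(c(exp(-tr / t2), exp(-tr / t2), exp(-tr / t1)))
    M <- solve(diag(3) - Rz %*% E %*% Rx, c(0, 0, (1 - exp(-tr / t1)) * m0))
    Mp <- Rx %*% M
    exp(-te / t2) * sqrt(Mp[1]^2 + Mp[2]^2)
  }
  set.seed(42)
  for (i in 1:25) {
    t1 <- runif(1, 300, 2500); t2 <- runif(1, 20, 150)
    df <- runif(1, -80, 80); a <- runif(1, 2, 70)
    dphi <- sample(c(0, pi), 1); k <- runif(1, 0.7, 1.3)
    p <- TissueParameters(t1 = t1, t2 = t2, offResonance = df, b1Scale = k)
    expect_equal(as.numeric(bssfpSignal(p, a, dphi)),
                 matrixBssfp(1, t1, t2, df, a, dphi, 2.8, 5.9, k),
                 tolerance = 1e-9)
  }
})

test_that("bSSFP reduces to the classic closed form at pi precession", {
  ## on resonance with a pi phase cycle the effective per-TR precession is pi
  te <- 2.8; tr <- 5.9
  for (a in c(10, 30, 60)) {
    t1 <- 1000; t2 <- 80
    e1 <- exp(-tr / t1); e2 <- exp(-tr / t2)
    ar <- a * pi / 180
    closed <- exp(-te / t2) * sin(ar) * (1 - e1) /
      (1 - (e1 - e2) * cos(ar) - e1 * e2)
    expect_equal(as.numeric(bssfpSignal(TissueParameters(t1 = t1, t2 = t2),
                                        a, pi, c(te, tr))),
                 closed, tolerance = 1e-9)
  }
  ## T1 = T2 = T limit: amplitude M0 sin(a) / (1 + E)
  tt <- 500; e <- exp(-5.9 / tt); ar <- 40 * pi / 180
  expect_equal(as.numeric(bssfpSignal(
    TissueParameters(t1 = tt, t2 = tt, t1Short = 100, t2Short = 100,
                     t1Long = tt, t2Long = tt), 40, pi)),
    exp(-2.8 / tt) * sin(ar) / (1 + e), tolerance = 1e-9)
})

test_that("bSSFP is periodic in the effective precession angle", {
  tr <- 5.9
  p1 <- TissueParameters(t1 = 900, t2 = 70, offResonance = 1000 / (2 * tr))
  p2 <- TissueParameters(t1 = 900, t2 = 70, offResonance = 0)
  ## beta = pi - pi = 0 for p1 with dphi = pi; beta = 0 for p2 with dphi = 0
  expect_equal(bssfpSignal(p1, c(10, 30), pi), bssfpSignal(p2, c(10, 30), 0),
               tolerance = 1e-12)
})

test_that("two-component signal is a linear mixture of the pool signals", {
  pr <- AcquisitionProtocol()
  mk <- function(mwf) TissueParameters(mwf = mwf, t1Short = 350,
                                       t1Long = 1100, t2Short = 20,
                                       t2Long = 85, m0 = 100)
  sShort <- twoComponentSignal(mk(1), pr)
  sLong <- twoComponentSignal(mk(0), pr)
  sMix <- twoComponentSignal(mk(0.3), pr)
  expect_equal(sMix@spgr, 0.3 * sShort@spgr + 0.7 * sLong@spgr,
               tolerance = 1e-12)
  expect_equal(sMix@bssfp, 0.3 * sShort@bssfp + 0.7 * sLong@bssfp,
               tolerance = 1e-12)

  ## degenerate mixtures: mwf = 0 / 1 equal the single-pool signals
  pLong <- TissueParameters(t1 = 1100, t2 = 85, m0 = 100)
  expect_equal(sLong@spgr[1, ],
               as.numeric(spgrSignal(pLong, pr@spgrFlipAngles, pr@spgrTeTr)),
               tolerance = 1e-12)
  ## identical pools: mixture equals the single-component signal
  pEq <- TissueParameters(mwf = 0.5, t1Short = 800 - 1e-9, t1Long = 800,
                          t2Short = 60 - 1e-9, t2Long = 60, m0 = 100)
  sEq <- twoComponentSignal(pEq, pr)
  expect_equal(sEq@spgr[1, ],
               as.numeric(spgrSignal(TissueParameters(t1 = 800, t2 = 60,
                                                      m0 = 100),
                                     pr@spgrFlipAngles, pr@spgrTeTr)),
               tolerance = 1e-6)
})

test_that("DAM pair follows exact double-angle trigonometry", {
  p <- TissueParameters()
  s <- damSignalPair(p, c(45, 90))
  expect_equal(s[1, 2] / s[1, 1], sqrt(2), tolerance = 1e-12)

  ## kappa = 4/3 at 45 degrees: ratio 2 cos(60 deg) = 1
  s2 <- damSignalPair(TissueParameters(b1Scale = 4 / 3), c(45, 90))
  expect_equal(s2[1, 2] / s2[1, 1], 1, tolerance = 1e-12)

  ## kappa alpha = 90 degrees: second signal vanishes
  s3 <- damSignalPair(TissueParameters(b1Scale = 2), c(45, 90))
  expect_equal(s3[1, 2], 0, tolerance = 1e-12)

  expect_error(damSignalPair(p, c(45, 80)), "double-angle")
})

test_that("forward models agree with Bloch iteration on a random grid", {
  ## property check at reduced size; the acceptance suite runs 1,000 draws
  set.seed(7)
  n <- 60
  t1 <- runif(n, 300, 2500); t2 <- pmin(runif(n, 20, 150), t1 / 2)
  df <- runif(n, -80, 80); a <- runif(n, 2, 60)
  dphi <- sample(c(0, pi), n, replace = TRUE); k <- runif(n, 0.8, 1.2)
  oracle <- blochBssfp(1, t1, t2, df, a, dphi, 2.8, 5.9, k, nTr = 20000)
  got <- vapply(seq_len(n), function(i)
    as.numeric(bssfpSignal(TissueParameters(t1 = t1[i], t2 = t2[i],
                                            offResonance = df[i],
                                            b1Scale = k[i]),
                           a[i], dphi[i])), numeric(1))
  expect_lt(max(abs(got - oracle)), 1e-8)

  oracleS <- vapply(seq_len(n), function(i)
    blochSpgr(1, t1[i], min(a[i], 90), 5, k[i], nTr = 20000), numeric(1))
  gotS <- vapply(seq_len(n), function(i)
    as.numeric(spgrSignal(TissueParameters(t1 = t1[i], b1Scale = k[i]),
                          min(a[i], 90))), numeric(1))
  expect_lt(max(abs(gotS - oracleS)), 1e-8)
})
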