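## Independent oracles used across the suite. These deliberately avoid the
## package's closed-form/vectorised code paths: signals are obtained by
## explicit per-TR Bloch iteration, BH by checking the step-up condition for
## every k, OLS by the normal equations.

## Ideally spoiled SPGR steady state by explicit iteration of the Mz
## recursion (transverse magnetisation destroyed every TR).
blochSpgr <- function(m0, t1, alphaDeg, trMs, kappa = 1, nTr = 20000L) {
  n <- max(lengths(list(m0, t1, alphaDeg, kappa)))
  a <- rep_len(kappa, n) * rep_len(alphaDeg, n) * pi / 180
  e1 <- exp(-trMs / rep_len(t1, n))
  m0 <- rep_len(m0, n)
  mz <- m0
  ca <- cos(a)
  for (i in seq_len(nTr)) mz <- (mz * ca) * e1 + (1 - e1) * m0
  mz * sin(a)
}

## bSSFP steady state by explicit per-TR propagation, vectorised across
## parameter draws: rotate about x by kappa*alpha, then relax and precess by
## beta = 2 pi df TR - dphi over the TR; magnitude read out at TE with
## transverse decay applied (precession up to TE does not change magnitude).
blochBssfp <- function(m0, t1, t2, offHz, alphaDeg, dphi, teMs, trMs,
                       kappa = 1, nTr = 20000L) {
  n <- max(lengths(list(m0, t1, t2, offHz, alphaDeg, dphi, kappa)))
  r <- function(x) rep_len(x, n)
  m0 <- r(m0); t1 <- r(t1); t2 <- r(t2); offHz <- r(offHz)
  a <- r(kappa) * r(alphaDeg) * pi / 180
  dphi <- r(dphi)
  e1 <- exp(-trMs / t1); e2 <- exp(-trMs / t2)
  beta <- 2 * pi * offHz * trMs / 1000 - dphi
  ca <- cos(a); sa <- sin(a); cb <- cos(beta); sb <- sin(beta)
  mx <- my <- numeric(n); mz <- m0
  for (i in seq_len(nTr)) {
    ## rotation about x
    my2 <- ca * my - sa * mz
    mz2 <- sa * my + ca * mz
    ## relaxation + precession about z over one TR
    mxr <- e2 * mx; myr <- e2 * my2
    mx <- cb * mxr - sb * myr
    my <- sb * mxr + cb * myr
    mz <- e1 * mz2 + (1 - e1) * m0
  }
  ## signal: magnitude just after the next pulse, decayed to TE
  my2 <- ca * my - sa * mz
  exp(-teMs / t2) * sqrt(mx^2 + my2^2)
}

## Brute-force Benjamini-Hochberg: for each test, reject iff there exists a
## k >= its rank with p_(k) <= k q / m; adjusted p by direct minimisation.
bruteForceBH <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  kmax <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kmax <- k
  rej <- rep(FALSE, m)
  if (kmax > 0) rej[seq_len(kmax)] <- TRUE
  out <- data.frame(p = p, pAdj = NA_real_, rejected = NA)
  out$pAdj[o] <- adj
  out$rejected[o] <- rej
  out
}

## OLS via the normal equations.
olsNormalEq <- function(X, y) as.numeric(solve(t(X) %*% X, t(X) %*% y))

## Single-voxel two-pool stacks for BMC tests.
makeTwoPoolVoxel <- function(mwf, t1Short = 350, t1Long = 1100,
                             t2Short = 20, t2Long = 85, m0 = 377,
                             protocol = AcquisitionProtocol()) {
  p <- TissueParameters(mwf = mwf, t1Short = t1Short, t1Long = t1Long,
                        t2Short = t2Short, t2Long = t2Long, m0 = m0)
  st <- twoComponentSignal(p, protocol)
  list(spgr = st@spgr[1, ], bssfp = st@bssfp[1, , ])
}
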