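#' @importFrom methods new validObject is slot slotNames show
#' @importFrom stats lm coef vcov predict rnorm runif rpois rbinom sd optim
#'   p.adjust pnorm quantile complete.cases as.formula model.frame setNames
#' @importFrom utils read.csv write.csv head
NULL

DEG2RAD <- pi / 180

## Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
## state afterwards so no global state leaks between operations.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Voxel-centre coordinates (mm) along one grid axis: voxel i spans
## [(i-1)*vs, i*vs), centre at (i - 0.5)*vs.
voxelCentres <- function(n, voxelSize) (seq_len(n) - 0.5) * voxelSize

## Recycle a per-voxel parameter vector (length 1 or nVox) to length nVox.
recycleField <- function(x, nVox) {
  if (length(x) == 1L) rep(x, nVox) else x
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
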