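## NIfTI / CSV / YAML plumbing. Volumes travel as column-major vectors plus
## grid geometry inside the package; on disk they are NIfTI with pixdim set,
## either one 3-D file per flip angle or a single 4-D file (both dialects are
## readable).

#' Write a volume (vector + geometry) as NIfTI
#'
#' @param x numeric/logical vector of length prod(dim), or an array.
#' @param dim integer grid shape (ignored when \code{x} is an array).
#' @param voxelSize numeric voxel size in mm, recycled to the array rank.
#' @param file output path (.nii or .nii.gz).
#' @return the file path, invisibly.
#' @export
writeNiftiVolume <- function(x, dim = NULL, voxelSize = 1, file) {
  arr <- if (is.array(x)) x else array(as.numeric(x), dim)
  img <- RNifti::asNifti(arr * 1)
  RNifti::pixdim(img) <- rep(voxelSize, length.out = length(base::dim(arr)))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI volume into vector + geometry form
#'
#' @param file path to a NIfTI file.
#' @return list with \code{data} (numeric vector, column-major), \code{dim}
#'   (integer) and \code{voxelSize} (numeric, mm).
#' @export
readNiftiVolume <- function(file) {
  img <- RNifti::readNifti(file)
  d <- base::dim(img)
  list(data = as.numeric(img), dim = as.integer(d),
       voxelSize = as.numeric(RNifti::pixdim(img))[seq_along(d)])
}

#' Write a SignalStackSet to a directory of NIfTI files
#'
#' One 4-D file per stack: \code{spgr.nii.gz} (x, y, z, flip angle),
#' \code{bssfp_<cycle>.nii.gz} per phase increment, \code{dam.nii.gz}, plus
#' \code{protocol.yaml}.
#'
#' @param stacks a \code{\link{SignalStackSet}}.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
writeSignalStacks <- function(stacks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gdim <- stacks@dim; vs <- stacks@voxelSize
  files <- character()
  w4 <- function(mat, name) {
    arr <- array(mat, c(gdim, ncol(mat)))
    f <- file.path(dir, name)
    writeNiftiVolume(arr, voxelSize = c(vs, 1), file = f)
    f
  }
  files <- c(files, w4(stacks@spgr, "spgr.nii.gz"))
  for (ci in seq_len(dim(stacks@bssfp)[3])) {
    nm <- sprintf("bssfp_%03.0f.nii.gz",
                  stacks@protocol@bssfpPhaseIncrements[ci] * 180 / pi)
    files <- c(files, w4(stacks@bssfp[, , ci], nm))
  }
  files <- c(files, w4(stacks@dam, "dam.nii.gz"))
  pf <- file.path(dir, "protocol.yaml")
  yaml::write_yaml(protocolToList(stacks@protocol), pf)
  invisible(c(files, pf))
}

#' Read a SignalStackSet from a directory written by writeSignalStacks
#'
#' Accepts either a single 4-D file per stack or a series of 3-D files
#' \code{<stack>_fa<k>.nii.gz} (one per flip angle).
#'
#' @param dir directory containing the stack files and protocol.yaml.
#' @return A \code{\link{SignalStackSet}}.
#' @export
readSignalStacks <- function(dir) {
  protocol <- protocolFromList(yaml::read_yaml(file.path(dir, "protocol.yaml")))
  read4 <- function(name, nExpected) {
    f <- file.path(dir, paste0(name, ".nii.gz"))
    if (file.exists(f)) {
      v <- readNiftiVolume(f)
      gdim <- v$dim[1:3]
      mat <- matrix(v$data, prod(gdim), v$dim[4])
      return(list(mat = mat, dim = gdim, vs = v$voxelSize[1:3]))
    }
    ## per-angle dialect
    parts <- lapply(seq_len(nExpected), function(k) {
      fk <- file.path(dir, sprintf("%s_fa%02d.nii.gz", name, k))
      stopIfNot(file.exists(fk), sprintf("missing stack file %s", fk))
      readNiftiVolume(fk)
    })
    gdim <- parts[[1]]$dim
    list(mat = vapply(parts, function(p) p$data, numeric(prod(gdim))),
         dim = gdim, vs = parts[[1]]$voxelSize)
  }
  spgr <- read4("spgr", length(protocol@spgrFlipAngles))
  nCyc <- length(protocol@bssfpPhaseIncrements)
  bssfp <- array(0, c(prod(spgr$dim), length(protocol@bssfpFlipAngles), nCyc))
  for (ci in seq_len(nCyc)) {
    nm <- sprintf("bssfp_%03.0f", protocol@bssfpPhaseIncrements[ci] * 180 / pi)
    bssfp[, , ci] <- read4(nm, length(protocol@bssfpFlipAngles))$mat
  }
  dam <- read4("dam", 2L)
  new("SignalStackSet", spgr = spgr$mat, bssfp = bssfp, dam = dam$mat,
      dim = spgr$dim, voxelSize = spgr$vs, protocol = protocol)
}

#' @rdname protocolFromList
#' @export
protocolToList <- function(protocol) {
  list(spgr_te_tr = protocol@spgrTeTr, spgr_flip_angles = protocol@spgrFlipAngles,
       bssfp_te_tr = protocol@bssfpTeTr,
       bssfp_flip_angles = protocol@bssfpFlipAngles,
       bssfp_phase_increments = protocol@bssfpPhaseIncrements,
       dam_flip_angles = protocol@damFlipAngles, dam_te_tr = protocol@damTeTr,
       noise_sd = protocol@noiseSd)
}

#' Protocol serialisation to and from plain lists (YAML-friendly)
#'
#' @param x a plain list (from YAML) or an \code{AcquisitionProtocol}.
#' @return \code{protocolFromList}: an \code{AcquisitionProtocol};
#'   \code{protocolToList}: a named list.
#' @export
protocolFromList <- function(x) {
  AcquisitionProtocol(
    spgrTeTr = as.numeric(x$spgr_te_tr),
    spgrFlipAngles = as.numeric(x$spgr_flip_angles),
    bssfpTeTr = as.numeric(x$bssfp_te_tr),
    bssfpFlipAngles = as.numeric(x$bssfp_flip_angles),
    bssfpPhaseIncrements = as.numeric(x$bssfp_phase_increments),
    damFlipAngles = as.numeric(x$dam_flip_angles),
    damTeTr = as.numeric(x$dam_te_tr),
    noiseSd = as.numeric(x$noise_sd))
}

#' Write / read an LcMask as NIfTI (0/1)
#' @param mask an \code{\link{LcMask}}; @param file path.
#' @return \code{writeLcMask}: the path invisibly; \code{readLcMask}: an
#'   \code{LcMask} (axis convention from arguments).
#' @export
writeLcMask <- function(mask, file) {
  writeNiftiVolume(array(as.numeric(mask@mask), mask@dim),
                   voxelSize = mask@voxelSize, file = file)
}

#' @rdname writeLcMask
#' @param rostrocaudalAxis,rostralDirection axis convention to attach.
#' @export
readLcMask <- function(file, rostrocaudalAxis = 3L, rostralDirection = 1L) {
  v <- readNiftiVolume(file)
  LcMask(v$data > 0.5, dim = v$dim, voxelSize = v$voxelSize,
         rostrocaudalAxis = rostrocaudalAxis,
         rostralDirection = rostralDirection)
}

#' Write / read a QmriMapSet as a directory of NIfTI maps plus a status CSV
#' @param maps a \code{\link{QmriMapSet}}; @param dir directory.
#' @return \code{writeQmriMaps}: file paths invisibly; \code{readQmriMaps}: a
#'   \code{QmriMapSet}.
#' @export
writeQmriMaps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in c("r1", "r2", "mwf", "m0", "resNorm")) {
    v <- slot(maps, nm)
    f <- file.path(dir, paste0(tolower(nm), ".nii.gz"))
    writeNiftiVolume(array(ifelse(is.na(v), -1, v), maps@dim),
                     voxelSize = maps@voxelSize, file = f)
    files <- c(files, f)
  }
  sf <- file.path(dir, "status.csv")
  write.csv(data.frame(voxel = seq_along(maps@status), status = maps@status),
            sf, row.names = FALSE)
  invisible(c(files, sf))
}

#' @rdname writeQmriMaps
#' @export
readQmriMaps <- function(dir) {
  rd <- function(nm) {
    v <- readNiftiVolume(file.path(dir, paste0(nm, ".nii.gz")))
    list(data = ifelse(v$data < 0, NA_real_, v$data), dim = v$dim,
         vs = v$voxelSize)
  }
  r1 <- rd("r1"); r2 <- rd("r2"); mwf <- rd("mwf"); m0 <- rd("m0")
  rn <- rd("resnorm")
  status <- read.csv(file.path(dir, "status.csv"))$status
  QmriMapSet(r1 = r1$data, r2 = r2$data, mwf = mwf$data, m0 = m0$data,
             status = status, resNorm = ifelse(is.na(rn$data), 0, rn$data),
             dim = r1$dim, voxelSize = r1$vs)
}
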