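#' @include AllClasses.R
NULL

# world coordinates (mm) of 1-based voxel index rows, NIfTI 0-based affine
.worldCoords <- function(idx, affine) {
  idx0 <- sweep(idx, 2, c(1, 1, 1))
  t(affine[1:3, 1:3] %*% t(idx0) + affine[1:3, 4])
}

.checkSameGrid <- function(a, b, what = "volumes") {
  if (!identical(dim(a@data), dim(b@data)))
    stop(what, " must share the same grid (dimension mismatch)")
  if (max(abs(a@spacing - b@spacing)) > 1e-6)
    stop(what, " must share the same grid (spacing mismatch)")
  invisible(TRUE)
}

.readNifti3D <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume, got ", length(d), "D image: ", path)
  aff <- structure(RNifti::xform(img), code = NULL)
  aff <- matrix(as.numeric(aff), 4, 4)
  if (any(!is.finite(aff)) || abs(det(aff[1:3, 1:3])) < 1e-12)
    stop("missing or degenerate affine in ", path)
  sp <- abs(RNifti::pixdim(img))[1:3]
  list(data = array(as.numeric(img), d), spacing = sp, affine = aff)
}

#' Read a probability volume from a NIfTI file
#'
#' Values are clipped to \[0, 1\]; excursions beyond a tolerance of 1e-3
#' (e.g. interpolation overshoot) trigger a warning. Gzipped files are
#' handled transparently.
#'
#' @param path a `.nii` / `.nii.gz` file with a 3D single-channel image.
#' @return a [ProbabilityVolume-class].
#' @export
readProbabilityVolume <- function(path) {
  x <- .readNifti3D(path)
  lo <- min(x$data); hi <- max(x$data)
  if (lo < -1e-3 || hi > 1 + 1e-3)
    warning(sprintf(
      "values outside [0, 1] beyond tolerance (range %.4g..%.4g); clipping",
      lo, hi))
  x$data[x$data < 0] <- 0
  x$data[x$data > 1] <- 1
  ProbabilityVolume(x$data, x$spacing, x$affine)
}

#' Read a binary mask from a NIfTI file
#'
#' Nonzero voxels become TRUE.
#'
#' @inheritParams readProbabilityVolume
#' @return a [BinaryMask-class].
#' @export
readBinaryMask <- function(path) {
  x <- .readNifti3D(path)
  BinaryMask(array(x$data != 0, dim(x$data)), x$spacing, x$affine)
}

#' Write a volume or mask to a NIfTI file
#'
#' The affine is stored as both sform and qform; masks are written as
#' uint8 0/1.
#'
#' @param vol an [ImageVolume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  dat <- vol@data
  if (is.logical(dat)) {
    dat <- array(as.integer(dat), dim(dat))
    dt <- "uint8"
  } else dt <- "double"
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol@spacing
  RNifti::qform(img) <- structure(vol@affine, code = 2L)
  RNifti::sform(img) <- structure(vol@affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

# trilinear / nearest sampling of a 3D array at fractional 0-based voxel
# coordinates (clamped to the grid, i.e. replicate border)
.sampleVolume <- function(x, cx, cy, cz, interp) {
  d <- dim(x)
  if (interp == "nearest") {
    i <- pmin(pmax(round(cx), 0), d[1] - 1)
    j <- pmin(pmax(round(cy), 0), d[2] - 1)
    k <- pmin(pmax(round(cz), 0), d[3] - 1)
    return(x[1 + i + d[1] * (j + d[2] * k)])
  }
  cx <- pmin(pmax(cx, 0), d[1] - 1)
  cy <- pmin(pmax(cy, 0), d[2] - 1)
  cz <- pmin(pmax(cz, 0), d[3] - 1)
  i0 <- pmin(floor(cx), max(d[1] - 2, 0)); fx <- cx - i0
  j0 <- pmin(floor(cy), max(d[2] - 2, 0)); fy <- cy - j0
  k0 <- pmin(floor(cz), max(d[3] - 2, 0)); fz <- cz - k0
  s1 <- ifelse(d[1] > 1, 1, 0); s2 <- ifelse(d[2] > 1, d[1], 0)
  s3 <- ifelse(d[3] > 1, d[1] * d[2], 0)
  base <- 1 + i0 + d[1] * (j0 + d[2] * k0)
  v000 <- x[base];            v100 <- x[base + s1]
  v010 <- x[base + s2];       v110 <- x[base + s1 + s2]
  v001 <- x[base + s3];       v101 <- x[base + s1 + s3]
  v011 <- x[base + s2 + s3];  v111 <- x[base + s1 + s2 + s3]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
  (v010 * (1 - fx) + v110 * fx) * fy       * (1 - fz) +
  (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
  (v011 * (1 - fx) + v111 * fx) * fy       * fz
}

.resampleCore <- function(vol, targetMm, interp) {
  stopifnot(is.numeric(targetMm), length(targetMm) == 1L, targetMm > 0)
  d <- dim(vol@data)
  sp <- vol@spacing
  nd <- pmax(1L, as.integer(ceiling(d * sp / targetMm)))
  # output voxel v maps to input voxel coordinates v * target/spacing,
  # so origin and direction cosines carry over unchanged
  scl <- targetMm / sp
  gx <- (seq_len(nd[1]) - 1) * scl[1]
  gy <- (seq_len(nd[2]) - 1) * scl[2]
  gz <- (seq_len(nd[3]) - 1) * scl[3]
  cx <- rep(gx, times = nd[2] * nd[3])
  cy <- rep(rep(gy, each = nd[1]), times = nd[3])
  cz <- rep(gz, each = nd[1] * nd[2])
  x <- vol@data
  storage.mode(x) <- "double"
  out <- array(.sampleVolume(x, cx, cy, cz, interp), nd)
  aff <- vol@affine %*% diag(c(scl, 1))
  list(data = out, spacing = rep(targetMm, 3), affine = aff)
}

#' @describeIn resampleIsotropic linear (default) or nearest interpolation;
#'   linear interpolation cannot leave \[0, 1\].
#' @export
setMethod("resampleIsotropic", "ProbabilityVolume",
  function(vol, targetMm, interp = "linear") {
    interp <- match.arg(interp, c("linear", "nearest"))
    r <- .resampleCore(vol, targetMm, interp)
    ProbabilityVolume(pmin(pmax(r$data, 0), 1), r$spacing, r$affine)
  })

#' @describeIn resampleIsotropic nearest-neighbour only (mask semantics).
#' @export
setMethod("resampleIsotropic", "BinaryMask",
  function(vol, targetMm, interp = "nearest") {
    r <- .resampleCore(vol, targetMm, "nearest")
    BinaryMask(array(r$data != 0, dim(r$data)), r$spacing, r$affine)
  })

#' Threshold a probability volume into a binary mask
#'
#' The comparison is inclusive (`>= t`), so a sweep that ends at 0.99
#' still retains voxels saturated at 0.99.
#'
#' @param vol a [ProbabilityVolume-class].
#' @param t threshold in \[0, 1\].
#' @return a [BinaryMask-class] on the same grid.
#' @export
thresholdVolume <- function(vol, t) {
  stopifnot(is(vol, "ProbabilityVolume"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop("threshold must be a single value in [0, 1]")
  BinaryMask(vol@data >= t, vol@spacing, vol@affine)
}
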