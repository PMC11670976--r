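#' @include detection.R
NULL

#' Quantification mask for a detected drain
#'
#' Detection uses a high threshold (default 0.9) to avoid false positive
#' objects, while coverage quantification uses a lower one (default 0.44,
#' the value that optimizes agreement with GT profiles). The
#' quantification mask is the connected component of the low-threshold
#' mask that contains the detected object's voxels, so noise objects
#' absent at the detection threshold are never resurrected. By threshold
#' monotonicity the result is a superset of the detected object.
#'
#' @param drainProb drain [ProbabilityVolume-class].
#' @param components [ComponentSet-class] from the detection threshold.
#' @param objectId id of the detected object.
#' @param tQuant quantification threshold (default 0.44).
#' @return a [BinaryMask-class].
#' @export
extractQuantificationMask <- function(drainProb, components, objectId,
                                      tQuant = 0.44) {
  stopifnot(is(drainProb, "ProbabilityVolume"), is(components, "ComponentSet"))
  objVox <- components@labels == objectId
  if (!any(objVox)) stop("detected object ", objectId, " is empty")
  maskQ <- thresholdVolume(drainProb, tQuant)
  labQ <- cc_label_3d(as.vector(maskQ@data), dim(maskQ@data),
                      components@connectivity)
  keep <- unique(labQ[objVox])
  keep <- keep[keep > 0L]
  out <- array(labQ %in% keep, dim(labQ))
  BinaryMask(out, drainProb@spacing, drainProb@affine)
}

#' Compute the volume of touch between a drain and the ICH
#'
#' A drain voxel belongs to the volume of touch V iff its spatially
#' nearest non-drain voxel (Euclidean distance in world mm) belongs to
#' the ICH rather than to the background. Voxels where drain and ICH
#' masks overlap are assigned to the drain ("drain-wins") before the
#' distance transforms. Ties between an equidistant ICH and background
#' voxel are resolved in favour of the ICH; the rule is deterministic and
#' invariant under translation and axis permutation.
#'
#' @param drain drain [BinaryMask-class].
#' @param ich ICH [BinaryMask-class] on the same grid.
#' @param parentDrain integer id recorded on the result.
#' @return a [TouchVolume-class] (a [BinaryMask-class] subset of the drain).
#' @export
computeTouchVolume <- function(drain, ich, parentDrain = 1L) {
  stopifnot(is(drain, "BinaryMask"), is(ich, "BinaryMask"))
  .checkSameGrid(drain, ich, "drain and ICH masks")
  d <- dim(drain@data)
  ichEff <- ich@data & !drain@data
  v <- array(FALSE, d)
  if (any(ichEff) && any(drain@data)) {
    dAll <- edt_sq_3d(as.vector(!drain@data), d, drain@spacing)
    dIch <- edt_sq_3d(as.vector(ichEff), d, drain@spacing)
    v <- drain@data & (sqrt(dIch) <= sqrt(dAll) + 1e-9)
  }
  new("TouchVolume", data = v, spacing = drain@spacing,
      affine = drain@affine, parentDrain = as.integer(parentDrain))
}

#' Principal-axis frame of a weighted voxel set
#'
#' Centroid and eigensystem of the weighted second central moment tensor
#' of the world coordinates (mm^2). Eigenvalues are sorted descending;
#' the leading eigenvector is the profile axis. Its sign is fixed later
#' by the tip rule.
#'
#' @param weights an [ImageVolume-class] whose data are nonnegative
#'   weights (a smoothed mask, typically).
#' @param source provenance string stored on the frame.
#' @return a [PrincipalFrame-class].
#' @export
principalFrame <- function(weights, source = "touch_volume") {
  stopifnot(is(weights, "ImageVolume"))
  w <- as.numeric(weights@data)
  idx <- which(w > 0)
  if (length(idx) == 0L || sum(w[idx]) <= 0)
    stop("total weight must be positive")
  wi <- w[idx]
  xyz <- .worldCoords(arrayInd(idx, dim(weights@data)), weights@affine)
  sw <- sum(wi)
  centroid <- colSums(xyz * wi) / sw
  cen <- sweep(xyz, 2, centroid)
  M <- crossprod(cen * wi, cen) / sw
  e <- eigen(M, symmetric = TRUE)   # descending eigenvalues
  if (e$values[1] <= 1e-12)
    stop("degenerate moment tensor (single point or zero spread)")
  if (e$values[2] > 0 && e$values[1] / e$values[2] < 1.05)
    warning("degenerate frame: leading eigenvalues nearly equal (ratio < 1.05)")
  axes <- e$vectors
  # canonical sign: largest-magnitude component positive
  for (j in 1:3) {
    m <- which.max(abs(axes[, j]))
    if (axes[m, j] < 0) axes[, j] <- -axes[, j]
  }
  new("PrincipalFrame", centroid = centroid, axes = axes,
      eigenvalues = e$values, source = source)
}

#' Regrid to 0.5-mm isotropic resolution and smooth to 1-mm
#'
#' Linear resampling onto an isotropic grid followed by separable
#' Gaussian smoothing with FWHM `fwhmMm` per axis (an integrated-Gaussian
#' kernel normalized to unit sum, so interior mass is preserved; zero
#' padding at the volume faces).
#'
#' @param vol an [ImageVolume-class] (masks are converted to 0/1 weights).
#' @param targetMm isotropic target spacing (default 0.5 mm).
#' @param fwhmMm Gaussian FWHM in mm (default 1.0, i.e. sigma 0.4247 mm).
#' @return a [ProbabilityVolume-class] of smoothed weights.
#' @export
regridAndSmooth <- function(vol, targetMm = 0.5, fwhmMm = 1.0) {
  stopifnot(is(vol, "ImageVolume"))
  dat <- vol@data
  if (is.logical(dat)) dat <- array(as.numeric(dat), dim(dat))
  pv <- ProbabilityVolume(pmin(pmax(dat, 0), 1), vol@spacing, vol@affine)
  rs <- resampleIsotropic(pv, targetMm, "linear")
  k <- .gaussKernel(fwhmMm, targetMm)
  sm <- conv_sep_3d(as.vector(rs@data), dim(rs@data), k, k, k)
  ProbabilityVolume(array(pmin(pmax(sm, 0), 1), dim(rs@data)),
                    rs@spacing, rs@affine)
}

# integrated-Gaussian kernel over voxel bins of width h, unit sum
.gaussKernel <- function(fwhmMm, h) {
  if (fwhmMm <= 0) return(1)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma / h))
  i <- (-r):r
  k <- pnorm((i + 0.5) * h, 0, sigma) - pnorm((i - 0.5) * h, 0, sigma)
  k / sum(k)
}

#' Locate the drain tip
#'
#' The two extremes of the drain along the axis are the candidates (each
#' taken as the centroid of the end cross-section, i.e. of the drain
#' voxels projecting within half a voxel of the extreme projection); the
#' tip is the candidate whose world-space distance to the nearest
#' image-volume face is larger (drains enter through the skull near the
#' volume surface, so the tip is the deep end). An explicit `override`
#' wins. The axis is re-signed to point tip -> entry.
#'
#' @param drain drain [BinaryMask-class] on the original (uncropped) grid.
#' @param axis unit vector (sign arbitrary on input).
#' @param override optional known tip, world mm.
#' @return list with `tip` (world mm), `axis` (unit, tip -> entry) and
#'   `entry` (opposite extreme).
#' @export
locateTip <- function(drain, axis, override = NULL) {
  stopifnot(is(drain, "BinaryMask"))
  idx <- which(drain@data)
  if (length(idx) == 0L) stop("empty drain mask")
  ijk <- arrayInd(idx, dim(drain@data))
  xyz <- .worldCoords(ijk, drain@affine)
  proj <- as.vector(xyz %*% axis)
  half <- max(drain@spacing) / 2
  endA <- proj <= min(proj) + half
  endB <- proj >= max(proj) - half
  candA <- colMeans(xyz[endA, , drop = FALSE])
  candB <- colMeans(xyz[endB, , drop = FALSE])
  d <- dim(drain@data); sp <- drain@spacing
  faceDist <- function(pt) {
    v0 <- as.vector(solve(drain@affine[1:3, 1:3], pt - drain@affine[1:3, 4]))
    min(pmin(v0 * sp, (d - 1 - v0) * sp))
  }
  fA <- faceDist(candA); fB <- faceDist(candB)
  if (!is.null(override)) {
    tip <- as.numeric(override)
    other <- if (sum((candA - tip)^2) > sum((candB - tip)^2)) candA else candB
  } else if (abs(fA - fB) < 0.5) {
    warning("tip candidates equidistant to volume faces; ",
            "using larger coordinate along axis")
    tip <- candB; other <- candA
  } else if (fA > fB) {
    tip <- candA; other <- candB
  } else {
    tip <- candB; other <- candA
  }
  s <- sum(axis * (other - tip))
  if (s < 0) axis <- -axis
  list(tip = as.numeric(tip), axis = as.numeric(axis / sqrt(sum(axis^2))),
       entry = as.numeric(other))
}

# crop an ImageVolume to the bounding box of `support` plus marginMm
.cropToSupport <- function(vol, support, marginMm = 4) {
  d <- dim(vol@data)
  idx <- which(support)
  ijk <- arrayInd(idx, d)
  mvox <- ceiling(marginMm / vol@spacing)
  lo <- pmax(apply(ijk, 2, min) - mvox, 1)
  hi <- pmin(apply(ijk, 2, max) + mvox, d)
  dat <- vol@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  aff <- vol@affine
  aff[1:3, 4] <- aff[1:3, 1:3] %*% (lo - 1) + aff[1:3, 4]
  if (is.logical(dat))
    BinaryMask(dat, vol@spacing, aff)
  else
    ProbabilityVolume(dat, vol@spacing, aff)
}

#' Coverage profile of a drain by the ICH
#'
#' The full quantification chain for one drain object: volume of touch on
#' the working grid; regrid of the drain and touch masks to 0.5-mm
#' isotropic resolution with Gaussian smoothing to 1-mm effective
#' resolution; principal-axis frame from the smoothed touch weights
#' (falling back to the drain's own frame when the touch volume holds
#' fewer than 10 voxels at 0.5 mm, so contact-free drains still yield a
#' near-zero profile); projection of both weight fields onto the major
#' axis; 0.5-mm slab ratios (touch mass over drain mass, zero where the
#' drain mass is < 1e-6, clipped to \[0, 1\]) over the full drain extent;
#' orientation from the tip.
#'
#' @param drain quantification drain [BinaryMask-class].
#' @param ich ICH [BinaryMask-class] on the same grid.
#' @param tipHint optional known tip (world mm) overriding the tip rule.
#' @param drainId id recorded on the profile.
#' @param targetMm profile sampling step / regrid resolution (default 0.5).
#' @param fwhmMm smoothing FWHM (default 1.0 mm).
#' @return a [CoverageProfile-class].
#' @export
coverageProfile <- function(drain, ich, tipHint = NULL, drainId = 1L,
                            targetMm = 0.5, fwhmMm = 1.0) {
  stopifnot(is(drain, "BinaryMask"))
  if (!any(drain@data)) stop("empty drain mask")
  touch <- computeTouchVolume(drain, ich, parentDrain = drainId)

  # work on the drain's bounding box (plus margin) from here on
  dcrop <- .cropToSupport(drain, drain@data)
  vcrop <- .cropToSupport(touch, drain@data)
  dS <- regridAndSmooth(dcrop, targetMm, fwhmMm)
  vS <- regridAndSmooth(vcrop, targetMm, fwhmMm)

  # frame fallback: effective touch voxel count on the 0.5-mm grid
  vCount <- sum(touch@data) * prod(drain@spacing) / targetMm^3
  if (vCount >= 10) {
    frame <- principalFrame(vS, source = "touch_volume")
  } else {
    frame <- principalFrame(dS, source = "drain_fallback")
  }

  tipInfo <- locateTip(drain, frame@axes[, 1], override = tipHint)
  axis <- tipInfo$axis
  tip <- tipInfo$tip

  wD <- as.numeric(dS@data)
  keep <- wD > 1e-6
  idx <- which(keep)
  xyz <- .worldCoords(arrayInd(idx, dim(dS@data)), dS@affine)
  p <- as.vector(sweep(xyz, 2, tip) %*% axis)
  bin <- floor(p / targetMm + 0.5)
  bin[bin < 0L] <- 0L
  K <- max(bin)
  den <- num <- numeric(K + 1)
  sums <- rowsum(cbind(as.numeric(vS@data)[idx], wD[idx]), bin)
  at <- as.integer(rownames(sums)) + 1L
  num[at] <- sums[, 1]
  den[at] <- sums[, 2]
  vals <- ifelse(den < 1e-6, 0, num / den)
  vals <- pmin(pmax(vals, 0), 1)
  new("CoverageProfile", positions = (0:K) * targetMm, values = vals,
      tipWorld = tip, axis = axis, drainId = as.integer(drainId),
      frameSource = frame@source)
}

#' Distal-15-mm classifier features
#'
#' Linear interpolation of the 0.5-mm profile at 0.5, 1.5, ..., 14.5 mm
#' from the tip. Drains shorter than 15 mm are zero-padded beyond their
#' extent and flagged.
#'
#' @param profile a [CoverageProfile-class].
#' @return a [ProfileFeatures-class] (15 values plus a short-drain flag).
#' @export
profileFeatures <- function(profile) {
  stopifnot(is(profile, "CoverageProfile"))
  xout <- seq(0.5, 14.5, by = 1)
  pos <- profile@positions
  val <- profile@values
  if (length(pos) >= 2) {
    y <- approx(pos, val, xout = xout, rule = 1)$y
  } else {
    y <- rep(NA_real_, length(xout))
    y[xout <= max(pos, 0)] <- val[1]
  }
  short <- anyNA(y)
  y[is.na(y)] <- 0
  new("ProfileFeatures", values = y, shortDrain = short)
}

#' Run detection and quantification end to end
#'
#' Detects drain objects at `tDetect`, extends each to its
#' `tQuant`-component, binarizes the ICH at `tIch` and computes one
#' coverage profile per detected object.
#'
#' @param drainProb,ichProb co-registered probability volumes.
#' @param tDetect detection threshold (default 0.9).
#' @param tQuant quantification threshold (default 0.44).
#' @param tIch ICH binarization threshold (default 0.5).
#' @param connectivity component connectivity (default 26).
#' @return list of [CoverageProfile-class], one per detected object.
#' @export
quantifyDrains <- function(drainProb, ichProb, tDetect = 0.9, tQuant = 0.44,
                           tIch = 0.5, connectivity = 26) {
  stopifnot(is(drainProb, "ProbabilityVolume"), is(ichProb, "ProbabilityVolume"))
  .checkSameGrid(drainProb, ichProb)
  comps <- labelComponents(thresholdVolume(drainProb, tDetect),
                           connectivity = connectivity, prob = drainProb)
  ichMask <- thresholdVolume(ichProb, tIch)
  lapply(seq_len(nComponents(comps)), function(id) {
    qmask <- extractQuantificationMask(drainProb, comps, id, tQuant)
    coverageProfile(qmask, ichMask, drainId = id)
  })
}
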