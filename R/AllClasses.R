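#' @include neurodrain-package.R
NULL

# --- volumes ----------------------------------------------------------------

#' Virtual base class for 3D image volumes
#'
#' Carries a 3D data grid, per-axis voxel spacing in mm and a 4x4
#' voxel-to-world affine (RAS mm, 0-based voxel indices, NIfTI sform
#' convention).
#'
#' @slot data 3D array.
#' @slot spacing numeric(3), voxel edge lengths in mm, strictly positive.
#' @slot affine 4x4 voxel-to-world matrix.
#' @exportClass ImageVolume
setClass("ImageVolume", representation("VIRTUAL",
  data = "array", spacing = "numeric", affine = "matrix"))

.validImageVolume <- function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (!all(dim(object@affine) == c(4L, 4L)) || any(!is.finite(object@affine)))
    msg <- c(msg, "affine must be a finite 4x4 matrix")
  else if (abs(det(object@affine[1:3, 1:3])) < 1e-12)
    msg <- c(msg, "degenerate affine (zero determinant)")
  if (length(msg)) msg else TRUE
}
setValidity("ImageVolume", .validImageVolume)

#' 3D probability volume
#'
#' A scalar grid with values in \[0, 1\] — the voxelwise output of a
#' segmentation model (e.g. drain or ICH probability).
#'
#' @slot data 3D numeric array with values in \[0, 1\].
#' @inheritSection ImageVolume-class Slots
#' @exportClass ProbabilityVolume
setClass("ProbabilityVolume", contains = "ImageVolume")

setValidity("ProbabilityVolume", function(object) {
  v <- object@data
  if (any(!is.finite(v))) return("values must be finite")
  if (min(v) < 0 || max(v) > 1) return("values must lie in [0, 1]")
  TRUE
})

#' 3D binary mask
#'
#' @slot data 3D logical array.
#' @exportClass BinaryMask
setClass("BinaryMask", contains = "ImageVolume")

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@data)) return("data must be logical")
  if (anyNA(object@data)) return("data must not contain NA")
  TRUE
})

#' Volume of touch
#'
#' The subset of drain voxels whose spatially nearest non-drain voxel
#' belongs to the ICH rather than to the background — the contact
#' construct underlying the coverage profile.
#'
#' @slot parentDrain integer id of the drain object the volume belongs to.
#' @exportClass TouchVolume
setClass("TouchVolume", contains = "BinaryMask",
  representation(parentDrain = "integer"))

.defaultAffine <- function(spacing) {
  a <- diag(c(spacing, 1))
  a
}

#' Construct a ProbabilityVolume
#'
#' @param data 3D numeric array in \[0, 1\].
#' @param spacing voxel size in mm (length 3).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a
#'   diagonal RAS affine built from `spacing` with origin 0.
#' @return A [ProbabilityVolume-class] object.
#' @export
ProbabilityVolume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) affine <- .defaultAffine(spacing)
  new("ProbabilityVolume", data = data, spacing = as.numeric(spacing),
      affine = affine)
}

#' Construct a BinaryMask
#'
#' @inheritParams ProbabilityVolume
#' @param data 3D logical array (numeric input is coerced via `!= 0`).
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) affine <- .defaultAffine(spacing)
  if (!is.logical(data)) {
    d <- dim(data)
    data <- array(data != 0, d)
  }
  new("BinaryMask", data = data, spacing = as.numeric(spacing), affine = affine)
}

# --- detection --------------------------------------------------------------

#' Discrete connected components of a binary mask
#'
#' @slot labels 3D integer array, 0 = background, 1..K = objects.
#' @slot sizes per-object voxel counts.
#' @slot maxProb per-object maximum source probability (NA when the
#'   component set was built without a probability volume).
#' @slot connectivity 6, 18 or 26.
#' @exportClass ComponentSet
setClass("ComponentSet", representation(
  labels = "array", sizes = "integer", maxProb = "numeric",
  connectivity = "integer", spacing = "numeric", affine = "matrix"))

setValidity("ComponentSet", function(object) {
  k <- length(object@sizes)
  if (length(object@maxProb) != k) return("sizes and maxProb lengths differ")
  if (k > 0 && any(object@sizes < 1L)) return("object sizes must be >= 1")
  lab <- object@labels
  if (k > 0 && max(lab) != k) return("labels must be contiguous 1..K")
  TRUE
})

#' Detection outcome over the baseline object universe
#'
#' One row per discrete object found at the baseline threshold, with its
#' ground-truth label ("drain" if it shares at least one voxel with the GT
#' drain mask, else "noise") and its maximum probability, from which
#' retention at any higher threshold is judged.
#'
#' @slot objects data.frame with columns id, size, max_prob, gt_label,
#'   n_gt_drains (number of distinct GT drains mapping onto the object; a
#'   value >= 2 flags touching drains merged into a single object).
#' @slot baseline the threshold that defined the object universe.
#' @exportClass DetectionOutcome
setClass("DetectionOutcome", representation(
  objects = "data.frame", baseline = "numeric"))

setValidity("DetectionOutcome", function(object) {
  need <- c("id", "size", "max_prob", "gt_label", "n_gt_drains")
  if (!all(need %in% names(object@objects)))
    return(paste("objects must have columns:", paste(need, collapse = ", ")))
  if (!all(object@objects$gt_label %in% c("drain", "noise")))
    return("gt_label must be 'drain' or 'noise'")
  TRUE
})

# --- coverage ---------------------------------------------------------------

#' Principal-axis frame of a weighted voxel set
#'
#' Centroid and eigensystem of the 3x3 second central moment tensor of the
#' world coordinates, weighted by the voxel weights. The leading
#' eigenvector defines the profile axis.
#'
#' @slot centroid world mm.
#' @slot axes 3x3 matrix; columns e1, e2, e3 (orthonormal, descending
#'   eigenvalue order).
#' @slot eigenvalues mm^2, descending.
#' @slot source "touch_volume" or "drain_fallback".
#' @exportClass PrincipalFrame
setClass("PrincipalFrame", representation(
  centroid = "numeric", axes = "matrix", eigenvalues = "numeric",
  source = "character"))

setValidity("PrincipalFrame", function(object) {
  if (max(abs(crossprod(object@axes) - diag(3))) > 1e-8)
    return("axes must be orthonormal")
  if (is.unsorted(rev(object@eigenvalues)))
    return("eigenvalues must be sorted descending")
  TRUE
})

#' Drain coverage profile
#'
#' Relative covered cross-sectional area (volume of touch over total drain,
#' per slab orthogonal to the principal axis) as a function of distance
#' from the drain tip, sampled at 0.5-mm steps.
#'
#' @slot positions mm from the tip, ascending from 0.
#' @slot values relative covered area in \[0, 1\].
#' @slot tipWorld tip location, world mm.
#' @slot axis unit vector pointing tip -> entry.
#' @slot drainId originating object id.
#' @slot frameSource "touch_volume" or "drain_fallback".
#' @exportClass CoverageProfile
setClass("CoverageProfile", representation(
  positions = "numeric", values = "numeric", tipWorld = "numeric",
  axis = "numeric", drainId = "integer", frameSource = "character"))

setValidity("CoverageProfile", function(object) {
  if (length(object@positions) != length(object@values))
    return("positions and values lengths differ")
  if (length(object@positions) && object@positions[1] != 0)
    return("positions must start at 0")
  if (length(object@values) &&
      (min(object@values) < 0 || max(object@values) > 1))
    return("values must lie in [0, 1]")
  TRUE
})

#' Classifier features from the distal 15 mm of a coverage profile
#'
#' @slot values 15 coverage values at 1-mm steps from the tip.
#' @slot shortDrain TRUE when the drain is shorter than 15 mm and the
#'   feature vector was zero-padded.
#' @exportClass ProfileFeatures
setClass("ProfileFeatures", representation(
  values = "numeric", shortDrain = "logical"))

setValidity("ProfileFeatures", function(object) {
  if (length(object@values) != 15L) return("exactly 15 feature values required")
  if (min(object@values) < 0 || max(object@values) > 1)
    return("feature values must lie in [0, 1]")
  TRUE
})

# --- classifier -------------------------------------------------------------

#' Per-feature centering/scaling learned on training data
#'
#' @slot center per-feature means.
#' @slot scale per-feature standard deviations (n-1 denominator); values
#'   below 1e-12 are replaced by 1 so constant features map to 0.
#' @exportClass FeatureScaler
setClass("FeatureScaler", representation(center = "numeric", scale = "numeric"))

#' L2-penalized logistic regression model for drain position
#'
#' Minimizes mean binomial deviance plus `lambda * ||w||^2` (intercept
#' unpenalized) on standardized features. The positive class is the
#' malposition ("not correct") by default.
#'
#' @slot weights coefficient vector on the standardized scale.
#' @slot intercept scalar.
#' @slot lambda L2 penalty, >= 0.
#' @slot scaler the [FeatureScaler-class] fitted on training data.
#' @slot decisionThreshold probability cut for the positive class.
#' @slot positiveClass,negativeClass label strings.
#' @slot gradNorm norm of the penalized gradient at the solution.
#' @slot converged logical.
#' @exportClass PenalizedLogisticModel
setClass("PenalizedLogisticModel", representation(
  weights = "numeric", intercept = "numeric", lambda = "numeric",
  scaler = "FeatureScaler", decisionThreshold = "numeric",
  positiveClass = "character", negativeClass = "character",
  gradNorm = "numeric", converged = "logical"))

setValidity("PenalizedLogisticModel", function(object) {
  if (any(!is.finite(c(object@weights, object@intercept, object@lambda))))
    return("parameters must be finite")
  if (object@lambda < 0) return("lambda must be >= 0")
  TRUE
})

#' Leave-one-out tuning result
#'
#' @slot grid candidate lambda values.
#' @slot auc pooled leave-one-out AUC per candidate.
#' @slot selected the winning lambda (ties broken toward larger lambda).
#' @slot model the final model refit on all data at `selected`.
#' @exportClass TuningResult
setClass("TuningResult", representation(
  grid = "numeric", auc = "numeric", selected = "numeric",
  model = "PenalizedLogisticModel"))

# --- phantom ----------------------------------------------------------------

#' Specification of a synthetic drain/ICH phantom
#'
#' @slot dim grid size in voxels.
#' @slot spacing voxel size, mm.
#' @slot tip drain tip, world mm.
#' @slot direction unit vector tip -> entry.
#' @slot radius,length drain cylinder dimensions, mm.
#' @slot ich list describing the hemorrhage: `list(type = "ellipsoid",
#'   center =, semiaxes =)`, `list(type = "half_space", point =, normal =)`,
#'   or `list(type = "none")`.
#' @slot embeddedFraction fraction f of the drain (from the tip) inside a
#'   half-space ICH; NA unless the half-space was built from f.
#' @slot blurSigma Gaussian blur of the probability maps, mm.
#' @slot noiseSd additive Gaussian noise SD (clipped to \[0,1\]).
#' @slot distractors list of `list(center =, radius =, prob =)` blobs added
#'   to the drain probability map only (bone-fragment / calcification
#'   surrogates).
#' @slot seed RNG seed for the noise.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  dim = "integer", spacing = "numeric", tip = "numeric",
  direction = "numeric", radius = "numeric", length = "numeric",
  ich = "list", embeddedFraction = "numeric", blurSigma = "numeric",
  noiseSd = "numeric", distractors = "list", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!is.na(object@embeddedFraction) &&
      (object@embeddedFraction < 0 || object@embeddedFraction > 1))
    msg <- c(msg, "embeddedFraction must lie in [0, 1]")
  if (object@radius >= object@length / 4)
    msg <- c(msg, "radius must be < length/4")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
    msg <- c(msg, "direction must be a unit vector")
  # cylinder must fit inside the grid with >= 2 mm margin at the tip
  extent <- (object@dim - 1) * object@spacing
  entry <- object@tip + object@length * object@direction
  for (p in list(object@tip, entry)) {
    if (any(p < -1e-9) || any(p > extent + 1e-9))
      msg <- c(msg, "drain endpoints must lie inside the grid")
  }
  if (min(object@tip, extent - object@tip) < 2)
    msg <- c(msg, "tip must keep a >= 2 mm margin to every volume face")
  if (length(msg)) msg else TRUE
})

#' A generated phantom with analytic truth
#'
#' @slot drainProb,ichProb probability volumes.
#' @slot gtDrain,gtIch ground-truth binary masks (drain-wins on overlap).
#' @slot truthProfile analytic coverage profile.
#' @slot truthTip true tip, world mm.
#' @slot truthLabel "correct" or "not correct" (distal-coverage rule).
#' @slot spec the generating [PhantomSpec-class].
#' @exportClass PhantomCase
setClass("PhantomCase", representation(
  drainProb = "ProbabilityVolume", ichProb = "ProbabilityVolume",
  gtDrain = "BinaryMask", gtIch = "BinaryMask",
  truthProfile = "CoverageProfile", truthTip = "numeric",
  truthLabel = "character", spec = "PhantomSpec"))
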