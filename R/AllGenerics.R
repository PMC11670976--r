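#' @include AllClasses.R
NULL

#' Access the voxel data array
#' @param x an [ImageVolume-class] (or ComponentSet label grid).
#' @return the underlying 3D array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Access the voxel spacing in mm
#' @param x an image-like object.
#' @return numeric(3).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Access the voxel-to-world affine
#' @param x an image-like object.
#' @return 4x4 matrix (0-based voxel index to world mm).
#' @export
setGeneric("worldAffine", function(x) standardGeneric("worldAffine"))

#' Number of discrete objects
#' @param x a [ComponentSet-class].
#' @return integer count.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Resample a volume onto an isotropic grid
#'
#' @param vol an [ImageVolume-class].
#' @param targetMm target isotropic voxel size in mm.
#' @param interp "linear" or "nearest" (binary masks always use nearest).
#' @return an object of the same class on the new grid; the world extent
#'   and direction cosines are preserved.
#' @export
setGeneric("resampleIsotropic",
  function(vol, targetMm, interp = "linear") standardGeneric("resampleIsotropic"))

#' Profile positions (mm from tip)
#' @param x a [CoverageProfile-class].
#' @return numeric vector.
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))

#' Profile coverage values
#' @param x a [CoverageProfile-class].
#' @return numeric vector in \[0, 1\].
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

setMethod("voxelData", "ImageVolume", function(x) x@data)
setMethod("voxelData", "ComponentSet", function(x) x@labels)
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
setMethod("voxelSpacing", "ComponentSet", function(x) x@spacing)
setMethod("worldAffine", "ImageVolume", function(x) x@affine)
setMethod("worldAffine", "ComponentSet", function(x) x@affine)
setMethod("nComponents", "ComponentSet", function(x) length(x@sizes))
setMethod("profilePositions", "CoverageProfile", function(x) x@positions)
setMethod("profileValues", "CoverageProfile", function(x) x@values)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(class(object), sprintf("%d x %d x %d voxels, spacing %s mm\n",
      d[1], d[2], d[3],
      paste(format(object@spacing, digits = 3), collapse = " x ")))
  if (is(object, "ProbabilityVolume"))
    cat(sprintf("  value range [%.3f, %.3f]\n",
        min(object@data), max(object@data)))
  if (is(object, "BinaryMask"))
    cat(sprintf("  %d foreground voxels\n", sum(object@data)))
  invisible(NULL)
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf("ComponentSet: %d object(s), %d-connectivity\n",
      nComponents(object), object@connectivity))
  if (nComponents(object) > 0) {
    cat("  sizes:", paste(utils::head(object@sizes, 8), collapse = ", "),
        if (nComponents(object) > 8) "..." else "", "\n")
  }
  invisible(NULL)
})

setMethod("show", "DetectionOutcome", function(object) {
  tab <- table(object@objects$gt_label)
  cat(sprintf("DetectionOutcome: %d object(s) at baseline %.2f (%s)\n",
      nrow(object@objects), object@baseline,
      paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "CoverageProfile", function(object) {
  cat(sprintf(
    "CoverageProfile (drain %d): %d samples over %.1f mm, mean %.3f, frame = %s\n",
    object@drainId, length(object@values),
    if (length(object@positions)) max(object@positions) else 0,
    if (length(object@values)) mean(object@values) else NA_real_,
    object@frameSource))
  invisible(NULL)
})

setMethod("show", "PenalizedLogisticModel", function(object) {
  cat(sprintf(
    "PenalizedLogisticModel: %d features, lambda = %.6g, positive = '%s'\n",
    length(object@weights), object@lambda, object@positiveClass))
  cat(sprintf("  |grad| = %.2e, converged = %s\n",
      object@gradNorm, object@converged))
  invisible(NULL)
})

setMethod("show", "TuningResult", function(object) {
  cat(sprintf(
    "TuningResult: %d candidates, selected lambda = %.6g (LOOCV AUC %.3f)\n",
    length(object@grid), object@selected,
    max(object@auc)))
  invisible(NULL)
})

setMethod("show", "PhantomCase", function(object) {
  cat(sprintf("PhantomCase: %s ICH, truth label '%s', tip (%s) mm\n",
      object@spec@ich$type, object@truthLabel,
      paste(format(object@truthTip, digits = 3), collapse = ", ")))
  invisible(NULL)
})
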