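#' @include volumes-io.R
NULL

#' Label discrete objects in a binary mask
#'
#' Connected-component labelling with 6-, 18- or 26-connectivity
#' (default 26: thin oblique drains fragment under 6-connectivity at 1 mm).
#' Labels are contiguous 1..K in raster-scan order of each component's
#' first voxel.
#'
#' @param mask a [BinaryMask-class].
#' @param connectivity 6, 18 or 26.
#' @param prob optional [ProbabilityVolume-class] on the same grid; when
#'   supplied, the per-object maximum probability is recorded (needed to
#'   judge retention at higher thresholds).
#' @return a [ComponentSet-class].
#' @export
labelComponents <- function(mask, connectivity = 26, prob = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  lab <- cc_label_3d(as.vector(mask@data), dim(mask@data), connectivity)
  k <- max(lab)
  sizes <- if (k > 0) as.integer(tabulate(lab[lab > 0L], nbins = k)) else integer()
  maxp <- rep(NA_real_, k)
  if (!is.null(prob) && k > 0) {
    .checkSameGrid(mask, prob)
    fg <- lab > 0L
    maxp <- as.numeric(tapply(prob@data[fg], lab[fg], max))
  }
  new("ComponentSet", labels = lab, sizes = sizes, maxProb = maxp,
      connectivity = connectivity, spacing = mask@spacing,
      affine = mask@affine)
}

#' Label detected objects drain/noise against a ground-truth mask
#'
#' An object is a "drain" iff it shares at least one voxel with the GT
#' drain mask, else "noise". When two or more distinct GT drains map onto
#' one object (touching drains merged into a single component) the
#' object's `n_gt_drains` column flags it.
#'
#' @param components a [ComponentSet-class] built at the baseline
#'   threshold, with per-object max probabilities.
#' @param gtDrain GT drain [BinaryMask-class] on the same grid.
#' @param baseline the threshold that defined the object universe
#'   (default 0.5).
#' @return a [DetectionOutcome-class].
#' @export
assignGtLabels <- function(components, gtDrain, baseline = 0.5) {
  stopifnot(is(components, "ComponentSet"), is(gtDrain, "BinaryMask"))
  if (!identical(dim(components@labels), dim(gtDrain@data)))
    stop("component labels and GT mask must share the same grid")
  k <- nComponents(components)
  lab <- components@labels
  gt <- gtDrain@data
  gtlab <- cc_label_3d(as.vector(gt), dim(gt), components@connectivity)
  overlap <- logical(k)
  ngt <- integer(k)
  if (k > 0) {
    fg <- lab > 0L & gt
    if (any(fg)) {
      byobj <- split(gtlab[fg], lab[fg])
      ids <- as.integer(names(byobj))
      overlap[ids] <- TRUE
      ngt[ids] <- vapply(byobj, function(g) length(unique(g)), integer(1))
    }
  }
  objects <- data.frame(
    id = seq_len(k),
    size = components@sizes,
    max_prob = components@maxProb,
    gt_label = ifelse(overlap, "drain", "noise"),
    n_gt_drains = ngt,
    stringsAsFactors = FALSE)
  new("DetectionOutcome", objects = objects, baseline = baseline)
}

#' Detection accuracy at one threshold over the baseline object universe
#'
#' An object is retained at `t` iff its maximum probability is `>= t`;
#' retained drains are true positives, suppressed noise objects true
#' negatives. Proportions come with exact (Clopper-Pearson) 95% CIs.
#'
#' @param outcome a [DetectionOutcome-class] built on the baseline universe.
#' @param t evaluation threshold.
#' @return a list with `threshold`, `counts` (TP, FN, TN, FP) and
#'   `accuracy`/`sensitivity`/`specificity`, each `list(est, lower, upper)`.
#' @export
evaluateThreshold <- function(outcome, t) {
  stopifnot(is(outcome, "DetectionOutcome"))
  obj <- outcome@objects
  if (nrow(obj) == 0L) stop("empty object universe")
  retained <- obj$max_prob >= t
  isDrain <- obj$gt_label == "drain"
  cm <- confusionMetrics(retained, isDrain)
  c(list(threshold = t), cm)
}

#' Sweep detection thresholds and find the 100%-accuracy interval(s)
#'
#' Evaluates the baseline object universe at every threshold in
#' `thresholds` and reports maximal runs of consecutive thresholds with
#' accuracy 1.
#'
#' @inheritParams evaluateThreshold
#' @param thresholds sweep grid (default 0.5 to 0.99 in steps of 0.01).
#' @return list with `table` (one row per threshold: counts and point
#'   estimates) and `perfectIntervals` (list of `c(low, high)`).
#' @export
detectionSweep <- function(outcome, thresholds = seq(0.5, 0.99, by = 0.01)) {
  rows <- lapply(thresholds, function(t) {
    m <- evaluateThreshold(outcome, t)
    data.frame(threshold = t,
               TP = m$counts[["TP"]], FN = m$counts[["FN"]],
               TN = m$counts[["TN"]], FP = m$counts[["FP"]],
               accuracy = m$accuracy$est,
               sensitivity = m$sensitivity$est,
               specificity = m$specificity$est)
  })
  tab <- do.call(rbind, rows)
  perfect <- tab$accuracy >= 1 - 1e-12
  intervals <- list()
  r <- rle(perfect)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values))
    if (r$values[i])
      intervals[[length(intervals) + 1L]] <-
        c(tab$threshold[starts[i]], tab$threshold[ends[i]])
  list(table = tab, perfectIntervals = intervals)
}

#' Detect drains in a probability volume
#'
#' Builds the baseline object universe (components of the
#' baseline-thresholded mask with per-object max probabilities) and, when
#' a GT mask is given, the labelled detection outcome.
#'
#' @param drainProb drain [ProbabilityVolume-class].
#' @param gtDrain optional GT drain [BinaryMask-class].
#' @param baseline universe-defining threshold (default 0.5).
#' @param connectivity component connectivity (default 26).
#' @return list with `components` ([ComponentSet-class]) and `outcome`
#'   ([DetectionOutcome-class] or NULL).
#' @export
detectDrains <- function(drainProb, gtDrain = NULL, baseline = 0.5,
                         connectivity = 26) {
  comps <- labelComponents(thresholdVolume(drainProb, baseline),
                           connectivity = connectivity, prob = drainProb)
  outcome <- NULL
  if (!is.null(gtDrain))
    outcome <- assignGtLabels(comps, gtDrain, baseline = baseline)
  list(components = comps, outcome = outcome)
}
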