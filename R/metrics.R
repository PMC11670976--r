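#' @include classifier.R
NULL

#' Intraclass correlation ICC(2,1): two-way random effects, single
#' measure, absolute agreement
#'
#' Computed from the two-way ANOVA mean squares (subjects x raters) with
#' the F-based 95% confidence interval of Shrout & Fleiss. This is the
#' agreement statistic used to compare predicted and ground-truth
#' coverage profiles.
#'
#' @param x,y paired measurements (rater 1 and rater 2), length n >= 3.
#' @param conf confidence level (default 0.95).
#' @return list with `value`, `lower`, `upper`, `n`, `k`.
#' @export
icc21 <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  m <- cbind(as.numeric(x), as.numeric(y))
  if (anyNA(m)) stop("missing values not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop("need at least 3 pairs")
  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  SSR <- k * sum((rowm - grand)^2)
  SSC <- n * sum((colm - grand)^2)
  SSE <- sum((m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2)
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + (k / n) * (MSC - MSE)
  if (MSR < 1e-12 * max(MSE, 1e-300) || abs(denom) < 1e-300) {
    warning("zero between-subject variance; ICC undefined, returning 0")
    return(list(value = 0, lower = NA_real_, upper = NA_real_, n = n, k = k))
  }
  icc <- (MSR - MSE) / denom
  if (MSE < 1e-300) {
    # zero error variance (e.g. exact offset); F-based CI undefined
    return(list(value = icc, lower = NA_real_, upper = NA_real_, n = n, k = k))
  }
  alpha <- 1 - conf
  Fj <- MSC / MSE
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * Fj + b)^2 / ((a * Fj)^2 / (k - 1) + b^2 / (n - 1))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(value = icc, lower = lower, upper = upper, n = n, k = k)
}

#' Bland-Altman agreement with limits-of-agreement outliers
#'
#' Differences d = x - y; bias = mean(d); limits of agreement
#' bias +/- 1.96 SD(d) (n-1 denominator); a pair is an outlier when its
#' difference falls outside the limits.
#'
#' @param x,y paired measurements, length n >= 3.
#' @return list with `bias`, `sd`, `loaLower`, `loaUpper`,
#'   `outlierCount`, `outlierFraction`, `n`.
#' @export
blandAltman <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- as.numeric(x) - as.numeric(y)
  if (length(d) < 3L) stop("need at least 3 pairs")
  bias <- mean(d)
  s <- sd(d)
  out <- abs(d - bias) > 1.96 * s
  list(bias = bias, sd = s,
       loaLower = bias - 1.96 * s, loaUpper = bias + 1.96 * s,
       outlierCount = sum(out), outlierFraction = mean(out), n = length(d))
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for n subjects rated by k raters into
#' categorical classes; the standard Fleiss formula over category
#' proportions.
#'
#' @param ratings n x k matrix (or data.frame) of categorical ratings,
#'   no missing cells.
#' @return scalar kappa.
#' @export
fleissKappa <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("missing ratings not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  cats <- sort(unique(as.vector(m)))
  counts <- vapply(cats, function(cc) rowSums(m == cc),
                   numeric(n))
  counts <- matrix(counts, nrow = n)
  Pi <- (rowSums(counts^2) - k) / (k * (k - 1))
  Pbar <- mean(Pi)
  pj <- colSums(counts) / (n * k)
  Pe <- sum(pj^2)
  if (abs(1 - Pe) < 1e-12)
    stop("all ratings fall in a single category; kappa undefined")
  (Pbar - Pe) / (1 - Pe)
}

.propCI <- function(xct, nct, conf = 0.95) {
  if (nct == 0) return(list(est = NA_real_, lower = NA_real_, upper = NA_real_,
                            x = xct, n = nct))
  ci <- binom.test(xct, nct, conf.level = conf)$conf.int
  list(est = xct / nct, lower = ci[1], upper = ci[2], x = xct, n = nct)
}

#' Confusion-matrix metrics with exact binomial confidence intervals
#'
#' Accuracy, sensitivity and specificity as proportions with
#' Clopper-Pearson 95% CIs. Entries whose denominator class is absent
#' are returned as NA.
#'
#' @param pred,truth logical vectors (TRUE = positive class).
#' @param conf confidence level (default 0.95).
#' @return list with `counts` (TP, FN, TN, FP) and `accuracy`,
#'   `sensitivity`, `specificity`, each `list(est, lower, upper, x, n)`.
#' @export
confusionMetrics <- function(pred, truth, conf = 0.95) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  stopifnot(length(pred) == length(truth))
  if (length(pred) == 0L) stop("empty input")
  TP <- sum(pred & truth); FN <- sum(!pred & truth)
  TN <- sum(!pred & !truth); FP <- sum(pred & !truth)
  list(counts = c(TP = TP, FN = FN, TN = TN, FP = FP),
       accuracy = .propCI(TP + TN, TP + FN + TN + FP, conf),
       sensitivity = .propCI(TP, TP + FN, conf),
       specificity = .propCI(TN, TN + FP, conf))
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC is the Mann-Whitney statistic (ties counted 1/2); the CI follows
#' DeLong et al., as implemented in pROC.
#'
#' @param scores numeric scores, larger = more positive.
#' @param truth logical (or 0/1) class labels.
#' @param conf confidence level (default 0.95).
#' @return list with `auc`, `lower`, `upper`, `n`.
#' @export
rocAuc <- function(scores, truth, conf = 0.95) {
  truth <- as.logical(truth)
  if (length(unique(truth)) < 2L)
    stop("both classes must be present to compute an AUC")
  r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- tryCatch(suppressWarnings(
    as.numeric(pROC::ci.auc(r, conf.level = conf, method = "delong"))),
    error = function(e) rep(NA_real_, 3))
  list(auc = as.numeric(pROC::auc(r)), lower = ci[1], upper = ci[3],
       n = length(truth))
}
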