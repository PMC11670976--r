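#' @include metrics.R
NULL

#' Specify a synthetic drain/ICH phantom
#'
#' A cylindrical drain (default radius 1.5 mm, a typical external drain
#' caliber; default length 60 mm) inside a grid, with an ellipsoidal or
#' half-space hemorrhage at controlled overlap, optional blur, noise and
#' distractor blobs (surrogates for the bone fragments and calcifications
#' that cause false positive detections).
#'
#' Rather than giving the half-space plane explicitly, `embeddedFraction`
#' places the plane perpendicular to the drain at `f * length` from the
#' tip, with the ICH on the tip side — so the analytic truth profile is 1
#' on the embedded fraction and 0 elsewhere.
#'
#' @param dim grid size in voxels (default 81 x 29 x 29).
#' @param spacing voxel size in mm (default 1 mm isotropic, the pipeline's
#'   working resolution).
#' @param tip drain tip in world mm.
#' @param direction unit vector tip -> entry.
#' @param radius,length cylinder radius / length in mm.
#' @param ich `list(type = "ellipsoid", center =, semiaxes =)`,
#'   `list(type = "half_space", point =, normal =)` or
#'   `list(type = "none")`. Ignored when `embeddedFraction` is given.
#' @param embeddedFraction f in \[0, 1\]: fraction of the drain (from the
#'   tip) embedded in a half-space ICH; f = 0 means no contact.
#' @param blurSigma Gaussian blur SD in mm applied to both probability
#'   maps (0 = crisp binary maps).
#' @param noiseSd additive Gaussian noise SD, clipped to \[0, 1\].
#' @param distractors list of `list(center =, radius =, prob =)` blobs
#'   added to the drain probability map only.
#' @param seed RNG seed for the noise (default 20240101).
#' @return a validated [PhantomSpec-class].
#' @export
phantomSpec <- function(dim = c(81L, 29L, 29L), spacing = c(1, 1, 1),
                        tip = c(64, 14, 14), direction = c(-1, 0, 0),
                        radius = 1.5, length = 60,
                        ich = list(type = "none"),
                        embeddedFraction = NA_real_,
                        blurSigma = 0, noiseSd = 0,
                        distractors = list(), seed = 20240101) {
  direction <- direction / sqrt(sum(direction^2))
  if (!is.na(embeddedFraction)) {
    # f = 0 means no contact at all, not a half-space grazing the tip
    ich <- if (embeddedFraction == 0) list(type = "none") else
      list(type = "half_space",
           point = tip + embeddedFraction * length * direction,
           normal = direction)
  }
  new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
      tip = as.numeric(tip), direction = as.numeric(direction),
      radius = radius, length = length, ich = ich,
      embeddedFraction = as.numeric(embeddedFraction),
      blurSigma = blurSigma, noiseSd = noiseSd,
      distractors = distractors, seed = as.integer(seed))
}

# world coordinates of every voxel of the phantom grid (n x 3)
.gridCoords <- function(spec) {
  d <- spec@dim; sp <- spec@spacing
  cx <- (seq_len(d[1]) - 1) * sp[1]
  cy <- (seq_len(d[2]) - 1) * sp[2]
  cz <- (seq_len(d[3]) - 1) * sp[3]
  cbind(rep(cx, times = d[2] * d[3]),
        rep(rep(cy, each = d[1]), times = d[3]),
        rep(cz, each = d[1] * d[2]))
}

.rasterCylinder <- function(xyz, tip, dir, radius, len) {
  rel <- sweep(xyz, 2, tip)
  t <- as.vector(rel %*% dir)
  r2 <- rowSums(rel^2) - t^2
  t >= 0 & t <= len & r2 <= radius^2
}

.rasterIch <- function(xyz, ich) {
  switch(ich$type,
    none = rep(FALSE, nrow(xyz)),
    half_space = {
      rel <- sweep(xyz, 2, as.numeric(ich$point))
      as.vector(rel %*% as.numeric(ich$normal)) <= 0
    },
    ellipsoid = {
      rel <- sweep(sweep(xyz, 2, as.numeric(ich$center)), 2,
                   as.numeric(ich$semiaxes), "/")
      rowSums(rel^2) <= 1
    },
    stop("unsupported ICH geometry: ", ich$type))
}

#' Generate a phantom case
#'
#' Rasterizes the cylinder and the ICH region (drain-wins on overlap for
#' the GT masks), blurs and adds seeded clipped Gaussian noise to build
#' the probability maps, adds distractor blobs to the drain map only, and
#' attaches the analytic truth profile, tip and position label. The label
#' rule is transparent and synthetic: "correct" iff the mean truth
#' coverage over the distal 15 mm is >= 0.5 (it makes no claim to match
#' radiologists' judgment).
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomCase-class]; identical seeds give identical volumes.
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@dim
  xyz <- .gridCoords(spec)
  drain <- array(.rasterCylinder(xyz, spec@tip, spec@direction,
                                 spec@radius, spec@length), d)
  ichRaw <- array(.rasterIch(xyz, spec@ich), d)
  gtIch <- ichRaw & !drain   # drain-wins
  aff <- .defaultAffine(spec@spacing)

  blur <- function(x) {
    x <- array(as.numeric(x), d)
    if (spec@blurSigma > 0) {
      ks <- lapply(1:3, function(a)
        .gaussKernel(spec@blurSigma * 2 * sqrt(2 * log(2)), spec@spacing[a]))
      x <- array(conv_sep_3d(as.vector(x), d, ks[[1]], ks[[2]], ks[[3]]), d)
    }
    x
  }
  drainP <- blur(drain)
  ichP <- blur(ichRaw)

  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(spec@seed)
  if (spec@noiseSd > 0) {
    drainP <- drainP + array(rnorm(prod(d), 0, spec@noiseSd), d)
    ichP <- ichP + array(rnorm(prod(d), 0, spec@noiseSd), d)
  }
  drainP <- pmin(pmax(drainP, 0), 1)
  ichP <- pmin(pmax(ichP, 0), 1)
  for (b in spec@distractors) {
    rel <- sweep(xyz, 2, as.numeric(b$center))
    inside <- array(rowSums(rel^2) <= b$radius^2, d)
    drainP[inside] <- pmax(drainP[inside], b$prob)
  }

  truth <- analyticProfile(spec)
  distal <- truth@positions <= 15
  label <- if (mean(truth@values[distal]) >= 0.5) "correct" else "not correct"

  new("PhantomCase",
      drainProb = ProbabilityVolume(drainP, spec@spacing, aff),
      ichProb = ProbabilityVolume(ichP, spec@spacing, aff),
      gtDrain = BinaryMask(drain, spec@spacing, aff),
      gtIch = BinaryMask(gtIch, spec@spacing, aff),
      truthProfile = truth, truthTip = spec@tip, truthLabel = label,
      spec = spec)
}

#' Analytic truth profile of a phantom
#'
#' Closed-form coverage profile for the supported geometries: a cylinder
#' fully inside an ellipsoid (1 everywhere), a half-space at embedded
#' fraction f (1 on the f-fraction from the tip, 0 elsewhere), a cylinder
#' disjoint from the ICH (0 everywhere).
#'
#' @param spec a [PhantomSpec-class].
#' @return a [CoverageProfile-class] sampled at 0.5-mm steps from the tip
#'   over the full drain length.
#' @export
analyticProfile <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  pos <- seq(0, spec@length, by = 0.5)
  ich <- spec@ich
  vals <- if (ich$type == "none") {
    rep(0, length(pos))
  } else if (ich$type == "half_space") {
    # signed distance of axis point at `pos` from the plane, ICH side <= 0
    axpts <- outer(pos, spec@direction) +
      matrix(spec@tip, length(pos), 3, byrow = TRUE)
    s <- as.vector(sweep(axpts, 2, as.numeric(ich$point)) %*%
                     as.numeric(ich$normal))
    f <- if (!is.na(spec@embeddedFraction)) spec@embeddedFraction else NA
    if (!is.na(f) && f == 0) rep(0, length(pos)) else as.numeric(s <= 1e-9)
  } else if (ich$type == "ellipsoid") {
    # supported closed forms: fully inside, or fully disjoint
    tgrid <- seq(0, spec@length, by = 0.25)
    ang <- seq(0, 2 * pi, length.out = 17)[-17]
    perp <- .anyPerp(spec@direction)
    perp2 <- .cross3(spec@direction, perp)
    surf <- do.call(rbind, lapply(tgrid, function(t) {
      ctr <- spec@tip + t * spec@direction
      (outer(cos(ang), perp) + outer(sin(ang), perp2)) * spec@radius +
        matrix(ctr, length(ang), 3, byrow = TRUE)
    }))
    rel <- sweep(sweep(surf, 2, as.numeric(ich$center)), 2,
                 as.numeric(ich$semiaxes), "/")
    q <- rowSums(rel^2)
    if (all(q <= 1)) rep(1, length(pos))
    else if (all(q > 1)) rep(0, length(pos))
    else stop("unsupported geometry: cylinder partially inside ellipsoid")
  } else stop("unsupported ICH geometry: ", ich$type)
  new("CoverageProfile", positions = pos, values = vals,
      tipWorld = spec@tip, axis = spec@direction, drainId = 1L,
      frameSource = "analytic")
}

.anyPerp <- function(v) {
  u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- u - sum(u * v) * v
  w / sqrt(sum(w^2))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
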