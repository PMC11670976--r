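test_that("quantification mask extends the detected object, never shrinks it", {
  prob <- array(0, c(12, 5, 5))
  prob[3:9, 3, 3] <- c(0.5, 0.7, 0.95, 0.95, 0.95, 0.7, 0.5)
  pv <- probVol(prob)
  comps <- labelComponents(thresholdVolume(pv, 0.9), prob = pv)
  expect_equal(nComponents(comps), 1L)
  q <- extractQuantificationMask(pv, comps, 1L, tQuant = 0.44)
  expect_true(all(voxelData(q)[voxelData(comps) == 1L]))      # superset
  expect_equal(sum(voxelData(q)), 7L)                          # full 0.44 run
  # identical when the components coincide
  q9 <- extractQuantificationMask(pv, comps, 1L, tQuant = 0.9)
  expect_equal(sum(voxelData(q9)), 3L)
  # a noise object absent at 0.9 is never resurrected
  prob2 <- prob
  prob2[1, 1, 1] <- 0.6
  pv2 <- probVol(prob2)
  comps2 <- labelComponents(thresholdVolume(pv2, 0.9), prob = pv2)
  q2 <- extractQuantificationMask(pv2, comps2, 1L, tQuant = 0.44)
  expect_false(voxelData(q2)[1, 1, 1])
  expect_error(extractQuantificationMask(pv, comps, 99L), "empty")
})

test_that("touch volume: full embedding, empty ICH, and the exhaustive oracle", {
  # drain column fully surrounded by ICH -> V is the whole drain
  d <- c(7, 7, 7)
  drain <- array(FALSE, d); drain[3:5, 4, 4] <- TRUE
  ich <- array(TRUE, d); ich[drain] <- FALSE
  V <- computeTouchVolume(BinaryMask(drain, c(1, 1, 1)),
                          BinaryMask(ich, c(1, 1, 1)))
  expect_equal(voxelData(V), drain)
  # empty ICH -> empty V
  V0 <- computeTouchVolume(BinaryMask(drain, c(1, 1, 1)),
                           BinaryMask(array(FALSE, d), c(1, 1, 1)))
  expect_false(any(voxelData(V0)))
  # V is always a subset of the drain
  expect_true(all(drain[voxelData(V)]))
  # grid mismatch is refused
  expect_error(computeTouchVolume(BinaryMask(drain, c(1, 1, 1)),
                                  BinaryMask(array(FALSE, c(5, 5, 5)),
                                             c(1, 1, 1))),
               "grid")
})

test_that("touch volume matches exhaustive nearest-neighbour search on random grids", {
  set.seed(14)
  for (rep in 1:6) {
    d <- sample(6:12, 3, replace = TRUE)
    sp <- runif(3, 0.5, 2)
    drain <- array(runif(prod(d)) < 0.25, d)
    ich <- array(runif(prod(d)) < 0.2, d)
    if (!any(drain) || all(drain)) next
    V <- voxelData(computeTouchVolume(BinaryMask(drain, sp),
                                      BinaryMask(ich, sp)))
    want <- bruteTouchMembership(drain, ich, sp)
    comparable <- !is.na(want)
    expect_equal(V[comparable], want[comparable] == 1)
  }
})

test_that("principal frame recovers a line's direction and symmetry", {
  d <- c(9, 9, 9)
  w <- array(0, d); w[5, 5, 2:8] <- 1      # straight line along z
  pf <- principalFrame(ProbabilityVolume(w, c(1, 1, 1)))
  expect_equal(abs(pf@axes[, 1]), c(0, 0, 1), tolerance = 1e-10)
  expect_equal(pf@eigenvalues[2], pf@eigenvalues[3], tolerance = 1e-10)
  expect_equal(pf@centroid, c(4, 4, 4), tolerance = 1e-10)  # 0-based world
  # permuting the grid axes permutes the principal axis identically
  wp <- aperm(w, c(3, 1, 2))
  pfp <- principalFrame(ProbabilityVolume(wp, c(1, 1, 1)))
  expect_equal(abs(pfp@axes[, 1]), c(1, 0, 0), tolerance = 1e-10)
  # single voxel: zero tensor
  w1 <- array(0, d); w1[3, 3, 3] <- 2
  expect_error(principalFrame(ProbabilityVolume(w1 / 2, c(1, 1, 1))),
               "degenerate")
  expect_error(principalFrame(ProbabilityVolume(array(0, d), c(1, 1, 1))),
               "weight")
})

test_that("regrid-and-smooth: constancy, impulse response, edge width, mass", {
  # constant volume stays constant
  v <- probVol(rep(0.37, 8 * 8 * 8), dim = c(8, 8, 8))
  s <- regridAndSmooth(v)
  interior <- voxelData(s)[6:11, 6:11, 6:11]   # beyond the kernel radius
  expect_true(all(abs(interior - 0.37) < 1e-9))
  # unit impulse on a 0.5-mm grid -> separable integrated Gaussian
  d <- c(17, 17, 17)
  imp <- array(0, d); imp[9, 9, 9] <- 1
  vi <- ProbabilityVolume(imp, c(0.5, 0.5, 0.5))
  si <- regridAndSmooth(vi, targetMm = 0.5, fwhmMm = 1.0)
  sigma <- 1.0 / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(4 * sigma / 0.5))
  k <- pnorm(((-r:r) + 0.5) * 0.5, 0, sigma) - pnorm(((-r:r) - 0.5) * 0.5, 0, sigma)
  k <- k / sum(k)
  want1d <- rep(0, 17); want1d[9 + (-r:r)] <- k
  # separable response: along a line through the peak the 1D kernel is
  # modulated by the central weight of the two orthogonal kernels
  expect_equal(voxelData(si)[, 9, 9], want1d * k[r + 1]^2, tolerance = 1e-12)
  expect_equal(sum(voxelData(si)), 1, tolerance = 1e-9)      # mass preserved
  # binary step edge: 25-75% transition width ~ 0.57 mm at sigma 0.4247
  d2 <- c(41, 9, 9)
  stepv <- array(0, d2); stepv[21:41, , ] <- 1
  ss <- regridAndSmooth(ProbabilityVolume(stepv, c(0.5, 0.5, 0.5)),
                        targetMm = 0.5, fwhmMm = 1.0)
  prof <- voxelData(ss)[, 5, 5]
  x <- (seq_along(prof) - 1) * 0.5
  x25 <- approx(prof[10:32], x[10:32], xout = 0.25)$y
  x75 <- approx(prof[10:32], x[10:32], xout = 0.75)$y
  width <- x75 - x25
  expect_equal(width, 2 * qnorm(0.75) * sigma, tolerance = 0.08)
})

test_that("tip location: deep end wins, override wins, phantom tip within 1 mm", {
  spec <- phantomSpec(embeddedFraction = 0.5, blurSigma = 0.4,
                      noiseSd = 0.02, seed = 5150)
  pc <- makePhantom(spec)
  drain <- thresholdVolume(pc@drainProb, 0.44)
  tipInfo <- locateTip(drain, c(1, 0, 0))
  expect_lt(sqrt(sum((tipInfo$tip - pc@truthTip)^2)), 1.0)
  # axis is re-signed tip -> entry
  expect_gt(sum(tipInfo$axis * (tipInfo$entry - tipInfo$tip)), 0)
  # override returned verbatim
  ov <- locateTip(drain, c(1, 0, 0), override = c(60, 14, 14))
  expect_equal(ov$tip, c(60, 14, 14))
  expect_error(locateTip(BinaryMask(array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
                         c(1, 0, 0)), "empty")
})

test_that("coverage profile: embedded, disjoint and half-space phantoms", {
  # fully embedded cylinder -> interior coverage ~ 1
  spec <- phantomSpec(ich = list(type = "ellipsoid", center = c(34, 14, 14),
                                 semiaxes = c(38, 9, 9)))
  pc <- makePhantom(spec)
  prof <- coverageProfile(thresholdVolume(pc@drainProb, 0.44),
                          thresholdVolume(pc@ichProb, 0.5))
  p <- profilePositions(prof); v <- profileValues(prof)
  expect_gte(mean(v[p >= 2 & p <= spec@length - 2]), 0.95)
  expect_equal(prof@frameSource, "touch_volume")

  # no ICH anywhere -> identically zero, via the drain-frame fallback
  spec0 <- phantomSpec(embeddedFraction = 0)
  pc0 <- makePhantom(spec0)
  prof0 <- coverageProfile(thresholdVolume(pc0@drainProb, 0.44),
                           thresholdVolume(pc0@ichProb, 0.5))
  expect_true(all(profileValues(prof0) == 0))
  expect_equal(prof0@frameSource, "drain_fallback")

  # half-space at 40%: step profile, transition within 2 mm of f * length
  specH <- phantomSpec(embeddedFraction = 0.4)
  pcH <- makePhantom(specH)
  profH <- coverageProfile(thresholdVolume(pcH@drainProb, 0.44),
                           thresholdVolume(pcH@ichProb, 0.5))
  pH <- profilePositions(profH); vH <- profileValues(profH)
  truth <- profileValues(analyticProfile(specH))[match(pH, profilePositions(analyticProfile(specH)))]
  truth[is.na(truth)] <- 0
  edge <- specH@embeddedFraction * specH@length
  away <- (pH > 2 & pH < edge - 2) | (pH > edge + 2 & pH < specH@length - 2)
  expect_lte(mean(abs(vH - truth)[away]), 0.05)
  expect_error(coverageProfile(BinaryMask(array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
                               BinaryMask(array(FALSE, c(4, 4, 4)), c(1, 1, 1))),
               "empty")
})

test_that("coverage profile is invariant under translation and axis permutation", {
  spec <- phantomSpec(embeddedFraction = 0.4, blurSigma = 0.5, noiseSd = 0.02,
                      seed = 99)
  pc <- makePhantom(spec)
  drainM <- thresholdVolume(pc@drainProb, 0.44)
  ichM <- thresholdVolume(pc@ichProb, 0.5)
  base <- coverageProfile(drainM, ichM)
  tr <- c(12.25, -5, 103)
  shifted <- coverageProfile(translateVolume(drainM, tr),
                             translateVolume(ichM, tr))
  expect_equal(profileValues(shifted), profileValues(base), tolerance = 1e-6)
  expect_equal(shifted@tipWorld, base@tipWorld + tr, tolerance = 1e-6)
  for (perm in list(c(2, 3, 1), c(3, 1, 2))) {
    rotated <- coverageProfile(permuteVolume(drainM, perm),
                               permuteVolume(ichM, perm))
    expect_equal(profileValues(rotated), profileValues(base),
                 tolerance = 1e-6)
  }
})

test_that("profile features: interpolation grid, padding and the short-drain flag", {
  mk <- function(pos, val) new("CoverageProfile", positions = pos,
                               values = val, tipWorld = c(0, 0, 0),
                               axis = c(1, 0, 0), drainId = 1L,
                               frameSource = "touch_volume")
  f1 <- profileFeatures(mk(seq(0, 30, 0.5), rep(1, 61)))
  expect_equal(f1@values, rep(1, 15))
  expect_false(f1@shortDrain)
  f0 <- profileFeatures(mk(seq(0, 30, 0.5), rep(0, 61)))
  expect_equal(f0@values, rep(0, 15))
  # 10-mm drain at constant 0.8: ten 0.8s then five zero-padded values
  fs <- profileFeatures(mk(seq(0, 10, 0.5), rep(0.8, 21)))
  expect_equal(fs@values, c(rep(0.8, 10), rep(0, 5)))
  expect_true(fs@shortDrain)
  # interpolation is linear between samples
  fr <- profileFeatures(mk(seq(0, 20, 0.5), seq(0, 1, length.out = 41)))
  expect_equal(fr@values[1], 0.5 / 20, tolerance = 1e-12)
})

test_that("profile mean never decreases with the embedded fraction", {
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    pc <- makePhantom(phantomSpec(embeddedFraction = f, seed = 7))
    mean(profileValues(coverageProfile(thresholdVolume(pc@drainProb, 0.44),
                                       thresholdVolume(pc@ichProb, 0.5))))
  }, numeric(1))
  expect_true(all(diff(means) >= -1e-9))
})
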