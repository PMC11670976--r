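# Independent brute-force oracles and small fixture builders.

# exhaustive nearest-non-drain-voxel membership for the volume of touch;
# returns NA where the two nearest non-drain candidates tie within tol
bruteTouchMembership <- function(drain, ich, spacing, tol = 1e-9) {
  d <- dim(drain)
  ichEff <- ich & !drain
  nd <- which(!drain)
  dv <- which(drain)
  Xs <- sweep(arrayInd(nd, d), 2, c(1, 1, 1)) *
    rep(spacing, each = length(nd))
  Xd <- sweep(arrayInd(dv, d), 2, c(1, 1, 1)) *
    rep(spacing, each = length(dv))
  D2 <- outer(rowSums(Xd^2), rep(1, length(nd))) +
    outer(rep(1, length(dv)), rowSums(Xs^2)) - 2 * Xd %*% t(Xs)
  out <- rep(NA, length(drain))
  for (q in seq_along(dv)) {
    dd <- sqrt(pmax(D2[q, ], 0))
    i1 <- which.min(dd)
    d1 <- dd[i1]
    dd[i1] <- Inf
    if (length(dd) > 1 && min(dd) - d1 < tol) next   # tie: excluded
    out[dv[q]] <- ichEff[nd[i1]]
  }
  out
}

# pairwise Mann-Whitney AUC (ties counted 1/2)
bruteAUC <- function(scores, truth) {
  ps <- scores[truth]
  ns <- scores[!truth]
  mean(outer(ps, ns, function(a, b) (a > b) + 0.5 * (a == b)))
}

# flood fill from scratch (independent of the C++ labelling)
bruteComponentCount <- function(mask, connectivity) {
  d <- dim(mask)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  off <- off[m > 0 & m <= switch(as.character(connectivity),
                                 "6" = 1, "18" = 2, "26" = 3), ]
  seen <- array(FALSE, d)
  count <- 0
  for (s in which(mask)) {
    if (seen[s]) next
    count <- count + 1
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(off))) {
        n <- ijk + c(off$dx[r], off$dy[r], off$dz[r])
        if (any(n < 1) || any(n > d)) next
        li <- n[1] + d[1] * (n[2] - 1 + d[2] * (n[3] - 1))
        if (mask[li] && !seen[li]) { seen[li] <- TRUE; queue <- c(queue, li) }
      }
    }
  }
  count
}

# tiny probability volume with hand-set values
probVol <- function(values, dim = NULL, spacing = c(1, 1, 1)) {
  if (is.null(dim)) dim <- dim(values)
  ProbabilityVolume(array(values, dim), spacing)
}

# shift the world origin of a volume
translateVolume <- function(vol, t) {
  a <- worldAffine(vol)
  a[1:3, 4] <- a[1:3, 4] + t
  if (is(vol, "BinaryMask")) BinaryMask(voxelData(vol), voxelSpacing(vol), a)
  else ProbabilityVolume(voxelData(vol), voxelSpacing(vol), a)
}

# permute the grid axes of a volume (isotropic spacing assumed by callers)
permuteVolume <- function(vol, perm) {
  d <- aperm(voxelData(vol), perm)
  if (is(vol, "BinaryMask")) BinaryMask(d, voxelSpacing(vol)[perm])
  else ProbabilityVolume(d, voxelSpacing(vol)[perm])
}

# features + label from one seeded phantom at embedded fraction f
phantomTrainingCase <- function(f, seed, blurSigma = 0.4, noiseSd = 0.02) {
  spec <- phantomSpec(embeddedFraction = f, blurSigma = blurSigma,
                      noiseSd = noiseSd, seed = seed)
  pc <- makePhantom(spec)
  prof <- quantifyDrains(pc@drainProb, pc@ichProb)[[1]]
  list(x = profileFeatures(prof)@values, y = pc@truthLabel, case = pc,
       profile = prof)
}

# a batch of phantom training cases with f ~ Uniform(0, 1)
phantomFeatureSet <- function(n, seedBase) {
  set.seed(seedBase)
  fs <- runif(n)
  out <- lapply(seq_len(n), function(i)
    phantomTrainingCase(fs[i], seed = seedBase + i))
  list(X = do.call(rbind, lapply(out, `[[`, "x")),
       y = vapply(out, `[[`, character(1), "y"),
       f = fs)
}
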