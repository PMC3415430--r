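# Independent oracles, written deliberately as literal per-pixel loops so
# they share no code with the package's vectorized implementations.

# Brute-force Zhang-Suen thinning: per-pixel loops, explicit neighbor
# reads, two subiterations per pass until stable.
zs_thin_oracle <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask))
  nr <- nrow(m); nc <- ncol(m)
  at <- function(img, r, c) {
    if (r < 1 || r > nr || c < 1 || c > nc) 0L else img[r, c]
  }
  pass <- function(img, step) {
    del <- matrix(FALSE, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (img[r, c] == 0L) next
      p <- c(at(img, r - 1, c), at(img, r - 1, c + 1), at(img, r, c + 1),
             at(img, r + 1, c + 1), at(img, r + 1, c),
             at(img, r + 1, c - 1), at(img, r, c - 1),
             at(img, r - 1, c - 1))  # P2..P9
    b <- sum(p)
      if (b < 2 || b > 6) next
      a <- sum(p == 0 & c(p[-1], p[1]) == 1)
      if (a != 1) next
      if (step == 1) {
        if (p[1] * p[3] * p[5] != 0) next
        if (p[3] * p[5] * p[7] != 0) next
      } else {
        if (p[1] * p[3] * p[7] != 0) next
        if (p[1] * p[5] * p[7] != 0) next
      }
      del[r, c] <- TRUE
    }
    img[del] <- 0L
    img
  }
  repeat {
    m1 <- pass(m, 1)
    m2 <- pass(m1, 2)
    if (identical(m2, m)) break
    m <- m2
  }
  m == 1L
}

# Endpoint count by literal neighbor counting.
endpoint_count_oracle <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  cnt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!skel[r, c]) next
    nn <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && skel[rr, cc])
        nn <- nn + 1L
    }
    if (nn <= 1L) cnt <- cnt + 1L
  }
  cnt
}

# Exhaustive between-class-variance threshold search over all 256 levels;
# ties (the flat plateau between well-separated modes) resolved by the
# plateau midpoint, as classical Otsu implementations do.
otsu_exhaustive <- function(frame) {
  x <- as.vector(frame)
  v <- rep(-Inf, 256)
  for (t in 0:255) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    v[t + 1] <- w0 * w1 * (mean(lo) - mean(hi))^2
  }
  mean(which(v >= max(v) - 1e-9) - 1)
}

# Small library of fixture masks (all <= 30 x 30) exercising the thinning
# and component operations.
fixture_masks <- function() {
  bar <- matrix(FALSE, 7, 15); bar[3:5, 3:13] <- TRUE
  vbar <- matrix(FALSE, 15, 7); vbar[3:13, 3:5] <- TRUE
  Lb <- matrix(FALSE, 20, 20); Lb[5:16, 5:7] <- TRUE; Lb[14:16, 5:16] <- TRUE
  disk <- matrix(FALSE, 19, 19)
  idx <- which(!disk, arr.ind = TRUE)
  disk[idx[(idx[, 1] - 10)^2 + (idx[, 2] - 10)^2 <= 49]] <- TRUE
  diagb <- matrix(FALSE, 18, 18)
  for (i in 3:15) diagb[i, (i - 1):(i + 1)] <- TRUE
  sq <- matrix(FALSE, 12, 12); sq[4:9, 4:9] <- TRUE
  cres <- matrix(FALSE, 25, 25)
  idx <- which(!cres, arr.ind = TRUE)
  r2 <- (idx[, 1] - 13)^2 + (idx[, 2] - 13)^2
  cres[idx[r2 <= 100 & r2 >= 36 & idx[, 2] >= 13]] <- TRUE
  list(bar = bar, vbar = vbar, L = Lb, disk = disk, diag = diagb,
       square = sq, crescent = cres)
}

# Distance from ground-truth mm point to an estimated pixel point, in px.
px_err <- function(est_px, truth_mm, mm_per_pixel) {
  truth_px <- truth_mm / mm_per_pixel + 0.5
  sqrt(sum((est_px - truth_px)^2))
}

# Shared small-scene parameters for posture fixtures (fine resolution).
posture_params <- function(...) {
  args <- list(noise_sd = 0, duration = 1, dt = 1, mm_per_pixel = 0.05,
               arena_size = c(12, 12))
  override <- list(...)
  args[names(override)] <- override
  do.call(crawl_params, args)
}
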