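# Independent oracles, deliberately written as slow explicit loops so they
# share no code path with the implementation they check.

# Count pixels whose hue (degrees) lies in [lo, hi) with saturation >= floor.
oracle_hue_band_count <- function(raster, lo, hi, sat_floor = 0.15) {
  count <- 0L
  for (i in seq_len(dim(raster)[1])) {
    for (j in seq_len(dim(raster)[2])) {
      r <- raster[i, j, 1] / 255; g <- raster[i, j, 2] / 255
      b <- raster[i, j, 3] / 255
      mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
      s <- if (mx == 0) 0 else d / mx
      if (s < sat_floor) next
      h <- if (d == 0) 0
      else if (mx == r) 60 * (((g - b) / d) %% 6)
      else if (mx == g) 60 * ((b - r) / d + 2)
      else 60 * ((r - g) / d + 4)
      if (h >= lo && h < hi) count <- count + 1L
    }
  }
  count
}

# Per-pixel membership count for one HSV box (closed intervals).
oracle_hsv_box_count <- function(raster, box) {
  count <- 0L
  for (i in seq_len(dim(raster)[1])) {
    for (j in seq_len(dim(raster)[2])) {
      r <- raster[i, j, 1] / 255; g <- raster[i, j, 2] / 255
      b <- raster[i, j, 3] / 255
      mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
      v <- mx
      s <- if (mx == 0) 0 else d / mx
      h <- if (d == 0) 0
      else if (mx == r) 60 * (((g - b) / d) %% 6)
      else if (mx == g) 60 * ((b - r) / d + 2)
      else 60 * ((r - g) / d + 4)
      if (h >= box$h[1] && h <= box$h[2] &&
          s >= box$s[1] && s <= box$s[2] &&
          v >= box$v[1] && v <= box$v[2]) count <- count + 1L
    }
  }
  count
}

# Brute-force enumeration of all in-bounds stride positions.
oracle_plan_origins <- function(width, height, tile, overlap) {
  s <- tile - overlap
  xs <- integer(0); x <- 0
  while (x + tile <= width) { xs <- c(xs, x); x <- x + s }
  ys <- integer(0); y <- 0
  while (y + tile <= height) { ys <- c(ys, y); y <- y + s }
  out <- expand.grid(x = xs, y = ys)
  out[order(out$y, out$x), , drop = FALSE]
}

# Exhaustive between-class-variance scan over all 256 thresholds.
oracle_otsu <- function(counts) {
  n <- sum(counts)
  lev <- 0:255
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    w0 <- sum(counts[lev <= t]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[lev <= t] * lev[lev <= t]) / w0
    mu1 <- sum(counts[lev > t] * lev[lev > t]) / w1
    v <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Pairwise Mann-Whitney counting with ties worth one half.
oracle_auc <- function(scores, truths) {
  pos <- scores[truths]; neg <- scores[!truths]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Count-and-compare majority with abstention.
oracle_consensus <- function(votes_logical) {
  pos <- 0L; neg <- 0L
  for (v in votes_logical) if (v) pos <- pos + 1L else neg <- neg + 1L
  if (pos > neg) list(decision = "positive", confidence = pos / (pos + neg))
  else if (neg > pos) list(decision = "negative", confidence = neg / (pos + neg))
  else list(decision = "indecision", confidence = 0.5)
}

# Two-pass pooled mean/sd over the Lab pixels of a tile set.
oracle_lab_moments <- function(rasters) {
  labs <- do.call(rbind, lapply(rasters, function(r) {
    m <- cbind(as.vector(r[, , 1]), as.vector(r[, , 2]),
               as.vector(r[, , 3])) / 255
    grDevices::convertColor(m, from = "sRGB", to = "Lab")
  }))
  mu <- c(mean(labs[, 1]), mean(labs[, 2]), mean(labs[, 3]))
  sdv <- numeric(3)
  for (c in 1:3) sdv[c] <- sqrt(mean((labs[, c] - mu[c])^2))
  list(mean = mu, sd = sdv)
}

# Small helper: raster filled with one constant RGB color.
const_raster <- function(size, rgb) {
  array(rep(rgb, each = size * size), c(size, size, 3))
}
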