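# Independent brute-force oracles, written as explicit loops so they share
# no code with the implementation they check.

# Exhaustive Otsu search: try every candidate bin edge, recompute class
# weights/means from scratch, keep the smallest edge among maxima.
oracle_otsu <- function(values, bins = 256) {
  counts <- integer(bins)
  for (v in values) {
    b <- min(floor(v * bins), bins - 1) + 1
    counts[b] <- counts[b] + 1
  }
  if (sum(counts > 0) == 1) return(which(counts > 0) / bins)
  mids <- (seq_len(bins) - 0.5) / bins
  n <- sum(counts)
  best_t <- NA_real_
  best_v <- -Inf
  for (k in 1:(bins - 1)) {
    n0 <- sum(counts[1:k]); n1 <- n - n0
    w0 <- n0 / n; w1 <- n1 / n
    mu0 <- if (n0 > 0) sum(counts[1:k] * mids[1:k]) / n0 else 0
    mu1 <- if (n1 > 0) sum(counts[(k + 1):bins] * mids[(k + 1):bins]) / n1 else 0
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- k / bins
    }
  }
  best_t
}

# Flood-fill connected-component labeling with a queue; labels numbered by
# first encounter in a row-major scan.
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  nxt <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_along(dr)) {
        nr <- p[1] + dr[q]; nc <- p[2] + dc[q]
        if (nr < 1 || nr > H || nc < 1 || nc > W) next
        if (mask[nr, nc] && lab[nr, nc] == 0L) {
          lab[nr, nc] <- nxt
          queue[[length(queue) + 1]] <- c(nr, nc)
        }
      }
    }
  }
  lab
}

# Loop-based pyramid: 5-tap binomial reduce with symmetric reflection and
# x2 decimation, then bilinear expansion through the recorded sizes.
oracle_reflect <- function(i, n) {
  while (i < 1 || i > n) {
    if (i < 1) i <- 1 - i
    if (i > n) i <- 2 * n + 1 - i
  }
  i
}

oracle_reduce <- function(m) {
  w <- c(1, 4, 6, 4, 1) / 16
  H <- nrow(m); W <- ncol(m)
  tmp <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    acc <- 0
    for (d in -2:2) acc <- acc + w[d + 3] * m[oracle_reflect(r + d, H), c]
    tmp[r, c] <- acc
  }
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    acc <- 0
    for (d in -2:2) acc <- acc + w[d + 3] * tmp[r, oracle_reflect(c + d, W)]
    out[r, c] <- acc
  }
  out[seq(1, H, by = 2), seq(1, W, by = 2), drop = FALSE]
}

oracle_expand <- function(m, H, W) {
  out <- matrix(0, H, W)
  hi <- nrow(m); wi <- ncol(m)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    sr <- (r - 0.5) * hi / H + 0.5
    sc <- (c - 0.5) * wi / W + 0.5
    sr <- min(max(sr, 1), hi); sc <- min(max(sc, 1), wi)
    r0 <- min(floor(sr), hi - 1); c0 <- min(floor(sc), wi - 1)
    if (hi == 1) r0 <- 1
    if (wi == 1) c0 <- 1
    tr <- sr - r0; tc <- sc - c0
    r1 <- min(r0 + 1, hi); c1 <- min(c0 + 1, wi)
    out[r, c] <- (1 - tr) * ((1 - tc) * m[r0, c0] + tc * m[r0, c1]) +
                 tr * ((1 - tc) * m[r1, c0] + tc * m[r1, c1])
  }
  out
}

oracle_pyramid <- function(m, levels) {
  sizes <- list()
  for (l in seq_len(levels)) {
    sizes[[l]] <- dim(m)
    m <- oracle_reduce(m)
  }
  for (l in rev(seq_len(levels))) m <- oracle_expand(m, sizes[[l]][1], sizes[[l]][2])
  pmin(pmax(m, 0), 1)
}

# Set-definition morphology with an arbitrary structuring element (centered
# odd-sized binary matrix); out-of-bounds counts as background.
oracle_erode <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask)
  k <- (nrow(se) - 1) / 2
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    keep <- TRUE
    for (dr in -k:k) for (dc in -k:k) {
      if (!se[dr + k + 1, dc + k + 1]) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > H || cc < 1 || cc > W || !mask[rr, cc]) {
        keep <- FALSE
        break
      }
    }
    out[r, c] <- keep
  }
  out
}

oracle_dilate <- function(mask, se) {
  H <- nrow(mask); W <- ncol(mask)
  k <- (nrow(se) - 1) / 2
  out <- matrix(FALSE, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    hit <- FALSE
    for (dr in -k:k) for (dc in -k:k) {
      if (!se[dr + k + 1, dc + k + 1]) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && mask[rr, cc]) {
        hit <- TRUE
        break
      }
    }
    out[r, c] <- hit
  }
  out
}

# Nearest-rank quantile by sorting.
oracle_quantile <- function(x, q) {
  sort(x)[ceiling(q * length(x))]
}

# Minimum Chebyshev distance between the pixels of two masks.
oracle_min_chebyshev <- function(maskA, maskB) {
  a <- which(maskA, arr.ind = TRUE)
  b <- which(maskB, arr.ind = TRUE)
  if (nrow(a) == 0 || nrow(b) == 0) return(Inf)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- pmax(abs(b[, 1] - a[i, 1]), abs(b[, 2] - a[i, 2]))
    best <- min(best, min(d))
  }
  best
}

# Per-pixel blending oracle for tiled inference: loop over pixels and tiles.
oracle_blend <- function(image, tile, overlap, stub) {
  H <- dim(image)[1]; W <- dim(image)[2]
  stride <- tile - overlap
  starts <- function(n) {
    o <- seq(0, n - tile, by = stride)
    if (o[length(o)] + tile < n) o <- c(o, n - tile)
    o
  }
  acc <- matrix(0, H, W); wt <- matrix(0, H, W)
  for (r0 in starts(H)) for (c0 in starts(W)) {
    p <- stub(image[r0 + 1:tile, c0 + 1:tile, , drop = FALSE])
    for (i in 1:tile) for (j in 1:tile) {
      acc[r0 + i, c0 + j] <- acc[r0 + i, c0 + j] + p[i, j]
      wt[r0 + i, c0 + j] <- wt[r0 + i, c0 + j] + 1
    }
  }
  acc / wt
}

# Small scene profile used by module tests (fast to generate).
small_scene_spec <- function(seed, nNerves = 2, pniFraction = 0.5, ...) {
  SceneSpec(heightPx = 576, widthPx = 576, nNerves = nNerves,
            pniFraction = pniFraction, nerveAxisRangePx = c(25, 40),
            perineuriumThicknessPx = 5, pniNestCells = c(4, 6),
            nNoiseBlobs = 3,
            noiseSizeDist = list(name = "lognormal", meanlog = 8, sdlog = 0.6),
            nSpecks = 2, seed = seed, ...)
}
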