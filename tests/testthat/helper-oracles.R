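# Independent brute-force oracles, written against the definitions only
# (no shared code with the package implementation).

# Haralick features of one window by direct enumeration: build each
# offset's co-occurrence matrix with explicit loops, normalize, average,
# evaluate the eight feature sums.
oracle_window_features <- function(lev, n_levels, offsets, symmetric) {
  mats <- list()
  for (o in seq_len(nrow(offsets))) {
    dx <- offsets[o, 1]; dy <- offsets[o, 2]
    P <- matrix(0, n_levels, n_levels)
    for (i in seq_len(nrow(lev))) {
      for (j in seq_len(ncol(lev))) {
        i2 <- i + dy; j2 <- j + dx
        if (i2 < 1 || i2 > nrow(lev) || j2 < 1 || j2 > ncol(lev)) next
        a <- lev[i, j]; b <- lev[i2, j2]
        if (is.na(a) || is.na(b)) next
        P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
        if (symmetric) P[b + 1, a + 1] <- P[b + 1, a + 1] + 1
      }
    }
    if (sum(P) > 0) mats[[length(mats) + 1]] <- P / sum(P)
  }
  if (length(mats) == 0) return(rep(NA_real_, 8))
  P <- Reduce(`+`, mats) / length(mats)
  iv <- row(P) - 1; jv <- col(P) - 1
  mu_i <- sum(iv * P); mu_j <- sum(jv * P)
  s_i <- sqrt(sum((iv - mu_i)^2 * P)); s_j <- sqrt(sum((jv - mu_j)^2 * P))
  c(
    MEAN = sum(iv * P),
    VAR = sum((iv - mu_i)^2 * P),
    HOM = sum(P / (1 + (iv - jv)^2)),
    CON = sum((iv - jv)^2 * P),
    DIS = sum(abs(iv - jv) * P),
    ENT = -sum(P[P > 0] * log(P[P > 0])),
    SEC = sum(P^2),
    COR = if (s_i * s_j == 0) 1 else sum((iv - mu_i) * (jv - mu_j) * P) / (s_i * s_j)
  )
}

# Per-pixel moving-window feature maps, O(n^4): every centre gets its own
# truncated window enumerated from scratch.
oracle_texture_map <- function(lev, n_levels, window, offsets, symmetric) {
  H <- nrow(lev); W <- ncol(lev)
  out <- array(NA_real_, c(H, W, 8))
  if (window %% 2 == 1) {
    up <- (window - 1) / 2; down <- up
  } else {
    up <- window / 2 - 1; down <- window / 2
  }
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      if (is.na(lev[r, c])) next
      rows <- max(1, r - up):min(H, r + down)
      cols <- max(1, c - up):min(W, c + down)
      out[r, c, ] <- oracle_window_features(lev[rows, cols, drop = FALSE],
                                            n_levels, offsets, symmetric)
    }
  }
  out
}

# Equal-width binning by direct comparison against bin edges.
oracle_quantize <- function(x, n_levels) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(array(0L, dim(as.matrix(x))))
  edges <- seq(lo, hi, length.out = n_levels + 1)
  out <- x
  for (i in seq_along(x)) {
    lev <- max(which(x[i] >= edges[-(n_levels + 1)])) - 1L
    out[i] <- min(lev, n_levels - 1L)
  }
  out
}
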