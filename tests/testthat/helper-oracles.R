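# Independent brute-force oracles, deliberately naive and separate from the
# package's implementation paths.

# Between-class-variance search over every candidate threshold 0..255,
# computed from first principles (class weights and means).
oracle_otsu <- function(gray) {
  g <- as.integer(gray)
  best_T <- NA_integer_
  best_v <- -Inf
  for (T in 0:255) {
    lo <- g[g <= T]
    hi <- g[g > T]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(g)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_T <- T
    }
  }
  best_T
}

# Flood-fill connected-component labelling with an explicit stack.
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  k <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    k <- k + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- k
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (j in seq_len(nrow(nb))) {
        r <- p[1] + nb$dr[j]; c <- p[2] + nb$dc[j]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- k
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

oracle_filter_blobs <- function(mask, min_area) {
  lab <- oracle_label(mask, 8)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

# Background flood fill from the border (4-connectivity); unreached
# background pixels are enclosed holes.
oracle_fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reached <- matrix(FALSE, nr, nc)
  stack <- list()
  for (r in seq_len(nr)) for (c in c(1L, nc))
    if (!mask[r, c]) { reached[r, c] <- TRUE; stack[[length(stack) + 1L]] <- c(r, c) }
  for (c in seq_len(nc)) for (r in c(1L, nr))
    if (!mask[r, c] && !reached[r, c]) { reached[r, c] <- TRUE; stack[[length(stack) + 1L]] <- c(r, c) }
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r <- p[1] + d[1]; c <- p[2] + d[2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          !mask[r, c] && !reached[r, c]) {
        reached[r, c] <- TRUE
        stack[[length(stack) + 1L]] <- c(r, c)
      }
    }
  }
  mask | !reached
}

# Uniform-colour frame helper.
uniform_frame <- function(rgb, h = 4, w = 5) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# Lab raster from explicit per-channel values.
lab_array <- function(L, a, b) {
  h <- nrow(as.matrix(L)); w <- ncol(as.matrix(L))
  array(c(L, a, b), dim = c(h, w, 3))
}
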