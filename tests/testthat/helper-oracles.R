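# Independent brute-force oracles used to pin the fast implementations.

# per-pixel windowed lower-median threshold by explicit double loop
oracle_median_mask <- function(px, radius, offset = 0) {
  h <- nrow(px); w <- ncol(px)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      win <- px[max(1, i - radius):min(h, i + radius),
                max(1, j - radius):min(w, j + radius)]
      med <- sort(as.numeric(win))[ceiling(length(win) / 2)]
      out[i, j] <- px[i, j] > med - offset
    }
  }
  out
}

# occupied-box count by explicit grid scan
oracle_box_count <- function(mask, s) {
  h <- nrow(mask); w <- ncol(mask)
  n <- 0L
  for (r0 in seq(1, h, by = s)) {
    for (c0 in seq(1, w, by = s)) {
      if (any(mask[r0:min(h, r0 + s - 1), c0:min(w, c0 + s - 1)])) n <- n + 1L
    }
  }
  n
}

# neighbour count by explicit loop
oracle_neighbour_count <- function(mask, i, j) {
  h <- nrow(mask); w <- ncol(mask)
  s <- 0L
  for (a in -1:1) for (b in -1:1) {
    if (a == 0 && b == 0) next
    r <- i + a; c <- j + b
    if (r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c]) s <- s + 1L
  }
  s
}

# random blobby binary mask (union of discs and bars), geometry from the
# current RNG stream
random_vessel_mask <- function(h, w, n_blobs = 4) {
  m <- matrix(FALSE, h, w)
  for (k in seq_len(n_blobs)) {
    if (runif(1) < 0.5) {
      cr <- runif(1, 5, h - 5); cc <- runif(1, 5, w - 5); rad <- runif(1, 2, 6)
      rr <- matrix(seq_len(h), h, w); ccix <- matrix(seq_len(w), h, w, byrow = TRUE)
      m <- m | ((rr - cr)^2 + (ccix - cc)^2 <= rad^2)
    } else {
      r0 <- sample(seq_len(h - 4), 1); c0 <- sample(seq_len(w - 10), 1)
      m[r0:(r0 + 2), c0:min(w, c0 + sample(5:10, 1))] <- TRUE
    }
  }
  m
}

# raster of a "+" cross: two perpendicular arm_len*2+1 pixel lines
cross_raster <- function(n = 31, arm = 10) {
  m <- matrix(FALSE, n, n)
  c0 <- (n + 1) %/% 2
  m[c0, (c0 - arm):(c0 + arm)] <- TRUE
  m[(c0 - arm):(c0 + arm), c0] <- TRUE
  m
}
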