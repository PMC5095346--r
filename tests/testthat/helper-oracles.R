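# Brute-force oracles and small fixture builders shared across test files.
# Oracles are deliberately naive (double loops, exhaustive enumeration) and
# independent of the package's vectorized implementations.

# exhaustive connected-component labeling by repeated neighbor sweeps
oracle_label <- function(m, connectivity = 8L) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  lab[m] <- seq_len(sum(m))
  offs <- if (connectivity == 8L)
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  repeat {
    changed <- FALSE
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (!m[i, j]) next
      for (o in offs) {
        ii <- i + o[1]; jj <- j + o[2]
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && m[ii, jj] &&
            lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # renumber compactly
  u <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], u)
  lab
}

# boundary = foreground pixels with at least one 4-neighbor outside the mask
oracle_boundary <- function(m) {
  h <- nrow(m); w <- ncol(m)
  b <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!m[i, j]) next
    nb <- c(
      if (i > 1) m[i - 1, j] else FALSE,
      if (i < h) m[i + 1, j] else FALSE,
      if (j > 1) m[i, j - 1] else FALSE,
      if (j < w) m[i, j + 1] else FALSE)
    b[i, j] <- any(!nb)
  }
  b
}

# exhaustive per-box masses for a grid anchored at `off` (0-based)
oracle_masses <- function(m, s, off = c(0L, 0L)) {
  h <- nrow(m); w <- ncol(m)
  starts_r <- seq(off[1] - s, h - 1, by = s)
  starts_r <- starts_r[starts_r + s > 0]
  starts_c <- seq(off[2] - s, w - 1, by = s)
  starts_c <- starts_c[starts_c + s > 0]
  out <- numeric(0)
  for (sr in starts_r) for (sc in starts_c) {
    rr <- max(0, sr):min(h - 1, sr + s - 1)
    cc <- max(0, sc):min(w - 1, sc + s - 1)
    mm <- sum(m[rr + 1, cc + 1, drop = FALSE])
    if (mm > 0) out <- c(out, mm)
  }
  out
}

# 8x8 quadrant fixture: 16, 4, 0, 8 foreground px in the four 4x4 quadrants
quadrant_fixture <- function() {
  m <- matrix(FALSE, 8, 8)
  m[1:4, 1:4] <- TRUE                          # 16 px
  m[1:2, 5:6] <- TRUE                          # 4 px
  m[5:8, 5:6] <- TRUE                          # 8 px
  m
}

# 10x10 filled square embedded in a larger canvas
square_in_canvas <- function(canvas = 30L, size = 10L, at = 10L) {
  m <- matrix(FALSE, canvas, canvas)
  m[at:(at + size - 1), at:(at + size - 1)] <- TRUE
  m
}

expect_p_value <- function(p) {
  expect_true(is.finite(p) && p >= 0 && p <= 1)
}
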