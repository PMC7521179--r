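# Independent brute-force oracles, deliberately written as plain per-pixel /
# per-arrangement loops so they share no code path with the package.

# Naive re-implementation of the scoring pipeline: explicit loops, same
# clipping and comparison order as the documented pipeline contract.
naive_score <- function(pixels, rect_fraction, alpha, beta, threshold,
                        bit_depth = 8L) {
  if (bit_depth == 16L) pixels <- pixels / 257
  h <- nrow(pixels); w <- ncol(pixels)
  rh <- max(1L, floor(rect_fraction * h + 0.5))
  rw <- max(1L, floor(rect_fraction * w + 0.5))
  r0 <- (h - rh) %/% 2L
  c0 <- (w - rw) %/% 2L
  s <- 0
  for (i in (r0 + 1L):(r0 + rh))
    for (j in (c0 + 1L):(c0 + rw))
      s <- s + pixels[i, j]
  bg <- s / (rh * rw)
  count <- 0L
  for (i in 1:h) {
    for (j in 1:w) {
      v <- pixels[i, j] - bg
      if (v < 0) v <- 0
      v <- v * alpha + beta
      if (v < 0) v <- 0
      if (v > 255) v <- 255
      if (v >= threshold) count <- count + 1L
    }
  }
  count
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n_a+n_b, n_a)
# group assignments of the pooled sample (no ties assumed).
enum_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, ">"))
  }
  u_obs <- sum(outer(a, b, ">"))
  us <- utils::combn(n, na, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# small, fast well geometry for io/pipeline tests
tiny_spec <- function(...) {
  synthetic_well_spec(height = 64, width = 64, organoid_radius = 20, ...)
}

tiny_positive_spec <- function(...) {
  tiny_spec(random_patches = list(fraction = c(0.02, 0.10), n = 1:2,
                                  intensity = 120), ...)
}
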