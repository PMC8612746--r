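# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own code paths.

# exhaustive pairwise source-detector distances on an optode array
oracle_pair_distances <- function(array) {
  s <- array$sources; d <- array$detectors
  out <- numeric(0)
  for (i in seq_len(nrow(s))) for (j in seq_len(nrow(d))) {
    out <- c(out, sqrt((s$x[i] - d$x[j])^2 + (s$y[i] - d$y[j])^2))
  }
  out
}

# channel count by scanning all pairs against separation windows
oracle_channel_count <- function(array, centers, window) {
  sep <- oracle_pair_distances(array)
  sum(vapply(sep, function(r) any(abs(r - centers) <= window), logical(1)))
}

# weighted centroid by direct accumulation
oracle_centroid <- function(coords, w) {
  c(sum(coords[, 1] * w), sum(coords[, 2] * w), sum(coords[, 3] * w)) / sum(w)
}

# exact O(n^2) max pairwise distance via a double loop
oracle_max_pair_dist <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  best <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    best <- max(best, sum((coords[i, ] - coords[j, ])^2))
  }
  sqrt(best)
}

# infinite-medium Green's function recomputed from first principles with
# explicit polar-form complex square root
oracle_greens <- function(mua, musp, n_ref, r, f_mhz) {
  v <- 299.792458 / n_ref
  Dm <- 1 / (3 * (mua + musp))
  om <- 2 * pi * f_mhz * 1e-3
  zre <- mua / Dm; zim <- -om / (v * Dm)
  mod <- sqrt(zre^2 + zim^2)
  arg <- atan2(zim, zre)
  k <- complex(modulus = sqrt(mod), argument = arg / 2)
  if (Re(k) < 0) k <- -k
  exp(-k * r) / (4 * pi * Dm * r)
}

# small homogeneous test slab shared by forward/sensitivity tests
tiny_slab <- function(lateral = 36, depth = 28, h = 2) {
  build_layered_slab(c(scalp = 4, skull = 7, CSF = 2, gray = 4),
                     lateral_extent = lateral, depth_extent = depth,
                     voxel_size = h)
}
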