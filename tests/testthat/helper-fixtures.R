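# Shared fixtures: tiny deterministic parcellations, streamline sets and
# graphs used across the unit tests.

# 4-region parcellation on an 8x8x8 grid: x-halves are hemispheres, z-halves
# split each hemisphere into two regions.
tiny_parcellation <- function() {
  lab <- array(0L, dim = c(8, 8, 8))
  lab[1:4, , 1:4] <- 1L
  lab[1:4, , 5:8] <- 2L
  lab[5:8, , 1:4] <- 3L
  lab[5:8, , 5:8] <- 4L
  parcellation(lab)
}

# straight streamline between two points (continuous voxel coordinates)
segment_sl <- function(a, b, n = 2) {
  t <- seq(0, 1, length.out = n)
  outer(1 - t, a) + outer(t, b)
}

small_phantom <- function(seed = 7, n_patients = 10, noise_sd = 2,
                          betas = c(5, 1.0, -60, -60), ...) {
  cfg <- phantom_config(grid_shape = c(16, 16, 16), n_regions = 12,
                        n_healthy = 6, n_streamlines = 400,
                        n_patients = n_patients, noise_sd = noise_sd,
                        planted_betas = betas, seed = seed, ...)
  ph <- generate_phantom(cfg)
  list(cfg = cfg, parc = ph$parcellation, healthy = ph$healthy)
}

# random symmetric nonnegative weight matrix with zero diagonal
random_connectome <- function(n, density = 0.7, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- stats::runif(sum(ut))
  vals[stats::runif(sum(ut)) > density] <- 0
  w[ut] <- vals
  w <- w + t(w)
  w
}

# adjacency matrix from an edge list on n nodes
adj_from_edges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- 1
    a[e[2], e[1]] <- 1
  }
  a
}
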