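# Shared fixtures and independent oracles.

rand_vol <- function(L, seed = 1) {
  subtomo:::with_seed(seed, array(rnorm(L^3), c(L, L, L)))
}

gaussian_blob <- function(L, sigma = 4, offset = c(-3, 2, 0)) {
  c0 <- floor(L / 2)
  i <- 0:(L - 1)
  d2 <- array((i - c0 - offset[1])^2, c(L, L, L)) +
    array(rep((i - c0 - offset[2])^2, each = L), c(L, L, L)) +
    array(rep((i - c0 - offset[3])^2, each = L * L), c(L, L, L))
  exp(-d2 / (2 * sigma^2))
}

# correlation of two volumes under a weight mask (mean-subtracted)
masked_cor <- function(a, b, m) {
  am <- a - sum(m * a) / sum(m)
  bm <- b - sum(m * b) / sum(m)
  sum(m * am * bm) / sqrt(sum(m * am^2) * sum(m * bm^2))
}

rot_dist <- function(e1, e2) subtomo:::rotation_distance(e1, e2)

# Independent sliding-window evaluation of the locally normalized
# correlation at one circular translation t (0-based offsets).
brute_local_cc <- function(particle, template_n, mask, t) {
  L <- dim(particle)[1]
  M <- sum(mask)
  idx <- function(s) ((seq_len(L) - 1 + s) %% L) + 1
  ps <- particle[idx(t[1]), idx(t[2]), idx(t[3])]
  mu <- sum(mask * ps) / M
  sdv <- sqrt(sum(mask * ps^2) / M - mu^2)
  sum(mask * template_n * ps) / (M * sdv)
}

# offset of the centred correlation-map voxel holding translation t
map_value_at <- function(map, t) {
  c0 <- floor(map$L / 2)
  map$values[c0 + t[1] + 1, c0 + t[2] + 1, c0 + t[3] + 1]
}

# minimal triangulated surface built by hand (for orientation tests)
manual_surface <- function(vertices, faces, normals) {
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "triangulated_surface")
}
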