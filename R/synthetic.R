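# Phantom and dataset generator: every other module is validated against
# ground truth produced here.
#
# Noise is added AFTER wedge filtering, so noise fills the missing wedge —
# the realistic situation, since noise enters at acquisition time. The SNR
# is variance-based and measured under the default alignment mask:
# noise variance = (variance of the noise-free, wedge-filtered particle
# under the mask) / SNR.

smoothstep <- function(d, r0, edge) {
  # 1 for d <= r0, raised-cosine to 0 over (r0, r0 + edge]
  v <- numeric(length(d))
  v[d <= r0] <- 1
  e <- d > r0 & d < r0 + edge
  v[e] <- 0.5 * (1 + cos(pi * (d[e] - r0) / edge))
  v
}

radial_distance <- function(L, center) {
  i <- 0:(L - 1)
  sqrt(array((i - center[1])^2, c(L, L, L)) +
       array(rep((i - center[2])^2, each = L), c(L, L, L)) +
       array(rep((i - center[3])^2, each = L * L), c(L, L, L)))
}

soft_sphere <- function(L, center, radius, edge = 2)
  array(smoothstep(radial_distance(L, center), radius, edge), c(L, L, L))

# distance from every voxel to the segment p..q
segment_distance <- function(L, p, q) {
  crd <- voxel_coords(L)
  v <- q - p
  t <- pmin(pmax(((crd[, 1] - p[1]) * v[1] + (crd[, 2] - p[2]) * v[2] +
                    (crd[, 3] - p[3]) * v[3]) / sum(v^2), 0), 1)
  dx <- crd[, 1] - (p[1] + t * v[1])
  dy <- crd[, 2] - (p[2] + t * v[2])
  dz <- crd[, 3] - (p[3] + t * v[3])
  array(sqrt(dx^2 + dy^2 + dz^2), c(L, L, L))
}

soft_capsule <- function(L, p, q, radius, edge = 2)
  array(smoothstep(segment_distance(L, p, q), radius, edge), c(L, L, L))

#' Geometric phantom volumes
#'
#' Smooth-edged, zero-background densities with peak value 1, designed to
#' have no self-symmetry beyond the identity (so alignment tests cannot
#' succeed by accident): an asymmetric cluster of spheres, a dumbbell with
#' unequal heads, or an L shape with unequal arms.
#'
#' @param kind one of `"sphere-cluster"`, `"dumbbell"`, `"L-shape"`.
#' @param L side length in voxels (>= 16).
#' @return cubic volume of side `L`.
#' @export
make_phantom <- function(kind = c("sphere-cluster", "dumbbell", "L-shape"),
                         L = 32) {
  kind <- match.arg(kind)
  if (L < 16) stop("phantom side must be at least 16 voxels")
  c0 <- rep(floor(L / 2), 3)
  u <- L / 32  # scale relative to the reference size
  vol <- switch(kind,
    "sphere-cluster" = {
      soft_sphere(L, c0, 4.5 * u) +
        0.8 * soft_sphere(L, c0 + c(7, 0, 0) * u, 3 * u) +
        0.7 * soft_sphere(L, c0 + c(0, 6, 2) * u, 2.5 * u) +
        0.6 * soft_sphere(L, c0 + c(-3, -5, 5) * u, 2 * u)
    },
    "dumbbell" = {
      soft_sphere(L, c0 + c(-6, 0, 0) * u, 4 * u) +
        0.85 * soft_sphere(L, c0 + c(7, 1, 0) * u, 2.8 * u) +
        0.5 * soft_capsule(L, c0 + c(-6, 0, 0) * u, c0 + c(7, 1, 0) * u,
                           1.5 * u)
    },
    "L-shape" = {
      soft_capsule(L, c0 + c(-4, -4, 0) * u, c0 + c(8, -4, 0) * u, 3 * u) +
        0.9 * soft_capsule(L, c0 + c(-4, -4, 0) * u, c0 + c(-4, 4, 1) * u,
                           2 * u)
    })
  vol / max(vol)
}

#' Simulation specification
#'
#' @param N number of particles.
#' @param L particle side length, voxels.
#' @param snr signal-to-noise ratio, defined as signal variance over noise
#'   variance (positive; use `Inf` for noise-free data).
#' @param wedge a [wedge_descriptor()] shared by all particles.
#' @param angles pose distribution: `list(type = "uniform")` for uniform
#'   random rotations (sampled correctly on the rotation group via random
#'   unit quaternions, not uniform Euler angles), `list(type = "cone",
#'   cone = <deg>, inplane = <deg>)` for a capped distribution, or
#'   `list(type = "fixed_set", triplets = <matrix>)` to draw poses from an
#'   explicit set (e.g. the points of an angular grid).
#' @param shift_halfwidth shifts are uniform in the cube
#'   `[-shift_halfwidth, shift_halfwidth]^3` (voxels).
#' @param integer_shifts round the sampled shifts to whole voxels (use for
#'   noise-free checks where sub-voxel displacement would cap the
#'   attainable correlation of an integer-translation search).
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(N, L, snr = Inf, wedge = c(-90, 90),
                            angles = list(type = "uniform"),
                            shift_halfwidth = 0, integer_shifts = FALSE,
                            seed = 1) {
  if (N < 1) stop("need at least one particle")
  if (snr <= 0) stop("snr must be positive")
  structure(list(N = as.integer(N), L = as.integer(L), snr = snr,
                 wedge = as_wedge_descriptor(wedge), angles = angles,
                 shift_halfwidth = shift_halfwidth,
                 integer_shifts = isTRUE(integer_shifts),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

random_rotation_euler <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
    2 * (q[2] * q[4] - q[1] * q[3]),
    2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] + q[1] * q[2]),
    2 * (q[2] * q[4] + q[1] * q[3]), 2 * (q[3] * q[4] - q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3)
  matrix_to_euler(R)
}

sample_euler <- function(angles) {
  switch(angles$type,
    uniform = random_rotation_euler(),
    cone = {
      # direction uniform on the cap of half-angle `cone` (tilt about the
      # in-plane axis at azimuth `ph`, which leaves the in-plane angle
      # untouched), in-plane uniform on +/- `inplane`
      cmax <- cos(deg2rad(angles$cone %||% 180))
      th <- rad2deg(acos(stats::runif(1, cmax, 1)))
      ph <- stats::runif(1, 0, 360)
      ps <- stats::runif(1, -(angles$inplane %||% 180),
                         angles$inplane %||% 180)
      matrix_to_euler(rot_z(ph) %*% rot_x(th) %*% rot_z(-ph) %*% rot_z(ps))
    },
    fixed_set = {
      tr <- angles$triplets
      as.numeric(tr[sample.int(nrow(tr), 1), ])
    },
    stop("unknown angle distribution: ", angles$type))
}

#' Simulate a particle dataset with known ground truth
#'
#' Each particle is `apply_wedge(shift(rotate(template, g_i), s_i), wedge)`
#' plus Gaussian noise whose variance is the masked signal variance divided
#' by the SNR. The ground-truth table stores `g_i`, `s_i` and the wedge.
#'
#' @param spec a [simulation_spec()].
#' @param template cubic volume of side `spec$L`.
#' @param dir optional directory; when given the dataset is written as a
#'   data folder.
#' @param mask mask under which the signal variance is measured (default:
#'   [default_mask()]).
#' @return list with `particles`, `table` (ground truth) and `clean` (the
#'   noise-free, wedge-filtered particles).
#' @export
simulate_dataset <- function(spec, template, dir = NULL, mask = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  L <- check_cubic(template, "template")
  if (L != spec$L) stop("template side must equal spec$L")
  if (is.null(mask)) mask <- default_mask(L)
  M <- sum(mask)
  with_seed(spec$seed, {
    particles <- vector("list", spec$N)
    clean <- vector("list", spec$N)
    tab <- particle_table(spec$N)
    tab$wedge_min <- spec$wedge$theta_min
    tab$wedge_max <- spec$wedge$theta_max
    for (i in seq_len(spec$N)) {
      g <- sample_euler(spec$angles)
      s <- if (spec$shift_halfwidth > 0)
        stats::runif(3, -spec$shift_halfwidth, spec$shift_halfwidth)
      else c(0, 0, 0)
      if (spec$integer_shifts) s <- round(s)
      cl <- apply_wedge(shift_volume(rotate_volume(template, g), s),
                        spec$wedge)
      p <- cl
      if (is.finite(spec$snr)) {
        mu <- sum(mask * cl) / M
        sig_var <- sum(mask * (cl - mu)^2) / M
        p <- cl + array(stats::rnorm(L^3, sd = sqrt(sig_var / spec$snr)),
                        c(L, L, L))
      }
      particles[[i]] <- p
      clean[[i]] <- cl
      tab[i, c("dx", "dy", "dz")] <- as.list(s)
      tab[i, c("tdrot", "tilt", "narot")] <- as.list(g)
    }
    if (!is.null(dir)) write_data_folder(particles, tab, dir)
    list(particles = particles, table = tab, clean = clean)
  })
}

#' Synthetic membrane tomogram
#'
#' A dark membrane shell of 2-3 voxel thickness on a bright background,
#' plus optional Gaussian noise; returns the analytic surface description
#' for oracle checks.
#'
#' @param shape `"sphere"` or `"plane"` (a plane of constant x, so every
#'   z-section shows it as a straight line).
#' @param dims brick dimensions, length 3.
#' @param radius sphere radius (shape `"sphere"`); the centre is the brick
#'   centre.
#' @param x0 plane coordinate (shape `"plane"`, default: centre).
#' @param contrast depth of the membrane minimum below the background.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed for the noise.
#' @param thickness_sigma Gaussian radial profile width; ~2.5 voxels of
#'   apparent thickness at the default.
#' @return list with `volume` and `surface` (analytic description).
#' @export
simulate_membrane_tomogram <- function(shape = c("sphere", "plane"),
                                       dims = c(96, 96, 96), radius = 30,
                                       x0 = NULL, contrast = 1,
                                       noise_sd = 0, seed = 1,
                                       thickness_sigma = 1.1) {
  shape <- match.arg(shape)
  ctr <- floor(dims / 2)
  i1 <- 0:(dims[1] - 1); i2 <- 0:(dims[2] - 1); i3 <- 0:(dims[3] - 1)
  if (shape == "sphere") {
    d <- sqrt(array((i1 - ctr[1])^2, dims) +
              array(rep((i2 - ctr[2])^2, each = dims[1]), dims) +
              array(rep((i3 - ctr[3])^2, each = dims[1] * dims[2]), dims))
    prof <- abs(d - radius)
    surface <- list(shape = "sphere", center = ctr, radius = radius)
  } else {
    x0 <- x0 %||% ctr[1]
    prof <- array(abs(i1 - x0), dims)
    surface <- list(shape = "plane", x0 = x0)
  }
  vol <- 1 - contrast * exp(-prof^2 / (2 * thickness_sigma^2))
  if (noise_sd > 0)
    vol <- vol + with_seed(seed,
      array(stats::rnorm(prod(dims), sd = noise_sd), dims))
  list(volume = vol, surface = surface)
}
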