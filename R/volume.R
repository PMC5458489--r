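# Elementary real-space and Fourier-space operators on cubic volumes.
#
# Volumes are plain 3-D numeric arrays with all three dimensions equal (side
# L voxels). The rotation centre is the voxel at 0-based index floor(L/2) on
# each axis, which coincides with the DC position of a centred ("fftshifted")
# Fourier grid, so real-space and Fourier-space centres agree for any L.

#' Rotate a cubic volume
#'
#' Resamples `vol` under the active rotation given by a ZXZ intrinsic Euler
#' triplet (degrees). Interpolation is trilinear; voxels whose source
#' coordinate falls outside the cube are filled with `fill` (default: the
#' mean of `vol`, which keeps masked correlation statistics unbiased). The
#' identity triplet returns the input unchanged, bit for bit.
#'
#' @param vol cubic 3-D numeric array.
#' @param euler Euler triplet in degrees (ZXZ intrinsic, active).
#' @param fill value used for voxels mapped from outside the cube.
#' @return rotated volume, same dimensions as `vol`.
#' @seealso [euler_to_matrix()] for the angle convention.
#' @export
rotate_volume <- function(vol, euler, fill = mean(vol)) {
  L <- check_cubic(vol)
  Rm <- euler_to_matrix(euler)
  if (max(abs(Rm - diag(3))) < 1e-12) return(vol)
  out <- .rotate_trilinear(as.double(vol), L, t(Rm), floor(L / 2), fill)
  array(out, dim(vol))
}

#' Translate a volume
#'
#' Integer shifts are exact circular translations; fractional shifts are
#' applied as Fourier phase ramps. A voxel at position `x` in the output
#' takes the value at `x - shift` in the input, so a positive shift moves
#' density towards larger indices.
#'
#' @param vol 3-D numeric array (need not be cubic).
#' @param shift numeric length-3 translation in voxels.
#' @return translated volume.
#' @export
shift_volume <- function(vol, shift) {
  stopifnot(length(shift) == 3)
  d <- dim(vol)
  if (is.null(d) || length(d) != 3) stop("vol must be a 3-D array")
  if (all(abs(shift - round(shift)) < 1e-9)) {
    s <- round(shift)
    if (all(s %% d == 0)) return(vol)
    ix <- lapply(1:3, function(a) ((seq_len(d[a]) - 1 - s[a]) %% d[a]) + 1)
    return(vol[ix[[1]], ix[[2]], ix[[3]], drop = FALSE])
  }
  fac <- lapply(1:3, function(a) {
    k <- seq_len(d[a]) - 1 - floor(d[a] / 2)     # centred frequencies
    f <- exp(-2i * pi * k * shift[a] / d[a])
    # even-length axes: the unpaired Nyquist frequency gets the real
    # cosine factor, keeping the operator real-to-real
    if (d[a] %% 2 == 0) f[1] <- cos(pi * shift[a])
    f[ifftshift_index(d[a])]                     # back to natural order
  })
  ramp <- array(fac[[1]], d) *
    array(rep(fac[[2]], each = d[1]), d) *
    array(rep(fac[[3]], each = d[1] * d[2]), d)
  Re(ifftn(fft(vol) * ramp))
}

#' Bandpass specification
#'
#' Radial Fourier filter with raised-cosine edges. The transfer function is
#' 1 for radii in `[low_radius, high_radius]` (Fourier pixels), rolls off as
#' a raised cosine of width `smoothing_width` on both sides, and is 0
#' beyond. A strictly positive `low_radius` always removes the DC term.
#'
#' @param low_radius,high_radius pass-band edges in Fourier pixels.
#' @param smoothing_width raised-cosine roll-off width in Fourier pixels;
#'   the default of 2 avoids the ringing of sharp edges.
#' @return an object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_radius, high_radius, smoothing_width = 2) {
  if (!is.numeric(low_radius) || !is.numeric(high_radius) ||
      !is.numeric(smoothing_width) || smoothing_width < 0 ||
      low_radius < 0 || high_radius <= low_radius)
    stop("invalid bandpass: need 0 <= low_radius < high_radius and smoothing_width >= 0")
  structure(list(low_radius = low_radius, high_radius = high_radius,
                 smoothing_width = smoothing_width),
            class = "bandpass_spec")
}

as_bandpass_spec <- function(x) {
  if (inherits(x, "bandpass_spec")) return(x)
  if (is.numeric(x) && length(x) %in% 2:3)
    return(bandpass_spec(x[1], x[2], if (length(x) == 3) x[3] else 2))
  stop("cannot interpret bandpass specification")
}

bandpass_transfer <- function(L, spec) {
  spec <- as_bandpass_spec(spec)
  key <- sprintf("bp_%d_%g_%g_%g", L, spec$low_radius, spec$high_radius,
                 spec$smoothing_width)
  cached(key, function() {
    r <- freq_grid(L)$r
    lo <- spec$low_radius; hi <- spec$high_radius; s <- spec$smoothing_width
    H <- array(0, dim(r))
    H[r >= lo & r <= hi] <- 1
    if (s > 0) {
      e <- r > lo - s & r < lo
      H[e] <- 0.5 * (1 + cos(pi * (lo - r[e]) / s))
      e <- r > hi & r < hi + s
      H[e] <- 0.5 * (1 + cos(pi * (r[e] - hi) / s))
    }
    if (lo > 0) H[r == 0] <- 0   # any non-zero low edge removes DC
    ifftshift3(H)
  })
}

#' Radial bandpass filter
#'
#' @param vol cubic 3-D numeric array.
#' @param spec a [bandpass_spec()] (or a numeric vector
#'   `c(low, high[, smoothing])`).
#' @return filtered, real-valued volume.
#' @export
bandpass_filter <- function(vol, spec) {
  L <- check_cubic(vol)
  Re(ifftn(fft(vol) * bandpass_transfer(L, spec)))
}

#' Missing-wedge descriptor
#'
#' Tilt range `[theta_min, theta_max]` in degrees describing which Fourier
#' coefficients were measured in a single-axis tilt acquisition. The full
#' range `(-90, 90)` denotes a wedge-free acquisition. Asymmetric ranges are
#' supported because real acquisitions are asymmetric.
#'
#' @param theta_min,theta_max tilt limits in degrees, both in `[-90, 90]`
#'   with `theta_min < theta_max`.
#' @return an object of class `wedge_descriptor`.
#' @export
wedge_descriptor <- function(theta_min, theta_max) {
  if (!is.numeric(theta_min) || !is.numeric(theta_max) ||
      theta_min >= theta_max || theta_min < -90 || theta_max > 90)
    stop("invalid wedge: need -90 <= theta_min < theta_max <= 90")
  structure(list(theta_min = theta_min, theta_max = theta_max),
            class = "wedge_descriptor")
}

as_wedge_descriptor <- function(x) {
  if (inherits(x, "wedge_descriptor")) return(x)
  if (is.numeric(x) && length(x) == 2) return(wedge_descriptor(x[1], x[2]))
  stop("cannot interpret wedge descriptor")
}

is_full_wedge <- function(w) {
  w <- as_wedge_descriptor(w)
  w$theta_min <= -90 && w$theta_max >= 90
}

#' Binary missing-wedge mask
#'
#' Returns the centred Fourier-domain mask of measured coefficients for a
#' single-axis acquisition with the tilt axis along the 2nd array axis (y)
#' and the beam along the 3rd axis (z) at zero tilt. A coefficient
#' `(k1, k2, k3)` is retained iff the signed angle `atan2(k3, k1)`, folded
#' into `[-90, 90]` by central (Friedel) symmetry, lies in
#' `[theta_min, theta_max]`; the `k1 = k3 = 0` line is always retained.
#'
#' @param L side length in voxels.
#' @param wedge a [wedge_descriptor()] (or numeric `c(theta_min, theta_max)`).
#' @return binary `L^3` array in centred Fourier layout (DC at 0-based index
#'   `floor(L/2)`).
#' @export
wedge_mask <- function(L, wedge) {
  wedge <- as_wedge_descriptor(wedge)
  key <- sprintf("wm_%d_%g_%g", L, wedge$theta_min, wedge$theta_max)
  cached(key, function() {
    fg <- freq_grid(L)
    ang <- rad2deg(atan2(fg$kz, fg$kx))
    ang <- ((ang + 90) %% 180) - 90
    ang[ang == -90 & wedge$theta_max >= 90] <- 90  # fold keeps +90 == -90
    m <- array(0, c(L, L, L))
    m[ang >= wedge$theta_min & ang <= wedge$theta_max] <- 1
    m[fg$kx == 0 & fg$kz == 0] <- 1
    m
  })
}

#' Fraction of Fourier coefficients retained by a wedge
#'
#' Measured within the Nyquist sphere (radius `L/2`), where the in-plane
#' angle is uniformly distributed and the retained fraction of a
#' single-axis wedge equals its analytic angular fraction
#' `(theta_max - theta_min) / 180`; the cube corners outside the sphere
#' carry no physically meaningful resolution and are excluded from the
#' measurement.
#'
#' @inheritParams wedge_mask
#' @return retained fraction in (0, 1].
#' @export
wedge_fraction_retained <- function(L, wedge) {
  m <- wedge_mask(L, wedge)
  r <- freq_grid(L)$r
  mean(m[r <= L / 2])
}

#' Apply a missing wedge to a volume
#'
#' Multiplies the spectrum of `vol` with the binary wedge mask and
#' transforms back; the output is real-valued and the operation is
#' idempotent (the mask is binary).
#'
#' @param vol cubic 3-D numeric array.
#' @inheritParams wedge_mask
#' @return wedge-filtered volume.
#' @export
apply_wedge <- function(vol, wedge) {
  L <- check_cubic(vol)
  if (is_full_wedge(wedge)) return(vol)
  Re(ifftn(fft(vol) * ifftshift3(wedge_mask(L, wedge))))
}

#' Normalize a volume under a mask
#'
#' Rescales `vol` so that its weighted mean is 0 and its weighted standard
#' deviation is 1 over the support of `mask` (weights = mask values in
#' `[0, 1]`); voxels where the mask is exactly 0 are set to 0. A volume that
#' is constant under the mask has no meaningful contrast and raises a
#' degenerate-variance error rather than silently returning zeros.
#'
#' @param vol 3-D numeric array.
#' @param mask non-negative weight array of the same dimensions, sum > 0.
#' @return normalized volume.
#' @export
normalize_under_mask <- function(vol, mask) {
  stopifnot(identical(dim(vol), dim(mask)))
  M <- sum(mask)
  if (M <= 0) stop("degenerate mask: all weights are zero")
  mu <- sum(mask * vol) / M
  sdev <- sqrt(sum(mask * (vol - mu)^2) / M)
  if (sdev < 1e-12)
    stop("degenerate variance: volume is constant under the mask")
  out <- (vol - mu) / sdev
  out[mask == 0] <- 0
  out
}

#' Default soft spherical alignment mask
#'
#' Sphere of radius `L/2 - 2` with a 2-voxel raised-cosine edge, centred on
#' the rotation centre.
#'
#' @param L side length in voxels.
#' @param radius sphere radius in voxels (value 1 inside `radius - edge`).
#' @param edge cosine edge width in voxels.
#' @return `L^3` array with values in `[0, 1]`.
#' @export
default_mask <- function(L, radius = L / 2 - 2, edge = 2) {
  key <- sprintf("mask_%d_%g_%g", L, radius, edge)
  cached(key, function() {
    c0 <- floor(L / 2)
    i <- (0:(L - 1)) - c0
    d <- sqrt(array(i^2, c(L, L, L)) +
              array(rep(i^2, each = L), c(L, L, L)) +
              array(rep(i^2, each = L * L), c(L, L, L)))
    m <- array(0, c(L, L, L))
    m[d <= radius - edge] <- 1
    e <- d > radius - edge & d < radius
    m[e] <- 0.5 * (1 + cos(pi * (d[e] - (radius - edge)) / edge))
    m
  })
}

#' Masked correlation of two volumes
#'
#' Pearson correlation of two volumes under a weight mask, with the masked
#' means removed — the standard figure of merit for comparing an average
#' against a reference inside the alignment mask.
#'
#' @param a,b volumes of identical dimensions.
#' @param mask non-negative weights (default: [default_mask()]).
#' @return correlation in `[-1, 1]`.
#' @export
masked_correlation <- function(a, b, mask = default_mask(dim(a)[1])) {
  stopifnot(identical(dim(a), dim(b)), identical(dim(a), dim(mask)))
  am <- a - sum(mask * a) / sum(mask)
  bm <- b - sum(mask * b) / sum(mask)
  sum(mask * am * bm) / sqrt(sum(mask * am^2) * sum(mask * bm^2))
}

#' Fourier cropping (binning)
#'
#' Downsamples a cubic volume by an integer factor by cropping its centred
#' spectrum, the standard anti-aliased binning of cryo-ET practice. Voxel
#' values are rescaled so grey levels remain comparable across binning
#' levels.
#'
#' @param vol cubic 3-D numeric array with side divisible by `factor`.
#' @param factor integer binning factor (1 returns the input).
#' @return volume of side `L / factor`.
#' @export
fourier_crop <- function(vol, factor) {
  L <- check_cubic(vol)
  factor <- as.integer(factor)
  if (factor == 1L) return(vol)
  if (L %% factor != 0) stop("side length not divisible by binning factor")
  Ls <- L %/% factor
  Fc <- fftshift3(fft(vol))
  c0 <- floor(L / 2); cs <- floor(Ls / 2)
  idx <- (c0 - cs + 1):(c0 - cs + Ls)
  Re(ifftn(ifftshift3(Fc[idx, idx, idx, drop = FALSE]))) / factor^3
}
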