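# Locally normalized cross-correlation and the single-particle alignment
# loop.
#
# The correlation of a template against a particle is recomputed under the
# mask at every candidate translation (local normalization), which makes the
# score invariant to affine changes of the particle's contrast. The map is
# evaluated for all translations at once through spectral convolutions of
# the particle and its square with the mask.

# Translation-dependent moments of the particle under the mask, plus the
# particle spectrum, shared by local_correlation_map() and align_particle()
# so both produce bit-identical scores.
particle_corr_stats <- function(particle, mask) {
  n <- length(particle)
  M <- sum(mask)
  if (M <= 0) stop("degenerate mask: all weights are zero")
  Fm <- Conj(fft(mask))
  Fp <- fft(particle)
  sum_p <- Re(fft(Fm * Fp, inverse = TRUE)) / n
  sum_p2 <- Re(fft(Fm * fft(particle^2), inverse = TRUE)) / n
  mu <- sum_p / M
  v <- sum_p2 / M - mu^2
  v[v < 0] <- 0
  sd_t <- sqrt(v)
  # variance floor: flat regions under the displaced mask score 0 instead
  # of dividing by ~0
  floor_sd <- 1e-6 * stats::sd(as.vector(particle))
  list(Fp = Fp, M = M, sd_t = sd_t, floor_sd = floor_sd)
}

corr_scores <- function(template_rw, mask, stats) {
  n <- length(template_rw)
  num <- Re(fft(Conj(fft(mask * template_rw)) * stats$Fp, inverse = TRUE)) / n
  den <- stats$M * stats$sd_t
  score <- num / den
  score[stats$sd_t < stats$floor_sd] <- 0
  score
}

valid_translation_mask <- function(L, shift_limit) {
  key <- sprintf("valid_%d_%g", L, shift_limit)
  cached(key, function() {
    fg <- freq_grid(L)  # centred offsets double as translation offsets
    abs(fg$kx) <= shift_limit & abs(fg$ky) <= shift_limit &
      abs(fg$kz) <= shift_limit
  })
}

#' Locally normalized cross-correlation map
#'
#' Scores every candidate translation `t` of a prepared template against a
#' particle:
#' `score(t) = sum_x mask(x) template(x) particle(x+t) / (M sigma_p(t))`,
#' where `M = sum(mask)` and `sigma_p(t)` is the standard deviation of the
#' particle under the mask displaced by `t`. The template is expected to be
#' already rotated, bandpassed, wedge-filtered and normalized to zero mean
#' and unit variance under the mask (see [normalize_under_mask()]), so its
#' own moments drop out of the formula. Translations outside the cube of
#' half-side `shift_limit` are marked invalid; translations where
#' `sigma_p(t)` falls below `1e-6` times the global particle standard
#' deviation score 0.
#'
#' @param particle cubic 3-D numeric array (bandpassed to the template's
#'   resolution).
#' @param template_rw prepared template (rotated, wedge-filtered,
#'   bandpassed, mask-normalized).
#' @param mask weight array with values in `[0, 1]`, sum > 0.
#' @param shift_limit largest allowed translation per axis, voxels.
#' @return an object of class `correlation_map`: `values` is the centred
#'   score array (zero translation at 0-based index `floor(L/2)`), `valid`
#'   the logical array of allowed translations.
#' @export
local_correlation_map <- function(particle, template_rw, mask, shift_limit) {
  L <- check_cubic(particle)
  stopifnot(identical(dim(particle), dim(template_rw)),
            identical(dim(particle), dim(mask)))
  st <- particle_corr_stats(particle, mask)
  values <- fftshift3(corr_scores(template_rw, mask, st))
  structure(list(values = values,
                 valid = valid_translation_mask(L, shift_limit),
                 shift_limit = shift_limit, L = L),
            class = "correlation_map")
}

#' Peak of a correlation map
#'
#' Maximum score over the valid translations; among tied maxima the
#' lexicographically smallest shift is returned, giving deterministic
#' results.
#'
#' @param map a `correlation_map`.
#' @return list with `cc` (peak score) and `shift` (length-3 integer
#'   translation in voxels).
#' @export
peak_translation <- function(map) {
  v <- map$values[map$valid]
  best <- max(v)
  idx <- which(map$valid & map$values == best)
  c0 <- floor(map$L / 2)
  off <- cbind((idx - 1) %% map$L,
               ((idx - 1) %/% map$L) %% map$L,
               (idx - 1) %/% (map$L^2)) - c0
  ord <- order(off[, 1], off[, 2], off[, 3])
  list(cc = best, shift = as.numeric(off[ord[1], ]))
}

# Template preparation for one grid rotation: rotate -> bandpass ->
# wedge-filter -> normalize under mask. Bandpass and wedge are both
# diagonal in Fourier space and commute; normalization must come last.
prepare_template <- function(template, euler, wedge, bandpass, mask) {
  t_r <- rotate_volume(template, euler)
  t_r <- bandpass_filter(t_r, bandpass)
  t_r <- apply_wedge(t_r, wedge)
  normalize_under_mask(t_r, mask)
}

#' Align one particle against a template
#'
#' Exhaustive search over an angular grid: for each of the R grid rotations
#' the template is rotated, bandpassed, filtered with the particle's
#' missing wedge and normalized under the mask, then scored against the
#' (bandpassed) particle at all allowed translations with
#' [local_correlation_map()]. The returned pose is the global maximum over
#' rotations and translations; ties are broken by the lowest rotation index,
#' then the lexicographically smallest shift. The particle is bandpassed
#' once (the filter does not depend on the rotation) and the wedge is
#' applied to the rotated template, so the reported shift is the
#' translation of the rotated template that best matches the particle:
#' `particle ~ shift_volume(rotate_volume(template, euler), shift)`.
#'
#' @param particle cubic 3-D numeric array.
#' @param template reference volume, same side length.
#' @param wedge the particle's [wedge_descriptor()].
#' @param grid an [make_angular_grid()] object.
#' @param bandpass a [bandpass_spec()].
#' @param mask alignment mask (default: [default_mask()]).
#' @param shift_limit largest allowed translation per axis, voxels.
#' @return list of class `alignment_result`: `shift`, `euler`, `cc`,
#'   `rotation_index`.
#' @export
align_particle <- function(particle, template, wedge, grid, bandpass,
                           mask = default_mask(dim(particle)[1]),
                           shift_limit = 4) {
  L <- check_cubic(particle)
  if (check_cubic(template, "template") != L ||
      check_cubic(mask, "mask") != L)
    stop("particle, template and mask must share the same side length")
  if (!inherits(grid, "angular_grid") || nrow(grid$triplets) < 1)
    stop("empty or invalid angular grid")

  pb <- bandpass_filter(particle, bandpass)
  st <- particle_corr_stats(pb, mask)
  valid <- valid_translation_mask(L, shift_limit)
  c0 <- floor(L / 2)

  best <- list(cc = -Inf, shift = c(0, 0, 0), euler = grid$triplets[1, ],
               rotation_index = 1L)
  for (r in seq_len(nrow(grid$triplets))) {
    e <- grid$triplets[r, ]
    tn <- prepare_template(template, e, wedge, bandpass, mask)
    sc <- fftshift3(corr_scores(tn, mask, st))
    m <- max(sc[valid])
    if (m > best$cc) {
      idx <- which(valid & sc == m)
      off <- cbind((idx - 1) %% L, ((idx - 1) %/% L) %% L,
                   (idx - 1) %/% (L^2)) - c0
      ord <- order(off[, 1], off[, 2], off[, 3])
      best <- list(cc = m, shift = as.numeric(off[ord[1], ]),
                   euler = e, rotation_index = r)
    }
  }
  structure(best, class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "Alignment: cc = %.4f, shift = (%g, %g, %g), euler = (%.2f, %.2f, %.2f)\n",
    x$cc, x$shift[1], x$shift[2], x$shift[3],
    x$euler[1], x$euler[2], x$euler[3]))
  invisible(x)
}
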