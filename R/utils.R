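# Shared internal helpers: Fourier layout, caches, argument checks.

.subtomo_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .subtomo_cache, inherits = FALSE))
    assign(key, make(), envir = .subtomo_cache)
  get(key, envir = .subtomo_cache, inherits = FALSE)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @noRd
check_cubic <- function(vol, what = "volume") {
  d <- dim(vol)
  if (is.null(d) || length(d) != 3L)
    stop(sprintf("%s must be a 3-D array", what), call. = FALSE)
  if (d[1] != d[2] || d[2] != d[3])
    stop(sprintf("%s must be cubic, got %s", what,
                 paste(d, collapse = "x")), call. = FALSE)
  d[1]
}

check_finite <- function(vol, what = "volume") {
  if (!all(is.finite(vol)))
    stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(vol)
}

# Index vectors for centering the DC component (fftshift) and its inverse.
# After fftshift the DC term sits at 0-based index floor(L/2), matching the
# real-space rotation centre used throughout the package.
fftshift_index <- function(L) ((seq_len(L) - 1 + floor(L / 2)) %% L) + 1
ifftshift_index <- function(L) ((seq_len(L) - 1 - floor(L / 2)) %% L) + 1

fftshift3 <- function(a) {
  s <- lapply(dim(a), fftshift_index)
  a[s[[1]], s[[2]], s[[3]], drop = FALSE]
}

ifftshift3 <- function(a) {
  s <- lapply(dim(a), ifftshift_index)
  a[s[[1]], s[[2]], s[[3]], drop = FALSE]
}

ifftn <- function(X) fft(X, inverse = TRUE) / length(X)

# Centered integer frequency coordinates and radius for an L^3 grid, cached.
freq_grid <- function(L) {
  cached(sprintf("freq_%d", L), function() {
    k <- seq_len(L) - 1 - floor(L / 2)
    kx <- array(k, c(L, L, L))
    ky <- array(rep(k, each = L), c(L, L, L))
    kz <- array(rep(k, each = L * L), c(L, L, L))
    list(kx = kx, ky = ky, kz = kz, r = sqrt(kx^2 + ky^2 + kz^2))
  })
}

# 0-based voxel coordinates of an L^3 grid as an (L^3 x 3) matrix, cached.
voxel_coords <- function(L) {
  cached(sprintf("crd_%d", L), function() {
    i <- 0:(L - 1)
    cbind(rep(i, times = L * L),
          rep(rep(i, each = L), times = L),
          rep(i, each = L * L))
  })
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators do not perturb unrelated randomness.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
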