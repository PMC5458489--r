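# Real-space and Fourier-space operators on cubic volumes.

test_that("rotation: identity is exact, axis rotations map voxels correctly", {
  L <- 16
  v <- rand_vol(L)
  expect_identical(rotate_volume(v, c(0, 0, 0)), v)

  # delta spike at (c+5, c, c); active 90 deg rotation about z sends the
  # offset (+5,0,0) to (0,+5,0)
  c0 <- floor(L / 2)
  d <- array(0, c(L, L, L))
  d[c0 + 5 + 1, c0 + 1, c0 + 1] <- 1
  r <- rotate_volume(d, c(90, 0, 0), fill = 0)
  peak <- which(r == max(r))
  expect_equal(max(r), 1, tolerance = 1e-12)
  expect_equal(c((peak - 1) %% L, ((peak - 1) %/% L) %% L,
                 (peak - 1) %/% L^2) - c0, c(0, 5, 0))

  expect_error(rotate_volume(array(0, c(4, 4, 5)), c(0, 0, 0)), "cubic")
})

test_that("rotation followed by its inverse restores a smooth blob", {
  L <- 32
  blob <- gaussian_blob(L)
  e <- c(33, 21, -40)
  back <- rotate_volume(rotate_volume(blob, e), euler_inverse(e))
  expect_lt(max(abs(back - blob)) / max(blob), 0.05)
})

test_that("shifts: integer exact and circular, fractional invertible", {
  L <- 16
  v <- rand_vol(L, 2)
  expect_identical(shift_volume(v, c(0, 0, 0)), v)

  c0 <- floor(L / 2)
  d <- array(0, c(L, L, L)); d[c0 + 1, c0 + 1, c0 + 1] <- 1
  s <- shift_volume(d, c(3, 0, 0))
  expect_equal(s[c0 + 3 + 1, c0 + 1, c0 + 1], 1)

  # fractional shifts are exactly invertible on Nyquist-free volumes (the
  # unpaired Nyquist planes of an even grid cannot carry a pure phase ramp)
  Fv <- subtomo:::fftshift3(fft(v))
  nyq <- 1
  Fv[nyq, , ] <- 0; Fv[, nyq, ] <- 0; Fv[, , nyq] <- 0
  vb <- Re(subtomo:::ifftn(subtomo:::ifftshift3(Fv)))
  sh <- c(0.6, -1.3, 2.2)
  back <- shift_volume(shift_volume(vb, sh), -sh)
  expect_lt(max(abs(back - vb)) / max(abs(vb)), 1e-10)
})

test_that("bandpass: all-pass and DC-removal limits, shell energies, linearity", {
  L <- 16
  v <- rand_vol(L, 3)
  allpass <- bandpass_spec(0, L / 2 + 8, 8)   # edges beyond the corner radius
  expect_lt(max(abs(bandpass_filter(v, allpass) - v)), 1e-10)

  con <- array(5, c(L, L, L))
  expect_equal(mean(bandpass_filter(con, bandpass_spec(1, 7, 2))), 0,
               tolerance = 1e-12)

  # hard-edged band [4, 8]: spectral energy vanishes outside, is preserved
  # per shell inside (direct spectrum binning oracle)
  bp <- bandpass_spec(4, 8, 0)
  out <- bandpass_filter(v, bp)
  r <- subtomo:::freq_grid(L)$r
  Pin <- abs(subtomo:::fftshift3(fft(v)))^2
  Pout <- abs(subtomo:::fftshift3(fft(out)))^2
  expect_lt(max(Pout[r < 4 | r > 8]), 1e-16 * max(Pin))
  inside <- r >= 4 & r <= 8
  expect_lt(max(abs(Pout[inside] - Pin[inside])) / max(Pin), 1e-10)

  w <- rand_vol(L, 4)
  lin <- bandpass_filter(2 * v - 3 * w, bp)
  expect_lt(max(abs(lin - (2 * bandpass_filter(v, bp) -
                             3 * bandpass_filter(w, bp)))), 1e-10)

  expect_error(bandpass_spec(5, 3), "bandpass")
})

test_that("wedge mask: limits, analytic fraction, Friedel symmetry", {
  L <- 32
  expect_true(all(wedge_mask(L, c(-90, 90)) == 1))
  expect_error(wedge_descriptor(60, -60), "wedge")

  # analytic angular fraction within the Nyquist sphere
  expect_lt(abs(wedge_fraction_retained(64, c(-60, 60)) - 2 / 3), 0.02)
  expect_lt(abs(wedge_fraction_retained(64, c(-30, 60)) - 0.5), 0.02)

  # point inversion through the Fourier origin (interior subgrid: for even
  # L the -L/2 planes have no mirrored counterpart)
  m <- wedge_mask(L, c(-60, 60))
  i <- 2:L
  expect_identical(m[i, i, i], m[rev(i), rev(i), rev(i)])
})

test_that("apply_wedge: identity for full range, idempotent, Parseval", {
  L <- 16
  v <- rand_vol(L, 5)
  expect_lt(max(abs(apply_wedge(v, c(-90, 90)) - v)), 1e-10)

  a1 <- apply_wedge(v, c(-60, 60))
  expect_lt(max(abs(apply_wedge(a1, c(-60, 60)) - a1)), 1e-10)

  ratio <- sum(a1^2) / sum(v^2)
  expect_lt(abs(ratio - mean(wedge_mask(L, c(-60, 60)))), 0.02)
})

test_that("normalize_under_mask enforces weighted moments and rejects degenerates", {
  L <- 16
  m <- default_mask(L)
  v <- rand_vol(L, 6)
  n <- normalize_under_mask(v, m)
  expect_equal(sum(m * n) / sum(m), 0, tolerance = 1e-10)
  expect_equal(sqrt(sum(m * n^2) / sum(m)), 1, tolerance = 1e-10)
  expect_true(all(n[m == 0] == 0))

  # an already-normalized volume under an all-ones mask is a fixed point
  ones <- array(1, c(L, L, L))
  z <- normalize_under_mask(v, ones)
  expect_lt(max(abs(normalize_under_mask(z, ones) - z)), 1e-10)

  expect_error(normalize_under_mask(array(3, c(L, L, L)), m), "variance")
  expect_error(normalize_under_mask(v, array(0, c(L, L, L))), "mask")
})

test_that("fourier_crop preserves grey levels and halves the grid", {
  L <- 32
  blob <- gaussian_blob(L, sigma = 5, offset = c(0, 0, 0))
  b <- fourier_crop(blob, 2)
  expect_equal(dim(b), c(16, 16, 16))
  expect_equal(mean(b), mean(blob), tolerance = 1e-10)
  expect_equal(max(b), max(blob), tolerance = 0.05)
})
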