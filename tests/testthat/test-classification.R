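# Pairwise cross-correlation matrix and PCA embedding.

make_two_class <- function(L = 16, n_per = 5, snr = 8) {
  mk <- function(ph, seed, tag0) {
    s <- simulation_spec(N = n_per, L = L, snr = snr, wedge = c(-60, 60),
                         angles = list(type = "uniform"),
                         shift_halfwidth = 1, seed = seed)
    d <- simulate_dataset(s, ph)
    d$table$tag <- tag0 + seq_len(n_per)
    d
  }
  dA <- mk(make_phantom("dumbbell", L), 1, 0)
  dB <- mk(make_phantom("L-shape", L), 2, n_per)
  list(particles = c(dA$particles, dB$particles),
       table = rbind(dA$table, dB$table))
}

test_that("identical copies give an all-ones matrix", {
  L <- 16
  ph <- make_phantom("dumbbell", L)
  tab <- particle_table(4)
  cm <- ccmatrix(rep(list(ph), 4), tab)
  expect_lt(max(abs(cm$values - 1)), 1e-6)
})

test_that("blockwise assembly matches the monolithic matrix exactly", {
  d <- make_two_class(n_per = 4)
  bp <- bandpass_spec(0, 8, 2)
  mono <- ccmatrix(d$particles, d$table, bandpass = bp)
  expect_lt(max(abs(mono$values - t(mono$values))), 1e-8)
  expect_lt(max(abs(diag(mono$values) - 1)), 1e-6)
  for (bs in c(1, 3, 5)) {
    blk <- ccmatrix(d$particles, d$table, bandpass = bp, block_size = bs)
    expect_lt(max(abs(mono$values - blk$values)), 1e-10)
  }
  expect_error(ccmatrix(list(), particle_table(0)), "empty")
})

test_that("two noise-free classes separate within > between", {
  d <- make_two_class(n_per = 5, snr = Inf)
  cm <- ccmatrix(d$particles, d$table, bandpass = bandpass_spec(0, 8, 2))
  C <- cm$values
  within <- c(C[1:5, 1:5][upper.tri(diag(5))], C[6:10, 6:10][upper.tri(diag(5))])
  between <- as.vector(C[1:5, 6:10])
  expect_gt(min(within), max(between))
})

test_that("relabelling particles permutes the matrix accordingly", {
  d <- make_two_class(n_per = 3)
  cm <- ccmatrix(d$particles, d$table)
  perm <- c(4, 1, 6, 2, 5, 3)
  cmp <- ccmatrix(d$particles[perm], d$table[perm, ])
  expect_lt(max(abs(cmp$values - cm$values[perm, perm])), 1e-12)
})

test_that("PCA: no structure collapses to a point, classes split on PC1", {
  ones <- matrix(1, 5, 5)
  pc <- pca_components(ones, 1)
  expect_lt(max(abs(pc$coordinates)), 1e-8)
  expect_lt(max(pc$variances), 1e-12)

  # block-diagonal two-class similarity (6x6 spectral oracle)
  C <- rbind(cbind(matrix(0.9, 3, 3), matrix(0.1, 3, 3)),
             cbind(matrix(0.1, 3, 3), matrix(0.9, 3, 3)))
  diag(C) <- 1
  pc2 <- pca_components(C, 2)
  s <- sign(pc2$coordinates[, 1])
  expect_true(all(s[1:3] == s[1]) && all(s[4:6] == -s[1]))
  expect_true(all(diff(pc2$variances) <= 1e-12))
  expect_error(pca_components(C, 6), "n_components")
})
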