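# Phantom generator and ground-truth simulations.

test_that("phantoms are compact, normalized and asymmetric", {
  for (kind in c("sphere-cluster", "dumbbell", "L-shape")) {
    ph <- make_phantom(kind, 32)
    expect_equal(max(ph), 1)
    corners <- ph[c(1, 32), c(1, 32), c(1, 32)]
    expect_true(all(corners == 0))
    expect_gt(sum(ph), 0)
  }
  # no accidental 4-fold symmetry about z
  ph <- make_phantom("L-shape", 32)
  m <- default_mask(32)
  expect_lt(masked_cor(ph, rotate_volume(ph, c(90, 0, 0)), m), 0.9)
  expect_error(make_phantom("cube", 32), "arg")
  expect_error(make_phantom("dumbbell", 8), "at least 16")
})

test_that("simulations are reproducible bit for bit given the seed", {
  L <- 16
  ph <- make_phantom("dumbbell", L)
  spec <- simulation_spec(N = 4, L = L, snr = 2, wedge = c(-60, 60),
                          angles = list(type = "uniform"),
                          shift_halfwidth = 2, seed = 7)
  d1 <- simulate_dataset(spec, ph)
  d2 <- simulate_dataset(spec, ph)
  expect_identical(d1$particles, d2$particles)
  expect_identical(d1$table, d2$table)
  # and the caller's RNG stream is untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulate_dataset(spec, ph)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noise-free particles match their construction; SNR is calibrated", {
  L <- 24
  ph <- make_phantom("sphere-cluster", L)
  spec0 <- simulation_spec(N = 5, L = L, snr = Inf, wedge = c(-60, 60),
                           angles = list(type = "uniform"),
                           shift_halfwidth = 1, seed = 9)
  d0 <- simulate_dataset(spec0, ph)
  m <- default_mask(L)
  for (i in 1:5)
    expect_gte(masked_cor(d0$particles[[i]], d0$clean[[i]], m), 0.999)

  # at SNR 1 the empirical noise variance equals the masked signal variance
  spec1 <- simulation_spec(N = 20, L = L, snr = 1, wedge = c(-60, 60),
                           angles = list(type = "uniform"),
                           shift_halfwidth = 1, seed = 10)
  d1 <- simulate_dataset(spec1, ph)
  M <- sum(m)
  ratios <- vapply(1:20, function(i) {
    noise <- d1$particles[[i]] - d1$clean[[i]]
    cl <- d1$clean[[i]]
    mu <- sum(m * cl) / M
    sig_var <- sum(m * (cl - mu)^2) / M
    mean(noise^2) / sig_var
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("pose sampling is uniform on the rotation group, not on angles", {
  # mean pairwise geodesic angle of uniform rotations is 126.47 degrees
  spec <- simulation_spec(N = 40, L = 16, snr = Inf, seed = 12)
  d <- simulate_dataset(spec, make_phantom("dumbbell", 16))
  eus <- as.matrix(d$table[, c("tdrot", "tilt", "narot")])
  pair <- combn(40, 2)
  angs <- vapply(seq_len(ncol(pair)), function(k)
    rot_dist(eus[pair[1, k], ], eus[pair[2, k], ]), numeric(1))
  expect_lt(abs(mean(angs) - (90 + 360 / pi^2)), 5)
})

test_that("membrane phantoms have their minima on the analytic surface", {
  sim <- simulate_membrane_tomogram("sphere", dims = c(48, 48, 48), radius = 15,
                                    contrast = 1, noise_sd = 0)
  ctr <- sim$surface$center
  i <- 0:47
  d <- sqrt(array((i - ctr[1])^2, c(48, 48, 48)) +
            array(rep((i - ctr[2])^2, each = 48), c(48, 48, 48)) +
            array(rep((i - ctr[3])^2, each = 48 * 48), c(48, 48, 48)))
  on_shell <- abs(d - 15) < 0.5
  expect_lt(max(sim$volume[on_shell]), min(sim$volume[d < 10]))

  simp <- simulate_membrane_tomogram("plane", dims = c(48, 48, 6), x0 = 20,
                                     contrast = 1, noise_sd = 0)
  resp <- membrane_response(simp$volume[, , 3])
  expect_equal(as.integer(which(resp == max(resp), arr.ind = TRUE)[1, 1]) - 1L,
               20L)
})
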