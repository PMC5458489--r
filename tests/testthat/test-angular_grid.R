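# Euler conventions and angular search grids.

test_that("euler triplets round-trip through rotation matrices", {
  set.seed(1)
  for (i in 1:20) {
    e <- c(runif(1, -180, 180), runif(1, 0, 180), runif(1, -180, 180))
    R <- euler_to_matrix(e)
    expect_lt(max(abs(euler_to_matrix(matrix_to_euler(R)) - R)), 1e-10)
  }
  # gimbal-locked poses
  expect_lt(max(abs(euler_to_matrix(matrix_to_euler(euler_to_matrix(c(30, 0, 40)))) -
                      euler_to_matrix(c(30, 0, 40)))), 1e-10)
  # inverse triplet
  e <- c(33, 21, -40)
  expect_lt(max(abs(euler_to_matrix(euler_inverse(e)) %*% euler_to_matrix(e) -
                      diag(3))), 1e-12)
})

test_that("degenerate ranges give exactly the centre pose", {
  g <- make_angular_grid(0, 10, 0, 10)
  expect_equal(nrow(g$triplets), 1)
  expect_equal(as.numeric(g$triplets[1, ]), c(0, 0, 0))

  ctr <- c(40, 30, -20)
  gc <- make_angular_grid(0, 10, 0, 10, center = ctr)
  expect_lt(rot_dist(gc$triplets[1, ], ctr), 1e-6)

  expect_error(make_angular_grid(10, 0, 10, 5), "positive")
})

test_that("full-sphere grid is separated and covering (brute force)", {
  g <- make_angular_grid(360, 30, 360, 30)
  dirs <- g$directions[!duplicated(round(g$directions, 6)), , drop = FALSE]
  # pairwise separation of distinct directions >= 15 degrees
  n <- nrow(dirs)
  cosmat <- dirs %*% t(dirs)
  diag(cosmat) <- -1
  expect_gte(min(acos(pmin(1, cosmat)) * 180 / pi), 15 - 1e-6)
  # covering: no random direction farther than 30 degrees from the grid
  set.seed(2)
  q <- matrix(rnorm(3 * 500), ncol = 3)
  q <- q / sqrt(rowSums(q^2))
  worst <- max(apply(q %*% t(dirs), 1, function(cc)
    min(acos(pmin(1, max(cc))) * 180 / pi)))
  expect_lte(worst, 30 + 1e-6)
})

test_that("cone grids stay inside the cone, around any centre", {
  g <- make_angular_grid(10, 5, 0, 1)
  ref <- c(0, 0, 1)
  angs <- acos(pmin(1, g$directions %*% ref)) * 180 / pi
  expect_lte(max(angs), 10 + 1e-6)

  ctr <- c(25, 50, 10)
  gc <- make_angular_grid(15, 5, 10, 5, center = ctr)
  refd <- subtomo:::euler_direction(ctr)
  angs <- acos(pmin(1, gc$directions %*% refd)) * 180 / pi
  expect_lte(max(angs), 15 + 1e-6)
})

test_that("refine_grid shrinks ranges geometrically and collapses in the limit", {
  prev <- structure(list(euler = c(10, 20, 30)), class = "alignment_result")
  g1 <- refine_grid(prev, level = 1, factor = 2,
                    cone_range = 20, cone_sampling = 10,
                    inplane_range = 20, inplane_sampling = 10)
  expect_equal(g1$cone_range, 10)
  expect_equal(g1$cone_sampling, 5)
  refd <- subtomo:::euler_direction(c(10, 20, 30))
  angs <- acos(pmin(1, g1$directions %*% refd)) * 180 / pi
  expect_lte(max(angs), 10 + 1e-6)

  g2 <- refine_grid(prev, level = 2, factor = 2,
                    cone_range = 20, cone_sampling = 10,
                    inplane_range = 20, inplane_sampling = 10)
  angs2 <- acos(pmin(1, g2$directions %*% refd)) * 180 / pi
  expect_lte(max(angs2), 5 + 1e-6)

  gh <- refine_grid(prev, level = 1, factor = 1e7,
                    cone_range = 20, cone_sampling = 10,
                    inplane_range = 20, inplane_sampling = 10)
  expect_equal(nrow(gh$triplets), 1)
  expect_lt(rot_dist(gh$triplets[1, ], c(10, 20, 30)), 1e-4)
})
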