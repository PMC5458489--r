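# Angular search grids.
#
# A grid is parametrized by a cone (half-angle `cone_range`, sampled
# quasi-uniformly with nearest-neighbour distance ~ `cone_sampling`, built
# ring by ring on the spherical cap) and an in-plane rotation range sampled
# at regular steps. Directions are composed with a centre pose so grids can
# be recentred on a particle's current orientation for local refinement.

#' Build an angular search grid
#'
#' Directions are sampled on the spherical cap of half-angle `cone_range`
#' around the direction encoded by `center` (rings at multiples of
#' `cone_sampling`, each ring holding `round(360 sin(theta) / cone_sampling)`
#' points). For each direction, in-plane angles are sampled on
#' `[-inplane_range, inplane_range]` at `inplane_sampling` steps. Duplicate
#' poses (equal rotations, e.g. from in-plane wrap-around) are removed.
#' With both ranges 0 the grid contains exactly the centre pose.
#'
#' @param cone_range cone half-angle in degrees (0 = no angular search;
#'   360 covers the full sphere).
#' @param cone_sampling angular distance between neighbouring directions,
#'   degrees, > 0.
#' @param inplane_range half-range of the in-plane rotation search, degrees.
#' @param inplane_sampling in-plane step, degrees, > 0.
#' @param center Euler triplet the grid is centred on (default identity).
#' @return an object of class `angular_grid` with elements `triplets`
#'   (R x 3 matrix of Euler triplets, degrees), `directions` (R x 3 unit
#'   vectors) and the generating parameters.
#' @export
make_angular_grid <- function(cone_range, cone_sampling,
                              inplane_range, inplane_sampling,
                              center = c(0, 0, 0)) {
  if (!is.numeric(cone_sampling) || cone_sampling <= 0 ||
      !is.numeric(inplane_sampling) || inplane_sampling <= 0)
    stop("sampling steps must be positive")
  if (cone_range < 0 || inplane_range < 0) stop("ranges must be non-negative")

  thetas <- if (cone_range == 0) 0 else seq(0, min(cone_range, 180),
                                            by = cone_sampling)
  dirs <- list()
  for (th in thetas) {
    if (th %in% c(0, 180)) {
      dirs[[length(dirs) + 1]] <- c(th, 0)
    } else {
      n <- max(1L, as.integer(round(360 * sin(deg2rad(th)) / cone_sampling)))
      for (ph in (0:(n - 1)) * 360 / n)
        dirs[[length(dirs) + 1]] <- c(th, ph)
    }
  }
  psis <- if (inplane_range == 0) 0 else
    seq(-inplane_range, inplane_range, by = inplane_sampling)

  Rc <- euler_to_matrix(center)
  trip <- matrix(0, length(dirs) * length(psis), 3)
  k <- 0
  for (d in dirs) {
    # tilt by theta about the in-plane axis at azimuth phi (conjugation),
    # so the azimuthal placement leaves the in-plane angle untouched
    Rd <- rot_z(d[2]) %*% rot_x(d[1]) %*% rot_z(-d[2])
    for (ps in psis) {
      k <- k + 1
      trip[k, ] <- matrix_to_euler(Rc %*% Rd %*% rot_z(ps))
    }
  }
  # drop duplicate rotations: greedy clustering by quaternion distance
  # (absolute tolerance 1e-4 degrees, far below any sensible sampling)
  qs <- t(apply(trip, 1, function(e) matrix_to_quat(euler_to_matrix(e))))
  dots <- abs(qs %*% t(qs))
  thr <- cos(deg2rad(1e-4) / 2)
  n <- nrow(trip)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    dup <- which(keep & dots[i, ] >= thr)
    keep[setdiff(dup, i)] <- FALSE
  }
  trip <- trip[keep, , drop = FALSE]
  dirv <- t(apply(trip, 1, euler_direction))

  structure(list(triplets = trip, directions = dirv,
                 cone_range = cone_range, cone_sampling = cone_sampling,
                 inplane_range = inplane_range,
                 inplane_sampling = inplane_sampling, center = center),
            class = "angular_grid")
}

#' @export
print.angular_grid <- function(x, ...) {
  cat(sprintf(
    "Angular grid: %d poses (cone %g/%g deg, in-plane %g/%g deg)\n",
    nrow(x$triplets), x$cone_range, x$cone_sampling,
    x$inplane_range, x$inplane_sampling))
  invisible(x)
}

#' Coarse-to-fine grid refinement
#'
#' Builds a grid centred on the pose of a previous alignment result, with
#' all ranges and sampling steps divided by `factor^level`.
#'
#' @param previous an alignment result (list with an `euler` element) or an
#'   Euler triplet.
#' @param level refinement level, >= 1.
#' @param factor shrink factor per level, > 1.
#' @param cone_range,cone_sampling,inplane_range,inplane_sampling base grid
#'   parameters (level 0), degrees.
#' @return an `angular_grid` centred on the previous pose.
#' @export
refine_grid <- function(previous, level, factor,
                        cone_range, cone_sampling,
                        inplane_range, inplane_sampling) {
  stopifnot(level >= 1, factor > 1)
  center <- if (is.list(previous)) previous$euler else previous
  f <- factor^level
  make_angular_grid(cone_range / f, cone_sampling / f,
                    inplane_range / f, inplane_sampling / f,
                    center = center)
}
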