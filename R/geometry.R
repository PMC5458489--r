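# Membrane-model workflow: track membrane points across tomogram sections,
# resample them by spline, triangulate the surface and seed regularly
# spaced particles oriented along the surface normals.
#
# Coordinates are 0-based voxel indices throughout; point sets are n x 3
# matrices (x, y, z).

# ------------------------------------------------------------- splines ----

#' Resample a curve by arc length
#'
#' Fits a cubic spline through the input points (periodic for closed
#' curves) parametrized by cumulative chord length, then resamples at
#' (near-)constant arc-length intervals. The interval count is chosen so
#' the realized spacing is within a rounding step of the request;
#' consecutive output distances are uniform to within ~2%.
#'
#' @param points n x 3 matrix of ordered points (>= 4 for open curves,
#'   >= 3 for closed ones).
#' @param spacing target arc-length spacing in voxels.
#' @param closed treat the point sequence as a closed loop.
#' @return resampled point matrix (for closed curves the first point is
#'   not repeated at the end).
#' @export
resample_spline <- function(points, spacing, closed = FALSE) {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  if ((closed && n < 3) || (!closed && n < 4))
    stop("too few points for a cubic spline")
  if (spacing <= 0) stop("spacing must be positive")
  if (closed) points <- rbind(points, points[1, ])
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0)) {
    keep <- c(TRUE, seg > 0)
    points <- points[keep, , drop = FALSE]
    seg <- sqrt(rowSums(diff(points)^2))
  }
  t0 <- c(0, cumsum(seg))
  method <- if (closed) "periodic" else "natural"
  fx <- stats::splinefun(t0, points[, 1], method = method)
  fy <- stats::splinefun(t0, points[, 2], method = method)
  fz <- stats::splinefun(t0, points[, 3], method = method)
  tt <- seq(0, max(t0), length.out = max(40 * nrow(points), 400))
  dense <- cbind(fx(tt), fy(tt), fz(tt))
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  total <- arc[length(arc)]
  m <- max(if (closed) 3 else 1, round(total / spacing))
  targets <- if (closed) (0:(m - 1)) * total / m else (0:m) * total / m
  tp <- stats::approx(arc, tt, xout = targets, ties = "ordered")$y
  cbind(fx(tp), fy(tp), fz(tp))
}

# ------------------------------------------------- membrane propagation ----

smooth2d <- function(img, sigma = 1, radius = 3) {
  off <- -radius:radius
  k <- exp(-off^2 / (2 * sigma^2)); k <- k / sum(k)
  d <- dim(img)
  # separable Gaussian, replicated edges
  tmp <- matrix(0, d[1], d[2]); out <- matrix(0, d[1], d[2])
  for (o in seq_along(off)) {
    i <- pmin(pmax(seq_len(d[1]) + off[o], 1), d[1])
    tmp <- tmp + k[o] * img[i, , drop = FALSE]
  }
  for (o in seq_along(off)) {
    j <- pmin(pmax(seq_len(d[2]) + off[o], 1), d[2])
    out <- out + k[o] * tmp[, j, drop = FALSE]
  }
  out
}

#' Membrane (ridge) response of a tomogram section
#'
#' Positive part of the Laplacian of the lightly smoothed section. For a
#' dark membrane on a bright background this peaks exactly on the membrane
#' centre line, with a single maximum across the profile; a plain gradient
#' magnitude would instead vanish on the centre of a symmetric membrane
#' and peak on both flanks.
#'
#' @param section 2-D numeric matrix.
#' @param sigma Gaussian smoothing width in voxels.
#' @return matrix of non-negative ridge responses.
#' @export
membrane_response <- function(section, sigma = 1) {
  s <- smooth2d(section, sigma)
  d <- dim(s)
  ip <- pmin(seq_len(d[1]) + 1, d[1]); im <- pmax(seq_len(d[1]) - 1, 1)
  jp <- pmin(seq_len(d[2]) + 1, d[2]); jm <- pmax(seq_len(d[2]) - 1, 1)
  lap <- s[ip, ] + s[im, ] + s[, jp] + s[, jm] - 4 * s
  lap[lap < 0] <- 0
  lap
}

#' Propagate membrane points to the next tomogram section
#'
#' For each seed on section `z`, searches the disk of radius
#' `search_radius` around the seed's lateral position on section
#' `z + direction` and keeps the pixel maximizing the membrane response
#' (gradient magnitude after light Gaussian smoothing). Seeds whose best
#' response falls below `floor_fraction` of the section's maximum response
#' (or that land on a featureless section) are flagged unpropagated rather
#' than fabricated.
#'
#' @param stack 3-D numeric array, sections along the third axis.
#' @param seeds n x 3 matrix of 0-based seed coordinates sharing one `z`,
#'   or n x 2 lateral coordinates plus the `section` argument.
#' @param search_radius lateral search radius in voxels.
#' @param section 0-based index of the seed section (default: taken from
#'   the seeds' third column).
#' @param direction +1 (towards larger z) or -1.
#' @param floor_fraction relative response floor for accepting a point.
#' @param smooth_sigma Gaussian smoothing width for the ridge response.
#' @param floor_value optional absolute response floor; overrides the
#'   relative rule. Anchoring the floor to the response at the user's
#'   seeds (as [membrane_workflow()] does) stops propagation on sections
#'   the membrane never reaches, where a purely relative rule would latch
#'   onto noise.
#' @return data frame with `x`, `y`, `z` (the new section), `propagated`
#'   and `response`; unpropagated rows keep the seed's lateral position.
#' @export
propagate_membrane_points <- function(stack, seeds, search_radius,
                                      section = NULL, direction = 1,
                                      floor_fraction = 0.1,
                                      floor_value = NULL,
                                      smooth_sigma = 1) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
  seeds <- matrix(as.numeric(seeds), nrow = nrow(seeds))
  if (nrow(seeds) == 0) stop("empty seed set")
  d <- dim(stack)
  z <- if (!is.null(section)) section else {
    zs <- unique(round(seeds[, 3]))
    if (length(zs) != 1) stop("seeds must share one section")
    zs
  }
  z1 <- z + direction
  if (z1 < 0 || z1 >= d[3]) stop("target section outside the stack")
  resp <- membrane_response(stack[, , z1 + 1], sigma = smooth_sigma)
  gmax <- max(resp)
  floor_resp <- floor_value %||% (floor_fraction * gmax)
  out <- data.frame(x = numeric(nrow(seeds)), y = numeric(nrow(seeds)),
                    z = z1, propagated = FALSE, response = 0)
  r2 <- search_radius^2
  for (s in seq_len(nrow(seeds))) {
    sx <- seeds[s, 1]; sy <- seeds[s, 2]
    xi <- max(0, ceiling(sx - search_radius)):min(d[1] - 1, floor(sx + search_radius))
    yi <- max(0, ceiling(sy - search_radius)):min(d[2] - 1, floor(sy + search_radius))
    sub <- resp[xi + 1, yi + 1, drop = FALSE]
    dx2 <- outer((xi - sx)^2, (yi - sy)^2, "+")
    sub[dx2 > r2] <- -Inf
    best <- max(sub)
    if (gmax > 0 && best >= floor_resp) {
      w <- which(sub == best)[1]
      ix <- xi[(w - 1) %% length(xi) + 1]
      iy <- yi[(w - 1) %/% length(xi) + 1]
      # sub-pixel refinement: 1-D parabolic fit through the peak
      refine <- function(m1, m0, p1) {
        den <- m1 - 2 * m0 + p1
        if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
      }
      px <- ix; py <- iy
      if (ix >= 1 && ix <= d[1] - 2)
        px <- ix + refine(resp[ix, iy + 1], resp[ix + 1, iy + 1],
                          resp[ix + 2, iy + 1])
      if (iy >= 1 && iy <= d[2] - 2)
        py <- iy + refine(resp[ix + 1, iy], resp[ix + 1, iy + 1],
                          resp[ix + 1, iy + 2])
      out$x[s] <- px
      out$y[s] <- py
      out$propagated[s] <- TRUE
      out$response[s] <- best
    } else {
      out$x[s] <- sx; out$y[s] <- sy
    }
  }
  out
}

# circular moving average along a closed ring (window of 3)
smooth_ring <- function(ring) {
  n <- nrow(ring)
  if (n < 4) return(ring)
  prev <- ring[c(n, seq_len(n - 1)), , drop = FALSE]
  nxt <- ring[c(seq_len(n)[-1], 1), , drop = FALSE]
  (prev + ring + nxt) / 3
}

# -------------------------------------------------------- triangulation ----

ring_band_faces <- function(iA, iB, A, B) {
  m <- nrow(A); n <- nrow(B)
  j0 <- which.min(colSums((t(B) - A[1, ])^2))
  ai <- function(i) ((i - 1) %% m) + 1
  bi <- function(j) ((j - 2 + j0) %% n) + 1
  faces <- matrix(0L, m + n, 3)
  i <- 1L; j <- 1L; f <- 0L
  while (i <= m || j <= n) {
    advance_a <- if (i > m) FALSE else if (j > n) TRUE else {
      da <- sum((A[ai(i + 1), ] - B[bi(j), ])^2)
      db <- sum((A[ai(i), ] - B[bi(j + 1), ])^2)
      da <= db
    }
    f <- f + 1L
    if (advance_a) {
      faces[f, ] <- c(iA[ai(i)], iA[ai(i + 1)], iB[bi(j)])
      i <- i + 1L
    } else {
      faces[f, ] <- c(iA[ai(i)], iB[bi(j + 1)], iB[bi(j)])
      j <- j + 1L
    }
  }
  faces[seq_len(f), , drop = FALSE]
}

face_geometry <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  list(centroids = (v1 + v2 + v3) / 3, normals = nrm, norm2 = len,
       areas = len / 2)
}

#' Triangulate a membrane surface from section contours
#'
#' Each section's contour is resampled at `mesh_parameter` spacing (the
#' target edge length), consecutive contours are stitched ring by ring
#' into triangle bands, and (optionally) the first and last rings are
#' closed with centroid fans. Face normals are oriented away from the
#' surface's interior centroid.
#'
#' @param sections list of point matrices (>= 2 sections, each >= 3
#'   points), ordered along the stacking direction.
#' @param mesh_parameter target triangle edge length in voxels.
#' @param closed treat each contour as a closed loop.
#' @param cap_ends close the first and last rings with triangle fans.
#' @return object of class `triangulated_surface` with `vertices`,
#'   `faces` (m x 3 vertex indices) and `normals` (unit face normals).
#' @export
triangulate_surface <- function(sections, mesh_parameter, closed = TRUE,
                                cap_ends = FALSE) {
  if (length(sections) < 2) stop("need at least two sections")
  rings <- lapply(sections, function(p) {
    p <- matrix(as.numeric(p), ncol = 3)
    if (nrow(p) < 3) stop("each section needs at least three points")
    resample_spline(p, mesh_parameter, closed = closed)
  })
  for (r in rings)
    if (anyDuplicated(round(r, 6)) || !all(is.finite(r)))
      stop("degenerate contour (repeated or non-finite points)")
  offs <- cumsum(c(0, vapply(rings, nrow, 0L)))
  vertices <- do.call(rbind, rings)
  faces <- list()
  for (s in seq_len(length(rings) - 1)) {
    iA <- offs[s] + seq_len(nrow(rings[[s]]))
    iB <- offs[s + 1] + seq_len(nrow(rings[[s + 1]]))
    faces[[length(faces) + 1]] <-
      ring_band_faces(iA, iB, rings[[s]], rings[[s + 1]])
  }
  if (cap_ends && closed) {
    for (end in c(1, length(rings))) {
      ring <- rings[[end]]
      ctr <- colMeans(ring)
      vertices <- rbind(vertices, ctr)
      ci <- nrow(vertices)
      ii <- offs[end] + seq_len(nrow(ring))
      nxt <- c(ii[-1], ii[1])
      faces[[length(faces) + 1]] <- cbind(ii, nxt, ci)
    }
  }
  faces <- do.call(rbind, faces)
  geo <- face_geometry(vertices, faces)
  ok <- geo$norm2 > 1e-12
  faces <- faces[ok, , drop = FALSE]
  geo <- face_geometry(vertices, faces)
  normals <- geo$normals / geo$norm2
  # orient normals away from the interior centroid
  ctr <- colMeans(vertices)
  flip <- rowSums(normals * sweep(geo$centroids, 2, ctr)) < 0
  normals[flip, ] <- -normals[flip, ]
  faces[flip, ] <- faces[flip, c(1, 3, 2), drop = FALSE]
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "triangulated_surface")
}

#' Laplacian smoothing of a triangulated surface
#'
#' Moves every vertex a fraction `lambda` towards the mean of its edge
#' neighbours, `iterations` times, then recomputes and reorients the face
#' normals. Damps sub-voxel detection noise in surfaces built from traced
#' membrane points; the mild shrinkage is second order in the edge length
#' over the curvature radius.
#'
#' @param surface a `triangulated_surface`.
#' @param iterations smoothing passes (each a positive step followed by a
#'   negative one).
#' @param lambda positive step fraction in (0, 1].
#' @param mu negative (inflating) step fraction; the default pairs with
#'   `lambda` in the classic Taubin scheme, which damps noise without the
#'   shrinkage of plain Laplacian smoothing.
#' @return the smoothed surface.
#' @export
smooth_surface <- function(surface, iterations = 8, lambda = 0.5,
                           mu = -0.53) {
  V <- surface$vertices; Fc <- surface$faces
  edges <- rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  adj <- split(edges[, 2], edges[, 1])
  adj <- lapply(adj, unique)
  ids <- as.integer(names(adj))
  pass <- function(V, step) {
    Vn <- V
    for (k in seq_along(adj))
      Vn[ids[k], ] <- V[ids[k], ] +
        step * (colMeans(V[adj[[k]], , drop = FALSE]) - V[ids[k], ])
    Vn
  }
  for (it in seq_len(iterations)) {
    V <- pass(V, lambda)
    if (mu != 0) V <- pass(V, mu)
  }
  surface$vertices <- V
  geo <- face_geometry(V, Fc)
  normals <- geo$normals / pmax(geo$norm2, 1e-12)
  ctr <- colMeans(V)
  flip <- rowSums(normals * sweep(geo$centroids, 2, ctr)) < 0
  normals[flip, ] <- -normals[flip, ]
  surface$faces[flip, ] <- Fc[flip, c(1, 3, 2), drop = FALSE]
  surface$normals <- normals
  surface
}

#' Total area of a triangulated surface
#'
#' @param surface a `triangulated_surface`.
#' @return sum of the face areas.
#' @export
surface_area <- function(surface)
  sum(face_geometry(surface$vertices, surface$faces)$areas)

#' Flip the orientation of a surface
#'
#' Reverses every face winding and normal; particle orientations derived
#' from a flipped surface flip exactly.
#'
#' @param surface a `triangulated_surface`.
#' @return the reoriented surface.
#' @export
flip_surface <- function(surface) {
  surface$faces <- surface$faces[, c(1, 3, 2), drop = FALSE]
  surface$normals <- -surface$normals
  surface
}

#' @export
print.triangulated_surface <- function(x, ...) {
  cat(sprintf("Triangulated surface: %d vertices, %d faces, area %.1f\n",
              nrow(x$vertices), nrow(x$faces), surface_area(x)))
  invisible(x)
}

# Euler triplet rotating the reference z-axis onto a unit normal, with the
# undetermined in-plane angle set to 0.
normal_to_euler <- function(n) {
  n <- n / sqrt(sum(n^2))
  b <- rad2deg(acos(max(-1, min(1, n[3]))))
  a <- if (abs(n[1]) < 1e-12 && abs(n[2]) < 1e-12) 0
       else rad2deg(atan2(n[1], -n[2]))
  c(a, b, 0)
}

subdivide_candidates <- function(v1, v2, v3, max_edge) {
  e <- max(sum((v1 - v2)^2), sum((v2 - v3)^2), sum((v1 - v3)^2))
  if (e <= max_edge^2) return(matrix((v1 + v2 + v3) / 3, 1, 3))
  m12 <- (v1 + v2) / 2; m23 <- (v2 + v3) / 2; m13 <- (v1 + v3) / 2
  rbind(subdivide_candidates(v1, m12, m13, max_edge),
        subdivide_candidates(m12, v2, m23, max_edge),
        subdivide_candidates(m13, m23, v3, max_edge),
        subdivide_candidates(m12, m23, m13, max_edge))
}

#' Seed particles regularly on a surface
#'
#' Candidate points are generated densely on the faces and accepted
#' greedily (in a deterministic pseudo-random order) under a minimum
#' pairwise distance of `0.8 * particle_spacing`, which saturates to about
#' one particle per `particle_spacing^2` of area. Each particle's
#' orientation is the Euler triplet rotating the z-axis onto the normal of
#' its face, with the in-plane angle (undetermined by a normal) set to 0.
#'
#' @param surface a `triangulated_surface`.
#' @param particle_spacing target spacing in voxels.
#' @return a particle table; positions in `x,y,z`, orientations in
#'   `tdrot,tilt,narot`. The sampled points and their normals are attached
#'   as attributes `points` and `normals`.
#' @export
particles_on_surface <- function(surface, particle_spacing) {
  if (particle_spacing <= 0) stop("particle spacing must be positive")
  V <- surface$vertices; Fc <- surface$faces
  extent <- max(apply(V, 2, function(v) diff(range(v))))
  if (particle_spacing > extent) {
    warning("particle spacing exceeds the surface extent; returning a single centroid particle")
    ctr <- colMeans(V)
    nrm <- colMeans(surface$normals)
    pts <- matrix(ctr, 1, 3)
    faceid <- which.max(rowSums(surface$normals * nrm))
    normals <- surface$normals[faceid, , drop = FALSE]
  } else {
    cand <- list(); cface <- list()
    for (f in seq_len(nrow(Fc))) {
      cs <- subdivide_candidates(V[Fc[f, 1], ], V[Fc[f, 2], ], V[Fc[f, 3], ],
                                 0.45 * particle_spacing)
      cand[[f]] <- cs
      cface[[f]] <- rep(f, nrow(cs))
    }
    cand <- do.call(rbind, cand)
    cface <- unlist(cface)
    # deterministic pseudo-random visiting order (golden-ratio hash)
    ord <- order((seq_len(nrow(cand)) * 0.6180339887498949) %% 1)
    cand <- cand[ord, , drop = FALSE]; cface <- cface[ord]
    dmin2 <- (0.8 * particle_spacing)^2
    acc <- matrix(0, nrow(cand), 3); accf <- integer(nrow(cand)); na <- 0L
    for (i in seq_len(nrow(cand))) {
      p <- cand[i, ]
      if (na > 0) {
        d2 <- (acc[seq_len(na), 1] - p[1])^2 +
              (acc[seq_len(na), 2] - p[2])^2 +
              (acc[seq_len(na), 3] - p[3])^2
        if (min(d2) < dmin2) next
      }
      na <- na + 1L
      acc[na, ] <- p; accf[na] <- cface[i]
    }
    pts <- acc[seq_len(na), , drop = FALSE]
    normals <- surface$normals[accf[seq_len(na)], , drop = FALSE]
  }
  tab <- particle_table(nrow(pts))
  tab[, c("x", "y", "z")] <- pts
  tab[, c("tdrot", "tilt", "narot")] <-
    t(apply(normals, 1, normal_to_euler))
  attr(tab, "points") <- pts
  attr(tab, "normals") <- normals
  tab
}

# Smooth pole closure: where section tracking runs out (the membrane turns
# parallel to the sections), extrapolate the meridian profile (z, mean ring
# radius) of the last traced rings with a fitted circle and emit synthetic
# rings along the arc towards the apex, so the closing cap is faceted at
# the same mesh resolution instead of one flat fan.
extend_pole <- function(rings, mesh_parameter, end = c("last", "first")) {
  end <- match.arg(end)
  if (end == "first") {
    out <- extend_pole(rev(rings), mesh_parameter, "last")
    return(rev(out))
  }
  n <- length(rings)
  if (n < 4) return(rings)
  m <- min(6L, n)
  sel <- (n - m + 1L):n
  ctrs <- t(vapply(rings[sel], colMeans, numeric(3)))
  rs <- vapply(seq_len(m), function(k)
    mean(sqrt(rowSums(sweep(rings[[sel[k]]][, 1:2, drop = FALSE], 2,
                            ctrs[k, 1:2])^2))), numeric(1))
  zs <- ctrs[, 3]
  dz <- zs[m] - zs[m - 1]; dr <- rs[m] - rs[m - 1]
  if (abs(dz) < 1e-9 || dr >= -0.2) return(rings)  # not shrinking: no cap
  # Kasa circle fit in the (z, r) meridian plane
  A <- cbind(2 * zs, 2 * rs, 1)
  b <- zs^2 + rs^2
  fit <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(fit)) return(rings)
  zc <- fit[1]; rc <- fit[2]
  Rc <- sqrt(max(fit[3] + zc^2 + rc^2, 1e-12))
  phi0 <- atan2(rs[m] - rc, zs[m] - zc)
  # walk along the arc in the direction of decreasing radius
  dphi <- mesh_parameter / Rc
  sgn <- if ((cos(phi0) * dz - 0 ) >= 0) 1 else -1   # continue past z of last ring
  test <- rc + Rc * sin(phi0 + sgn * 1e-3)
  if (test > rs[m]) sgn <- -sgn                       # pick the shrinking branch
  ctr_xy <- colMeans(rings[[n]][, 1:2, drop = FALSE])
  phi <- phi0
  added <- 0L
  repeat {
    phi <- phi + sgn * dphi
    r_new <- rc + Rc * sin(phi)
    z_new <- zc + Rc * cos(phi)
    if (added >= 8L) break
    if (r_new <= 0.35 * mesh_parameter || r_new >= rs[m]) break
    if (abs(z_new - zs[m]) > 1.2 * Rc) break
    np <- max(3L, as.integer(round(2 * pi * r_new / mesh_parameter)))
    th <- (0:(np - 1)) * 2 * pi / np
    rings[[length(rings) + 1]] <- cbind(ctr_xy[1] + r_new * cos(th),
                                        ctr_xy[2] + r_new * sin(th), z_new)
    added <- added + 1L
  }
  rings
}

# ------------------------------------------------------------ workflow ----

#' Full membrane workflow: seeds to oriented particles
#'
#' Chains the membrane tools: propagate the seed ring section by section in
#' both stacking directions, resample each detected ring at
#' `control_spacing`, triangulate at `mesh_parameter` (capping the ends)
#' and seed particles at `particle_spacing`. Propagation stops when points
#' stop being detected or the ring becomes too small to resample.
#'
#' @param tomogram 3-D numeric array.
#' @param seeds n x 3 matrix of 0-based seed coordinates on one section.
#' @param control_spacing spacing of the spline control points, voxels.
#' @param mesh_parameter target triangulation edge length, voxels.
#' @param particle_spacing particle spacing, voxels.
#' @param search_radius lateral search radius for propagation, voxels.
#' @return list with `surface`, `particles` (a particle table) and `rings`
#'   (the resampled per-section contours).
#' @export
membrane_workflow <- function(tomogram, seeds, control_spacing,
                              mesh_parameter, particle_spacing,
                              search_radius = 5) {
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  z0 <- unique(round(seeds[, 3]))
  if (length(z0) != 1) stop("seeds must lie on one section")
  d <- dim(tomogram)

  # absolute propagation floor anchored to the membrane response at the
  # user's seeds, so propagation halts on membrane-free sections
  smooth_sigma <- 1.5
  resp0 <- membrane_response(tomogram[, , z0 + 1], sigma = smooth_sigma)
  si <- cbind(pmin(pmax(round(seeds[, 1]), 0), d[1] - 1) + 1,
              pmin(pmax(round(seeds[, 2]), 0), d[2] - 1) + 1)
  floor_value <- 0.5 * stats::median(resp0[si])

  trace_dir <- function(direction) {
    rings <- list()
    pts <- seeds
    z <- z0
    repeat {
      z1 <- z + direction
      if (z1 < 0 || z1 >= d[3]) break
      nxt <- propagate_membrane_points(tomogram, cbind(pts[, 1:2], z),
                                       search_radius, section = z,
                                       direction = direction,
                                       floor_value = floor_value,
                                       smooth_sigma = smooth_sigma)
      ok <- nxt$propagated
      if (sum(ok) < 3 || mean(ok) < 0.5) break
      ring_pts <- cbind(nxt$x[ok], nxt$y[ok], z1)
      ring_pts <- ring_pts[!duplicated(round(ring_pts, 3)), , drop = FALSE]
      if (nrow(ring_pts) < 3) break
      perim <- sum(sqrt(rowSums((ring_pts -
        ring_pts[c(2:nrow(ring_pts), 1), , drop = FALSE])^2)))
      if (perim < 3 * control_spacing) break
      ring <- tryCatch(resample_spline(ring_pts, control_spacing,
                                       closed = TRUE),
                       error = function(e) NULL)
      if (is.null(ring) || nrow(ring) < 3) break
      rings[[length(rings) + 1]] <- ring
      pts <- ring
      z <- z1
    }
    rings
  }

  ring0 <- resample_spline(seeds, control_spacing, closed = TRUE)
  up <- trace_dir(+1)
  down <- trace_dir(-1)
  rings <- c(rev(down), list(ring0), up)
  # triangulate on rings spaced ~ mesh_parameter apart along the MERIDIAN
  # (near-equilateral faces; stacking every 1-voxel section would make the
  # facet normals hostage to sub-voxel detection noise, while a fixed
  # z-step under-resolves regions where the surface runs oblique to the
  # sections), each kept ring lightly smoothed along its arc
  ctrs <- t(vapply(rings, colMeans, numeric(3)))
  radii <- vapply(seq_along(rings), function(k)
    mean(sqrt(rowSums(sweep(rings[[k]][, 1:2, drop = FALSE], 2,
                            ctrs[k, 1:2])^2))), numeric(1))
  arc <- c(0, cumsum(sqrt(diff(ctrs[, 3])^2 + diff(radii)^2)))
  keep <- 1L
  for (k in seq_along(rings)[-1])
    if (arc[k] - arc[keep[length(keep)]] >= mesh_parameter) keep <- c(keep, k)
  keep <- unique(c(keep, length(rings)))
  tri_rings <- lapply(rings[keep], smooth_ring)
  tri_rings <- extend_pole(tri_rings, mesh_parameter, end = "first")
  tri_rings <- extend_pole(tri_rings, mesh_parameter, end = "last")
  surface <- triangulate_surface(tri_rings, mesh_parameter, closed = TRUE,
                                 cap_ends = TRUE)
  surface <- smooth_surface(surface, iterations = 32)
  particles <- particles_on_surface(surface, particle_spacing)
  list(surface = surface, particles = particles, rings = rings)
}
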