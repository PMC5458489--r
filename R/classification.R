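# Pairwise cross-correlation matrix and PCA coordinates for particle
# classification.
#
# Particles are first moved into the common reference frame using their
# table poses; entry (i, j) is then the masked, bandpassed, normalized
# correlation of particles i and j at zero shift, computed in Fourier
# space over the INTERSECTION of the two particles' rotated wedge masks so
# that only jointly measured coefficients are compared. The matrix is
# assembled from independent rectangular blocks (each block a task for the
# task pool); because every entry is computed by the same expression, the
# blockwise result is identical to a monolithic computation.

prepare_for_ccmatrix <- function(particles, table, mask, bandpass) {
  check_table(table)
  N <- nrow(table)
  if (N == 0) stop("empty particle set")
  from_dir <- is.character(particles)
  L <- NULL
  Fs <- vector("list", N); Ws <- vector("list", N)
  for (i in seq_len(N)) {
    p <- if (from_dir) read_volume(particle_file(particles, table$tag[i]),
                                   cubic = TRUE) else particles[[i]]
    if (is.null(L)) L <- check_cubic(p)
    einv <- euler_inverse(table_euler(table, i))
    a <- rotate_volume(shift_volume(p, -table_shift(table, i)), einv)
    if (!is.null(bandpass)) a <- bandpass_filter(a, bandpass)
    if (is.null(mask)) mask <- default_mask(L)
    mu <- sum(mask * a) / sum(mask)
    Fs[[i]] <- fft(mask * (a - mu))
    wr <- rotated_wedge_mask(L, table_wedge(table, i), einv)
    Ws[[i]] <- ifftshift3(wr >= 0.5)  # binarized for a clean intersection
  }
  list(Fs = Fs, Ws = Ws, L = L)
}

cc_entry <- function(Fi, Fj, Wi, Wj) {
  W <- Wi & Wj
  num <- sum(Re(Fi[W] * Conj(Fj[W])))
  den <- sqrt(sum(abs(Fi[W])^2) * sum(abs(Fj[W])^2))
  if (den == 0) return(0)
  num / den
}

#' Pairwise cross-correlation matrix
#'
#' @param particles list of cubic volumes or a data-folder path.
#' @param table particle table with the pose aligning each particle into
#'   the common frame.
#' @param mask real-space mask applied after alignment (default:
#'   [default_mask()]).
#' @param bandpass optional [bandpass_spec()] applied to every particle.
#' @param block_size side of the rectangular computation blocks (default:
#'   the whole matrix as one block).
#' @param n_workers,semaphore_mode task-pool settings for block execution.
#' @return an object of class `cc_matrix` with `values` (N x N symmetric
#'   matrix, unit diagonal) and `block_size`.
#' @export
ccmatrix <- function(particles, table, mask = NULL, bandpass = NULL,
                     block_size = NULL, n_workers = 1,
                     semaphore_mode = "none") {
  prep <- prepare_for_ccmatrix(particles, table, mask, bandpass)
  N <- length(prep$Fs)
  block_size <- as.integer(block_size %||% N)
  if (block_size < 1) stop("block_size must be >= 1")
  starts <- seq(1L, N, by = block_size)
  blocks <- lapply(starts, function(s) s:min(s + block_size - 1L, N))
  nb <- length(blocks)
  pairs <- list()
  for (a in seq_len(nb)) for (b in a:nb)
    pairs[[length(pairs) + 1]] <- c(a, b)

  tasks <- lapply(pairs, function(ab) {
    force(ab)
    list(id = paste0("block_", ab[1], "_", ab[2]), fun = function() {
      ia <- blocks[[ab[1]]]; ib <- blocks[[ab[2]]]
      sub <- matrix(0, length(ia), length(ib))
      for (i in seq_along(ia)) for (j in seq_along(ib)) {
        gi <- ia[i]; gj <- ib[j]
        if (ab[1] == ab[2] && gj < gi) next
        sub[i, j] <- cc_entry(prep$Fs[[gi]], prep$Fs[[gj]],
                              prep$Ws[[gi]], prep$Ws[[gj]])
      }
      sub
    })
  })
  pool <- task_pool(tasks, n_workers = n_workers,
                    semaphore_mode = semaphore_mode)
  values <- matrix(0, N, N)
  for (t in seq_along(pairs)) {
    ab <- pairs[[t]]
    ia <- blocks[[ab[1]]]; ib <- blocks[[ab[2]]]
    sub <- pool$results[[t]]
    values[ia, ib] <- sub
    if (ab[1] == ab[2]) {
      # fill the lower triangle of a diagonal block from the upper
      di <- values[ia, ib, drop = FALSE]
      dd <- diag(length(ia)) * di
      values[ia, ib] <- di + t(di) - dd
    } else {
      values[ib, ia] <- t(sub)
    }
  }
  dimnames(values) <- list(table$tag, table$tag)
  structure(list(values = values, block_size = block_size),
            class = "cc_matrix")
}

#' @export
print.cc_matrix <- function(x, ...) {
  cat(sprintf("Cross-correlation matrix: %d particles (block size %d)\n",
              nrow(x$values), x$block_size))
  invisible(x)
}

#' PCA coordinates from a cross-correlation matrix
#'
#' Eigendecomposition of the double-centred matrix (the classical-scaling
#' construction): coordinates are eigenvectors scaled by the square root of
#' their (non-negative) eigenvalues, ordered by decreasing variance.
#' Negative eigenvalues, which can arise because wedge-intersection
#' correlations need not form a Gram matrix, are truncated to zero in the
#' coordinates and reported unchanged in `eigenvalues`.
#'
#' @param matrix a `cc_matrix` or a plain symmetric numeric matrix.
#' @param n_components number of components, `1 <= n_components < N`.
#' @return list with `coordinates` (N x n_components), `variances`
#'   (truncated, non-increasing) and `eigenvalues` (untruncated).
#' @export
pca_components <- function(matrix, n_components) {
  C <- if (inherits(matrix, "cc_matrix")) matrix$values else matrix
  N <- nrow(C)
  if (n_components < 1 || n_components >= N)
    stop("need 1 <= n_components < N")
  J <- diag(N) - 1 / N
  G <- J %*% C %*% J
  G <- (G + t(G)) / 2
  ee <- eigen(G, symmetric = TRUE)
  lam <- ee$values[seq_len(n_components)]
  coords <- ee$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(pmax(lam, 0)), n_components)
  rownames(coords) <- rownames(C)
  list(coordinates = coords, variances = pmax(lam, 0),
       eigenvalues = ee$values)
}

#' Export PCA coordinates as delimited text
#'
#' @param components result of [pca_components()].
#' @param path destination path (tab-separated, one row per particle).
#' @export
write_pca_coordinates <- function(components, path) {
  df <- data.frame(tag = rownames(components$coordinates) %||%
                     seq_len(nrow(components$coordinates)),
                   components$coordinates)
  names(df)[-1] <- paste0("pc", seq_len(ncol(components$coordinates)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
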