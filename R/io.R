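# Volume, table and list I/O; subtomogram cropping.
#
# Volumes travel as MRC (mode 2, 32-bit float, primary format) or as the
# common single-volume EM flavour. Particle metadata travels as a
# whitespace-delimited plain-text table with a fixed column order:
#
#   tag cc dx dy dz tdrot tilt narot ref wedge_min wedge_max x y z
#
# Coordinate convention, stated loudly: positions are 0-based voxel indices
# INTERNALLY and 1-based IN TABLE FILES (for ecosystem familiarity); the
# conversion happens only at the read/write boundary. Shifts and angles are
# relative quantities and are never converted.

TABLE_COLUMNS <- c("tag", "cc", "dx", "dy", "dz", "tdrot", "tilt", "narot",
                   "ref", "wedge_min", "wedge_max", "x", "y", "z")

#' Create an empty particle table
#'
#' @param n number of rows.
#' @return data frame with the package's fixed column layout: `tag`
#'   (unique positive id), `cc` (correlation), `dx,dy,dz` (shift, voxels),
#'   `tdrot,tilt,narot` (Euler triplet, degrees), `ref` (reference index),
#'   `wedge_min,wedge_max` (tilt range, degrees), `x,y,z` (position in the
#'   tomogram, 0-based voxels, `NA` when unset).
#' @export
particle_table <- function(n = 0) {
  data.frame(tag = seq_len(n), cc = numeric(n),
             dx = numeric(n), dy = numeric(n), dz = numeric(n),
             tdrot = numeric(n), tilt = numeric(n), narot = numeric(n),
             ref = rep(1L, n),
             wedge_min = rep(-90, n), wedge_max = rep(90, n),
             x = rep(NA_real_, n), y = rep(NA_real_, n), z = rep(NA_real_, n))
}

check_table <- function(table) {
  miss <- setdiff(TABLE_COLUMNS, names(table))
  if (length(miss)) stop("particle table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(table$tag)) stop("particle tags must be unique")
  invisible(table)
}

table_shift <- function(table, i) as.numeric(table[i, c("dx", "dy", "dz")])
table_euler <- function(table, i) as.numeric(table[i, c("tdrot", "tilt", "narot")])
table_wedge <- function(table, i)
  wedge_descriptor(table$wedge_min[i], table$wedge_max[i])

# ---------------------------------------------------------------- MRC ----

mrc_mode_info <- function(mode) {
  switch(as.character(mode),
         "0" = list(what = "integer", size = 1L, signed = TRUE),
         "1" = list(what = "integer", size = 2L, signed = TRUE),
         "2" = list(what = "numeric", size = 4L, signed = TRUE),
         "6" = list(what = "integer", size = 2L, signed = FALSE),
         NULL)
}

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 4 * 23)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  info <- mrc_mode_info(mode)
  if (is.null(info))
    stop(sprintf("unsupported MRC mode field: %d (expected 0, 1, 2 or 6)",
                 mode))
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5))
    stop(sprintf("implausible MRC dimension fields: %d x %d x %d",
                 nx, ny, nz))
  n <- as.double(nx) * ny * nz
  expected <- 1024 + nsymbt + n * info$size
  actual <- file.size(path)
  if (actual < expected)
    stop(sprintf("truncated MRC file: expected %d bytes, found %d",
                 expected, actual))
  seek(con, 1024 + nsymbt)
  data <- readBin(con, info$what, n = n, size = info$size,
                  signed = info$signed, endian = "little")
  vol <- array(as.double(data), c(nx, ny, nz))
  attr(vol, "voxel_size") <- if (hdr[8] > 0) cella[1] / hdr[8] else 1
  vol
}

write_mrc <- function(vol, path, voxel_size = 1) {
  d <- dim(vol)
  if (is.null(d) || length(d) != 3) stop("vol must be a 3-D array")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(d * voxel_size, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(vol), max(vol), mean(vol))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4, endian = "little")  # ispg, nsymbt
  writeBin(raw(4 * 27), con)                                  # extra (25..51)
  writeBin(as.integer(0L), con, size = 4, endian = "little")  # word 52
  writeBin(charToRaw("MAP "), con)                            # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)            # machine stamp
  writeBin(as.numeric(stats::sd(as.vector(vol))), con, size = 4,
           endian = "little")
  writeBin(as.integer(0L), con, size = 4, endian = "little")  # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(as.vector(vol)), con, size = 4, endian = "little")
  invisible(path)
}

# ----------------------------------------------------------------- EM ----

read_em <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h4 <- readBin(con, "integer", n = 4, size = 1, signed = FALSE)
  dtype <- h4[4]
  if (dtype != 5)
    stop(sprintf("unsupported EM data-type field: %d (only 5 = float32)",
                 dtype))
  d <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  if (any(d <= 0)) stop("implausible EM dimension fields")
  n <- as.double(d[1]) * d[2] * d[3]
  expected <- 512 + 4 * n
  if (file.size(path) < expected)
    stop(sprintf("truncated EM file: expected %d bytes, found %d",
                 expected, file.size(path)))
  seek(con, 512)
  array(readBin(con, "numeric", n = n, size = 4, endian = "little"), d)
}

write_em <- function(vol, path) {
  d <- dim(vol)
  if (is.null(d) || length(d) != 3) stop("vol must be a 3-D array")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(6, 0, 0, 5)), con)  # machine = PC, dtype = float32
  writeBin(as.integer(d), con, size = 4, endian = "little")
  writeBin(raw(512 - 16), con)
  writeBin(as.numeric(as.vector(vol)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a volume from disk
#'
#' Format is chosen by extension: `.em` reads the common single-volume EM
#' flavour, anything else is treated as MRC. Particles and templates must
#' be cubic; tomogram bricks need not be.
#'
#' @param path file path.
#' @param cubic if `TRUE`, a non-cubic volume is a shape error (use for
#'   particles/templates).
#' @return 3-D numeric array; MRC volumes carry a `voxel_size` attribute.
#' @export
read_volume <- function(path, cubic = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  vol <- if (grepl("\\.em$", path, ignore.case = TRUE)) read_em(path)
         else read_mrc(path)
  if (cubic) check_cubic(vol, path)
  vol
}

#' Write a volume to disk
#'
#' MRC mode 2 (32-bit float) by default; `.em` paths are written in EM
#' format. Round-tripping a volume already stored in 32-bit precision is
#' lossless.
#'
#' @param vol 3-D numeric array.
#' @param path destination; extension selects the format.
#' @param voxel_size voxel size recorded in the MRC header (Angstrom or
#'   arbitrary units).
#' @export
write_volume <- function(vol, path, voxel_size = 1) {
  if (grepl("\\.em$", path, ignore.case = TRUE)) write_em(vol, path)
  else write_mrc(vol, path, voxel_size)
}

# -------------------------------------------------------------- tables ----

#' Read a particle table
#'
#' Whitespace-delimited text, one row per particle, columns in the package's
#' fixed order (see [particle_table()]). File positions are 1-based and are
#' converted to the internal 0-based convention on read; positions written
#' as 0 in the file (unset) become `NA`.
#'
#' @param path file path.
#' @return particle table data frame.
#' @export
read_table_particles <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) stop("empty particle table: ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  nc <- lengths(fields)
  bad <- which(nc != length(TABLE_COLUMNS))
  if (length(bad))
    stop(sprintf("parse error in %s: row %d has %d columns (expected %d)",
                 path, bad[1], nc[bad[1]], length(TABLE_COLUMNS)))
  m <- matrix(as.numeric(unlist(fields)), ncol = length(TABLE_COLUMNS),
              byrow = TRUE)
  tab <- as.data.frame(m)
  names(tab) <- TABLE_COLUMNS
  tab$tag <- as.integer(tab$tag)
  tab$ref <- as.integer(tab$ref)
  for (cc in c("x", "y", "z")) {
    unset <- tab[[cc]] == 0
    tab[[cc]] <- tab[[cc]] - 1          # 1-based on disk -> 0-based internal
    tab[[cc]][unset] <- NA_real_
  }
  check_table(tab)
}

#' Write a particle table
#'
#' Values are printed with full precision (`%.17g`); positions are shifted
#' to the 1-based file convention, with `NA` written as 0.
#'
#' @param table particle table data frame.
#' @param path destination path.
#' @export
write_table_particles <- function(table, path) {
  check_table(table)
  out <- table[, TABLE_COLUMNS]
  for (cc in c("x", "y", "z")) {
    v <- out[[cc]] + 1                  # 0-based internal -> 1-based on disk
    v[is.na(v)] <- 0
    out[[cc]] <- v
  }
  lines <- apply(out, 1, function(r)
    paste(sprintf("%.17g", as.numeric(r)), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Import a classic 35-column particle table
#'
#' Maps the relevant columns of the widespread 35-column subtomogram table
#' layout onto this package's layout: tag (1), shifts (4-6), Euler angles
#' (7-9), cc (10), wedge tilt range (14-15), class/reference (22) and
#' positions (24-26, converted from 1- to 0-based).
#'
#' @param path file path to a 35-column table.
#' @return particle table data frame.
#' @export
read_table_legacy <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) < 26) stop("legacy table needs at least 26 columns, found ",
                         ncol(m))
  tab <- particle_table(nrow(m))
  tab$tag <- as.integer(m[, 1]); tab$cc <- m[, 10]
  tab[, c("dx", "dy", "dz")] <- m[, 4:6]
  tab[, c("tdrot", "tilt", "narot")] <- m[, 7:9]
  tab$wedge_min <- m[, 14]; tab$wedge_max <- m[, 15]
  tab$ref <- as.integer(m[, 22])
  tab[, c("x", "y", "z")] <- m[, 24:26] - 1
  check_table(tab)
}

# ---------------------------------------------------------------- lists ----

#' Read a tomogram list
#'
#' Plain text, one tomogram path per line; blank lines and lines starting
#' with `#` are ignored. Entries receive sequential ids. Missing files and
#' duplicate paths are reported as warnings, not errors, so lists can be
#' prepared before the data arrive.
#'
#' @param path file path.
#' @return data frame with columns `id` and `path`.
#' @export
read_tomogram_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty tomogram list: ", path)
  if (anyDuplicated(lines))
    warning("duplicate tomogram paths in ", path)
  missing <- lines[!file.exists(lines)]
  if (length(missing))
    warning("tomogram files not found: ", paste(missing, collapse = ", "))
  data.frame(id = seq_along(lines), path = lines, stringsAsFactors = FALSE)
}

# ---------------------------------------------------------- data folder ----

particle_file <- function(dir, tag) file.path(dir, sprintf("particle_%05d.mrc", tag))

#' Write a data folder
#'
#' A data folder pairs one MRC file per particle (`particle_<tag>.mrc`)
#' with its metadata table (`table.tbl`).
#'
#' @param particles list of cubic volumes, in table row order.
#' @param table particle table data frame.
#' @param dir destination directory (created if needed).
#' @export
write_data_folder <- function(particles, table, dir) {
  check_table(table)
  if (length(particles) != nrow(table))
    stop("particle count does not match table rows")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(particles))
    write_mrc(particles[[i]], particle_file(dir, table$tag[i]))
  write_table_particles(table, file.path(dir, "table.tbl"))
  invisible(dir)
}

#' Read a data folder
#'
#' @param dir directory written by [write_data_folder()] (or laid out the
#'   same way).
#' @return list with `particles` (list of volumes, table row order) and
#'   `table`.
#' @export
read_data_folder <- function(dir) {
  table <- read_table_particles(file.path(dir, "table.tbl"))
  particles <- lapply(table$tag, function(tg)
    read_volume(particle_file(dir, tg), cubic = TRUE))
  list(particles = particles, table = table)
}

# ------------------------------------------------------------- cropping ----

#' Extract subtomograms from a tomogram
#'
#' For each position (0-based tomogram voxel coordinates) the `L^3` cube
#' whose centre voxel (offset `floor(L/2)`) sits at the rounded position is
#' extracted; the residual sub-voxel offset is recorded in the table's
#' shift columns. Positions too close to the border for a full cube are
#' skipped and reported.
#'
#' @param tomogram 3-D numeric array (brick; need not be cubic).
#' @param positions n x 3 matrix of 0-based voxel coordinates, or a
#'   particle table with `x`, `y`, `z` columns.
#' @param L even cube side length.
#' @param dir optional directory; when given, particles and table are
#'   written as a data folder.
#' @return list with `particles`, `table` (positions of retained
#'   particles, residual offsets in `dx..dz`) and `skipped` (indices of
#'   skipped input positions).
#' @export
crop_subtomograms <- function(tomogram, positions, L, dir = NULL) {
  if (L %% 2 != 0) stop("cube side L must be even")
  if (is.data.frame(positions)) positions <- as.matrix(positions[, c("x", "y", "z")])
  positions <- matrix(as.numeric(positions), ncol = 3)
  d <- dim(tomogram)
  c0 <- floor(L / 2)
  keep <- integer(0); parts <- list(); resid <- NULL
  for (i in seq_len(nrow(positions))) {
    p <- positions[i, ]
    pr <- round(p)
    lo <- pr - c0           # 0-based start of the cube
    if (any(lo < 0) || any(lo + L > d)) next
    keep <- c(keep, i)
    parts[[length(parts) + 1]] <-
      tomogram[lo[1] + 1:L, lo[2] + 1:L, lo[3] + 1:L, drop = FALSE]
    resid <- rbind(resid, p - pr)
  }
  if (!length(keep)) stop("all positions fall outside the tomogram bounds")
  skipped <- setdiff(seq_len(nrow(positions)), keep)
  if (length(skipped))
    message(length(skipped), " position(s) skipped at the tomogram border")
  tab <- particle_table(length(keep))
  tab$tag <- seq_along(keep)
  tab[, c("dx", "dy", "dz")] <- resid
  tab[, c("x", "y", "z")] <- positions[keep, , drop = FALSE]
  if (!is.null(dir)) write_data_folder(parts, tab, dir)
  list(particles = parts, table = tab, skipped = skipped)
}
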