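# The iterative subtomogram-averaging engine.
#
# A project bundles data, templates, masks and per-iteration numerical
# settings. Each iteration aligns every particle against each of the K
# current references (independently), assigns each particle to its
# best-correlating reference, applies the selection policy per reference
# and forms a wedge-compensated average that becomes the next reference.
# All per-particle work is dispatched through the task pool; results are
# merged by particle tag, so the outcome is a pure function of
# (configuration, data, templates) regardless of worker count.

#' Project configuration
#'
#' Per-iteration parameters may be given as length-1 vectors (broadcast to
#' all iterations) or as vectors of length `n_iterations`.
#'
#' @param n_iterations number of alignment/averaging iterations.
#' @param n_references number of references K (multireference alignment
#'   when K > 1).
#' @param cone_range,cone_sampling,inplane_range,inplane_sampling angular
#'   grid parameters per iteration, degrees (see [make_angular_grid()]).
#' @param bandpass_low,bandpass_high,bandpass_smooth radial bandpass per
#'   iteration, Fourier pixels.
#' @param shift_limit largest allowed translation per iteration, voxels.
#' @param threshold_mode `"fraction"` (keep the best fraction of particles
#'   per reference) or `"absolute"` (keep particles with cc above a value).
#' @param threshold_value fraction in (0, 1] or absolute cc threshold.
#' @param binning Fourier-cropping level per iteration (0 = none; level b
#'   bins by `2^b` and rescales shifts accordingly).
#' @param n_workers worker count for the task pool.
#' @param semaphore_mode task claim coordination, see [task_pool()].
#' @param seed seed recorded with the project; the engine itself is
#'   deterministic and uses no randomness.
#' @return an object of class `project_config`.
#' @export
project_config <- function(n_iterations = 1, n_references = 1,
                           cone_range = 360, cone_sampling = 15,
                           inplane_range = 360, inplane_sampling = 15,
                           bandpass_low = 0, bandpass_high = NULL,
                           bandpass_smooth = 2,
                           shift_limit = 4,
                           threshold_mode = "fraction", threshold_value = 1,
                           binning = 0,
                           n_workers = 1, semaphore_mode = "none",
                           seed = 1) {
  bcast <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1) rep(x, n_iterations)
    else if (length(x) == n_iterations) x
    else stop(sprintf("%s must have length 1 or n_iterations", what))
  }
  if (threshold_mode == "fraction" &&
      (threshold_value <= 0 || threshold_value > 1))
    stop("threshold fraction must be in (0, 1]")
  structure(list(
    n_iterations = as.integer(n_iterations),
    n_references = as.integer(n_references),
    cone_range = bcast(cone_range, "cone_range"),
    cone_sampling = bcast(cone_sampling, "cone_sampling"),
    inplane_range = bcast(inplane_range, "inplane_range"),
    inplane_sampling = bcast(inplane_sampling, "inplane_sampling"),
    bandpass_low = bcast(bandpass_low, "bandpass_low"),
    bandpass_high = bcast(bandpass_high, "bandpass_high"),
    bandpass_smooth = bcast(bandpass_smooth, "bandpass_smooth"),
    shift_limit = bcast(shift_limit, "shift_limit"),
    threshold_mode = threshold_mode, threshold_value = threshold_value,
    binning = as.integer(bcast(binning, "binning")),
    n_workers = as.integer(n_workers), semaphore_mode = semaphore_mode,
    seed = as.integer(seed)), class = "project_config")
}

#' Write / read a project configuration as flat key=value text
#'
#' @param config a [project_config()].
#' @param path destination file.
#' @export
write_project_config <- function(config, path) {
  keys <- setdiff(names(config), NULL)
  lines <- vapply(keys, function(k)
    paste0(k, "=", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_project_config
#' @export
read_project_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    suppressWarnings({n <- as.numeric(v)})
    if (!anyNA(n)) n else v
  })
  names(vals) <- vapply(kv, `[[`, "", 1)
  do.call(project_config, vals[names(vals) %in% names(formals(project_config))])
}

#' Select particles for averaging
#'
#' Mode `"fraction"` keeps the `ceiling(f * N)` particles of highest cc
#' (ties broken towards the lower tag); mode `"absolute"` keeps particles
#' with `cc >= value`.
#'
#' @param table particle table (rows considered for selection).
#' @param policy list with `mode` and `value`.
#' @return integer row indices of the selected particles.
#' @export
select_particles <- function(table, policy) {
  if (nrow(table) == 0) stop("empty particle table")
  if (policy$mode == "fraction") {
    f <- policy$value
    if (f <= 0 || f > 1) stop("threshold fraction must be in (0, 1]")
    n_sel <- ceiling(f * nrow(table))
    ord <- order(-table$cc, table$tag)
    sort(ord[seq_len(n_sel)])
  } else if (policy$mode == "absolute") {
    which(table$cc >= policy$value)
  } else stop("unknown threshold mode: ", policy$mode)
}

#' Assign a particle to its best reference
#'
#' @param cc_per_reference vector of the best correlation attained against
#'   each reference.
#' @return index of the winning reference (ties go to the lowest index).
#' @export
mra_assign <- function(cc_per_reference) {
  if (!length(cc_per_reference)) stop("empty correlation vector")
  which.max(cc_per_reference)
}

rotated_wedge_mask <- function(L, wedge, euler_inv) {
  wm <- wedge_mask(L, wedge)
  wr <- rotate_volume(wm, euler_inv, fill = 0)
  wr[wr < 0] <- 0
  wr[wr > 1] <- 1
  wr
}

#' Wedge-compensated average of aligned particles
#'
#' Each selected particle is moved into the reference frame by undoing its
#' table pose (shift first, then rotation, the inverse of the
#' template-to-particle transform stored in the table). The average
#' compensates the missing wedge in Fourier space: the summed particle
#' spectra are divided by the summed (rotated) wedge masks, so coefficients
#' measured in only some particles are weighted correctly instead of being
#' averaged against zeros. Coefficients whose summed coverage falls below
#' `max(min_coverage, eps * K_sel)` were measured by no particle (up to
#' interpolation leakage) and are set to zero rather than divided by a tiny
#' denominator, which would amplify leakage by orders of magnitude.
#'
#' @param particles list of cubic volumes or a data-folder path.
#' @param table particle table holding pose and wedge per particle.
#' @param selection row indices to average (default: all rows).
#' @param eps relative coverage floor (fraction of the selection size).
#' @param min_coverage absolute coverage floor, in units of one particle's
#'   wedge mask; 0.5 means "at least half a particle measured this
#'   coefficient".
#' @return the average volume.
#' @export
average_particles <- function(particles, table, selection = seq_len(nrow(table)),
                              eps = 1e-3, min_coverage = 0.5) {
  check_table(table)
  if (!length(selection)) stop("empty selection")
  from_dir <- is.character(particles)
  get_particle <- function(i) {
    if (from_dir) read_volume(particle_file(particles, table$tag[i]),
                              cubic = TRUE)
    else particles[[i]]
  }
  first <- get_particle(selection[1])
  L <- check_cubic(first)
  num <- array(0 + 0i, c(L, L, L))
  den <- array(0, c(L, L, L))
  for (i in selection) {
    p <- get_particle(i)
    einv <- euler_inverse(table_euler(table, i))
    aligned <- rotate_volume(shift_volume(p, -table_shift(table, i)), einv)
    num <- num + fft(aligned)
    den <- den + ifftshift3(rotated_wedge_mask(L, table_wedge(table, i), einv))
  }
  floor_cov <- max(min_coverage, eps * length(selection))
  out <- num / pmax(den, floor_cov)
  out[den < floor_cov] <- 0
  Re(ifftn(out))
}

# One particle's alignment against all current references; grid centred on
# the particle's current pose.
align_particle_task <- function(p, row, refs, grid_params, bp, mask,
                                shift_limit) {
  grid <- make_angular_grid(grid_params[1], grid_params[2], grid_params[3],
                            grid_params[4],
                            center = as.numeric(row[c("tdrot", "tilt", "narot")]))
  wedge <- wedge_descriptor(row$wedge_min, row$wedge_max)
  lapply(refs, function(ref)
    align_particle(p, ref, wedge, grid, bp, mask, shift_limit))
}

#' Run an iterative alignment project
#'
#' @param config a [project_config()].
#' @param data a data-folder path or a list with `particles` (list of
#'   volumes) and `table`.
#' @param templates list of K initial reference volumes (or paths).
#' @param mask alignment mask (default: [default_mask()]).
#' @param outdir optional directory; when given, every iteration's
#'   references, table and audit log are persisted under
#'   `ite_0001`, `ite_0002`, ...
#' @return an object of class `project_results`: `tables` (per iteration),
#'   `references` (per iteration, list of K volumes), `selections` (per
#'   iteration, per reference row indices), `audit` (task dispatch log) and
#'   the final `table`.
#' @export
run_project <- function(config, data, templates, mask = NULL, outdir = NULL) {
  stopifnot(inherits(config, "project_config"))
  if (is.character(data)) data <- read_data_folder(data)
  particles <- data$particles
  table <- check_table(data$table)
  if (length(particles) != nrow(table))
    stop("particle count does not match table rows")
  templates <- lapply(templates, function(t)
    if (is.character(t)) read_volume(t, cubic = TRUE) else t)
  K <- config$n_references
  if (length(templates) != K)
    stop(sprintf("expected %d templates, got %d", K, length(templates)))
  L <- check_cubic(particles[[1]], "particle")
  for (p in particles) if (check_cubic(p) != L)
    stop("all particles must share the same side length")
  for (t in templates) if (check_cubic(t, "template") != L)
    stop("templates must match the particle side length")
  if (is.null(mask)) mask <- default_mask(L)
  if (check_cubic(mask, "mask") != L) stop("mask must match particle size")
  policy <- list(mode = config$threshold_mode, value = config$threshold_value)
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  results <- list(tables = list(), references = list(), selections = list(),
                  audit = list())
  refs <- templates
  for (it in seq_len(config$n_iterations)) {
    bin <- config$binning[it]
    f <- 2^bin
    bp_high <- config$bandpass_high[it] %||% (L / f / 2)
    bp <- bandpass_spec(config$bandpass_low[it] / f, bp_high,
                        config$bandpass_smooth[it])
    grid_params <- c(config$cone_range[it], config$cone_sampling[it],
                     config$inplane_range[it], config$inplane_sampling[it])
    sl <- config$shift_limit[it] / f
    if (bin > 0) {
      parts_it <- lapply(particles, fourier_crop, factor = f)
      refs_it <- lapply(refs, fourier_crop, factor = f)
      mask_it <- fourier_crop(mask, f)
      mask_it[mask_it < 0] <- 0; mask_it[mask_it > 1] <- 1
    } else {
      parts_it <- particles; refs_it <- refs; mask_it <- mask
    }

    tasks <- lapply(seq_len(nrow(table)), function(i) {
      force(i)
      list(id = table$tag[i],
           fun = function() align_particle_task(
             parts_it[[i]], table[i, ], refs_it, grid_params, bp, mask_it, sl))
    })
    pool <- task_pool(tasks, n_workers = config$n_workers,
                      semaphore_mode = config$semaphore_mode)

    for (i in seq_len(nrow(table))) {
      per_ref <- pool$results[[as.character(table$tag[i])]]
      ccs <- vapply(per_ref, `[[`, 0, "cc")
      k <- mra_assign(ccs)
      best <- per_ref[[k]]
      table$cc[i] <- best$cc
      table$ref[i] <- k
      table[i, c("dx", "dy", "dz")] <- as.list(best$shift * f)
      table[i, c("tdrot", "tilt", "narot")] <- as.list(best$euler)
    }

    sel_by_ref <- vector("list", K)
    new_refs <- refs
    for (k in seq_len(K)) {
      rows <- which(table$ref == k)
      if (!length(rows)) {
        warning(sprintf("iteration %d: no particles assigned to reference %d",
                        it, k))
        sel_by_ref[[k]] <- integer(0)
        next
      }
      sel <- rows[select_particles(table[rows, , drop = FALSE], policy)]
      sel_by_ref[[k]] <- sel
      new_refs[[k]] <- average_particles(particles, table, sel)
    }
    refs <- new_refs

    results$tables[[it]] <- table
    results$references[[it]] <- refs
    results$selections[[it]] <- sel_by_ref
    results$audit[[it]] <- pool$audit
    if (!is.null(outdir)) {
      itdir <- file.path(outdir, sprintf("ite_%04d", it))
      dir.create(itdir, showWarnings = FALSE)
      for (k in seq_len(K))
        write_mrc(refs[[k]], file.path(itdir, sprintf("average_ref_%03d.mrc", k)))
      write_table_particles(table, file.path(itdir, "table.tbl"))
      utils::write.table(pool$audit, file.path(itdir, "audit.txt"),
                         row.names = FALSE, quote = FALSE)
    }
  }
  structure(c(results, list(table = table, config = config)),
            class = "project_results")
}

#' @export
print.project_results <- function(x, ...) {
  n_it <- length(x$tables)
  cat(sprintf("Project results: %d iteration(s), %d particle(s), K = %d\n",
              n_it, nrow(x$table), x$config$n_references))
  cat(sprintf("Final cc: mean %.4f, range [%.4f, %.4f]\n",
              mean(x$table$cc), min(x$table$cc), max(x$table$cc)))
  invisible(x)
}
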