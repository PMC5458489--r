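# First-come-first-served task pool.
#
# Tasks are independent closures identified by unique ids. Three
# coordination modes are provided:
#   "none"         - an in-process queue: the master dispatches tasks to
#                    workers (forked with the parallel package) as they
#                    become idle; with one worker this is a plain serial
#                    loop in input order.
#   "atomic_mkdir" - workers claim task i by atomically creating a claim
#                    directory on disk, suitable wherever mkdir is atomic.
#   "lockfile"     - workers claim via hard-link creation (link(2) is atomic
#                    even on NFS), the classic lockfile technique.
# In the file-semaphore modes every worker scans the task list in order and
# executes whatever it can claim, so idle workers immediately pick up the
# next unclaimed task regardless of how long other tasks run. Results are
# always merged by task id in input order, never by completion order, so
# the output is independent of the worker count and of scheduling.

#' Run independent tasks through a first-come-first-served pool
#'
#' @param tasks list of tasks; each task is either a function of no
#'   arguments or a list with elements `id` and `fun` (and optionally
#'   `args`, a list of arguments for `fun`). Unnamed tasks get ids
#'   `1..N`. Duplicate ids are a validation error.
#' @param n_workers number of concurrent workers (>= 1). Multicore modes
#'   use forked processes and fall back to serial execution on platforms
#'   without fork support.
#' @param semaphore_mode one of `"none"`, `"atomic_mkdir"`, `"lockfile"`.
#' @param scratch directory for claim records and results in the
#'   file-semaphore modes (default: a fresh temporary directory).
#' @param reclaim_stale if `TRUE`, tasks whose claim exists but whose result
#'   never appeared (a crashed worker) are re-executed by the master; the
#'   audit marks them as reclaimed.
#' @return list with `results` (named by task id, in input order) and
#'   `audit`, a data frame with one row per executed task: `id`, `worker`,
#'   `t_claim`, `t_done`, `reclaimed`, in dispatch order.
#' @export
task_pool <- function(tasks, n_workers = 1L,
                      semaphore_mode = c("none", "atomic_mkdir", "lockfile"),
                      scratch = NULL, reclaim_stale = TRUE) {
  semaphore_mode <- match.arg(semaphore_mode)
  n_workers <- max(1L, as.integer(n_workers))
  tasks <- normalize_tasks(tasks)
  ids <- vapply(tasks, function(t) t$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate task ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  can_fork <- .Platform$OS.type == "unix"
  if (semaphore_mode == "none") {
    if (n_workers == 1L || !can_fork) return(pool_serial(tasks))
    return(pool_master_queue(tasks, n_workers))
  }
  if (is.null(scratch))
    scratch <- tempfile(paste0("pool_", semaphore_mode, "_"))
  dir.create(scratch, recursive = TRUE, showWarnings = FALSE)
  pool_semaphore(tasks, can_fork, n_workers, semaphore_mode,
                 scratch, reclaim_stale)
}

normalize_tasks <- function(tasks) {
  if (!is.list(tasks) || length(tasks) == 0) stop("empty task list")
  lapply(seq_along(tasks), function(i) {
    t <- tasks[[i]]
    if (is.function(t)) t <- list(fun = t)
    if (is.null(t$fun) || !is.function(t$fun))
      stop(sprintf("task %d has no function", i))
    t$id <- as.character(t$id %||% i)
    t$args <- t$args %||% list()
    t
  })
}

run_task <- function(task) do.call(task$fun, task$args)

audit_row <- function(id, worker, t0, t1, reclaimed = FALSE)
  data.frame(id = id, worker = worker, t_claim = t0, t_done = t1,
             reclaimed = reclaimed, stringsAsFactors = FALSE)

pool_serial <- function(tasks) {
  res <- vector("list", length(tasks))
  aud <- vector("list", length(tasks))
  for (i in seq_along(tasks)) {
    t0 <- as.numeric(Sys.time())
    res[[i]] <- run_task(tasks[[i]])
    aud[[i]] <- audit_row(tasks[[i]]$id, 1L, t0, as.numeric(Sys.time()))
  }
  names(res) <- vapply(tasks, `[[`, "", "id")
  list(results = res, audit = do.call(rbind, aud))
}

# Master-dispatched queue over forked jobs: keeps up to n_workers tasks in
# flight, assigning the next task in input order as soon as a slot frees.
pool_master_queue <- function(tasks, n_workers) {
  n <- length(tasks)
  res <- vector("list", n)
  aud <- list()
  running <- list()   # pid-name -> list(task_index, job, t0, slot)
  next_i <- 1L
  while (next_i <= n || length(running) > 0) {
    while (next_i <= n && length(running) < n_workers) {
      i <- next_i
      job <- parallel::mcparallel(list(value = run_task(tasks[[i]])))
      running[[as.character(job$pid)]] <-
        list(i = i, job = job, t0 = as.numeric(Sys.time()))
      next_i <- next_i + 1L
    }
    got <- parallel::mccollect(lapply(running, `[[`, "job"), wait = FALSE,
                               timeout = 10)
    if (length(got)) {
      for (pid in names(got)) {
        if (is.null(running[[pid]]) || is.null(got[[pid]])) next
        slot <- running[[pid]]
        out <- got[[pid]]
        if (inherits(out, "try-error"))
          stop("task ", tasks[[slot$i]]$id, " failed: ", out)
        res[[slot$i]] <- out$value
        aud[[length(aud) + 1]] <- audit_row(tasks[[slot$i]]$id,
                                            as.integer(pid), slot$t0,
                                            as.numeric(Sys.time()))
        running[[pid]] <- NULL
      }
    }
  }
  names(res) <- vapply(tasks, `[[`, "", "id")
  list(results = res, audit = do.call(rbind, aud))
}

claim_task <- function(mode, scratch, id) {
  claim <- file.path(scratch, paste0("claim_", id))
  if (mode == "atomic_mkdir")
    return(list(ok = suppressWarnings(dir.create(claim)), path = claim))
  # lockfile: creating a hard link is atomic, including on NFS
  lock <- paste0(claim, ".lock")
  tmp <- tempfile("lk", tmpdir = scratch)
  file.create(tmp)
  ok <- suppressWarnings(file.link(tmp, lock))
  unlink(tmp)
  list(ok = isTRUE(ok), path = lock)
}

semaphore_worker <- function(worker, tasks, mode, scratch) {
  claimed <- list()
  for (i in seq_along(tasks)) {
    id <- tasks[[i]]$id
    done <- file.path(scratch, paste0("done_", id))
    if (file.exists(done)) next
    cl <- claim_task(mode, scratch, id)
    if (!cl$ok) next
    t0 <- as.numeric(Sys.time())
    writeLines(sprintf("worker %d pid %d t %.6f", worker, Sys.getpid(), t0),
               file.path(scratch, paste0("info_", id)))
    out <- run_task(tasks[[i]])
    saveRDS(out, file.path(scratch, paste0("result_", id, ".rds")))
    file.create(done)
    claimed[[length(claimed) + 1]] <-
      audit_row(id, worker, t0, as.numeric(Sys.time()))
  }
  if (length(claimed)) do.call(rbind, claimed) else NULL
}

pool_semaphore <- function(tasks, can_fork, n_workers, mode, scratch,
                           reclaim_stale) {
  if (n_workers == 1L || !can_fork) {
    auds <- list(semaphore_worker(1L, tasks, mode, scratch))
  } else {
    jobs <- lapply(seq_len(n_workers), function(w)
      parallel::mcparallel(semaphore_worker(w, tasks, mode, scratch)))
    auds <- parallel::mccollect(jobs)
  }
  aud <- do.call(rbind, Filter(Negate(is.null), auds))
  ids <- vapply(tasks, `[[`, "", "id")
  res <- vector("list", length(tasks))
  names(res) <- ids
  for (i in seq_along(ids)) {
    f <- file.path(scratch, paste0("result_", ids[i], ".rds"))
    if (file.exists(f)) {
      res[[i]] <- readRDS(f)
    } else if (reclaim_stale) {
      # claim without result: worker crashed; re-run in the master
      t0 <- as.numeric(Sys.time())
      res[[i]] <- run_task(tasks[[i]])
      aud <- rbind(aud, audit_row(ids[i], 0L, t0, as.numeric(Sys.time()),
                                  reclaimed = TRUE))
    } else stop("no result for task ", ids[i])
  }
  if (!is.null(aud)) aud <- aud[order(aud$t_claim), , drop = FALSE]
  list(results = res, audit = aud, scratch = scratch)
}
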