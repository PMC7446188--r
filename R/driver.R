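# Serial and coordinator/worker execution.
#
# The coordinator dispatches one interval per idle worker with a COMPUTE
# message; a worker analyses its interval into a temporary per-interval
# table and answers DONE (carrying the temp path), upon which the
# coordinator assigns it the next unprocessed interval.  When no intervals
# remain each worker is sent FINISH.  Temporaries are merged, in plan
# order, into a single file that is byte-identical to the serial run.
#
# The protocol is transport-agnostic: the "fork" backend runs workers as
# forked child processes, the "inprocess" backend executes them in the
# coordinator's process with identical message bookkeeping (and fully
# deterministic traces).

#' Run configuration
#'
#' @param pileup A [pileup_config()].
#' @param caller A [caller_config()].
#' @param scratch Directory for per-interval temporary files.
#' @param workers Worker count (>= 1).
#' @param backend `"inprocess"` or `"fork"` (forked child processes; Unix
#'   only).
#' @return An object of class `run_config`.
#' @export
run_config <- function(pileup = pileup_config(), caller = caller_config(),
                       scratch = tempfile("redikit-scratch-"),
                       workers = 1L,
                       backend = c("inprocess", "fork")) {
  rk_assert(is_count(workers, 1L), "redikit_bad_config",
            "workers must be >= 1")
  structure(list(pileup = pileup, caller = caller, scratch = scratch,
                 workers = as.integer(workers),
                 backend = match.arg(backend)),
            class = "run_config")
}

# analyse one interval: traverse + call + per-interval record frame
process_interval <- function(bam, fasta, interval, config) {
  handle <- open_alignment(bam)
  pu <- traverse(handle, interval, config$pileup, dense = FALSE)
  if (nrow(pu) == 0L) return(empty_sites())
  refwin <- reference_window(fasta, interval)
  call_sites(pu, refwin, config$caller)
}

tmp_name <- function(scratch, interval) {
  file.path(scratch, sprintf("%s_%d_%d.tmp.tsv", interval$chrom,
                             interval$start, interval$end))
}

as_interval_list <- function(intervals) {
  if (inherits(intervals, "interval_plan")) intervals <- intervals$intervals
  if (is.data.frame(intervals)) {
    return(lapply(seq_len(nrow(intervals)), function(i)
      genomic_interval(intervals$chrom[i], intervals$start[i],
                       intervals$end[i],
                       weight = if ("weight" %in% names(intervals))
                         intervals$weight[i] else NA_real_)))
  }
  rk_assert(is.list(intervals) &&
              all(vapply(intervals, inherits, logical(1), "genomic_interval")),
            "redikit_bad_interval", "cannot interpret interval list")
  intervals
}

#' Serial per-interval analysis
#'
#' Traverses each interval in order, calls editing sites, and writes one
#' unified table.  This is the reference semantics every parallel run must
#' reproduce byte for byte.
#'
#' @param bam Path to a sorted, indexed BAM.
#' @param fasta Path to the reference FASTA.
#' @param intervals An `interval_plan`, a data.frame with
#'   `chrom`/`start`/`end`, or a list of [genomic_interval()]; must be
#'   sorted and non-overlapping.
#' @param config A [run_config()].
#' @param out Output file path.
#' @param verbose Emit a per-interval log line via [message()].
#' @return Invisibly, a list with `output` (path) and `n_records`.
#' @export
run_serial <- function(bam, fasta, intervals, config = run_config(),
                       out = "redikit_output.tsv", verbose = FALSE) {
  intervals <- as_interval_list(intervals)
  records <- lapply(intervals, function(iv) {
    recs <- process_interval(bam, fasta, iv, config)
    if (verbose) {
      message(sprintf("interval %s:[%d,%d): %d record(s)",
                      iv$chrom, iv$start, iv$end, nrow(recs)))
    }
    recs
  })
  all <- do.call(rbind, c(records, list(empty_sites())))
  n <- write_site_table(all, out, qcut = config$pileup$min_base_quality)
  invisible(list(output = out, n_records = n))
}

new_trace <- function() new.env(parent = emptyenv())

trace_event <- function(tr, worker, kind, interval = NULL) {
  ev <- list(worker = worker, kind = kind,
             chrom = if (is.null(interval)) NA_character_ else interval$chrom,
             start = if (is.null(interval)) NA_integer_ else interval$start,
             end = if (is.null(interval)) NA_integer_ else interval$end)
  tr$events <- c(tr$events, list(ev))
}

trace_df <- function(tr) {
  evs <- tr$events
  data.frame(worker = vapply(evs, `[[`, integer(1), "worker"),
             kind = vapply(evs, `[[`, character(1), "kind"),
             chrom = vapply(evs, `[[`, character(1), "chrom"),
             start = vapply(evs, `[[`, integer(1), "start"),
             end = vapply(evs, `[[`, integer(1), "end"),
             stringsAsFactors = FALSE)
}

#' Coordinator/worker parallel analysis
#'
#' Dispatches intervals to workers under the COMPUTE/DONE/FINISH protocol,
#' collects per-interval temporaries named `<chrom>_<start>_<end>.tmp.tsv`
#' in the scratch directory, merges them in plan order and removes them on
#' success.  The merged output is byte-identical to [run_serial()] on the
#' same inputs regardless of worker count, plan granularity or completion
#' order.  On a worker failure the run aborts naming the failed interval
#' and leaves the temporaries in place for diagnosis.
#'
#' @inheritParams run_serial
#' @param plan Intervals to process (same forms as in [run_serial()]), in
#'   genomic order.
#' @return Invisibly, a `redikit_run` list with `output`, `n_records` and
#'   the message `trace` (see [schedule_trace()]).
#' @export
run_parallel <- function(bam, fasta, plan, config = run_config(),
                         out = "redikit_output.tsv", verbose = FALSE) {
  intervals <- as_interval_list(plan)
  dir.create(config$scratch, recursive = TRUE, showWarnings = FALSE)
  tr <- new_trace()
  nw <- config$workers

  if (config$backend == "fork" &&
      .Platform$OS.type == "unix" && nw >= 1L) {
    run_workers_fork(bam, fasta, intervals, config, tr, verbose)
  } else {
    run_workers_inprocess(bam, fasta, intervals, config, tr, verbose)
  }

  tmps <- vapply(intervals, function(iv) tmp_name(config$scratch, iv),
                 character(1))
  n <- merge_outputs(tmps, out, remove = TRUE)
  res <- list(output = out, n_records = n, trace = trace_df(tr))
  class(res) <- "redikit_run"
  invisible(res)
}

# deterministic in-process backend: workers are simulated; the oldest busy
# worker always completes first
run_workers_inprocess <- function(bam, fasta, intervals, config, tr,
                                  verbose) {
  nw <- config$workers
  idle <- seq_len(nw)
  busy <- list()        # list of (worker, interval)
  nxt <- 1L
  finish_sent <- logical(nw)
  repeat {
    while (length(idle) && nxt <= length(intervals)) {
      w <- idle[1]; idle <- idle[-1]
      iv <- intervals[[nxt]]; nxt <- nxt + 1L
      trace_event(tr, w, "COMPUTE", iv)
      busy[[length(busy) + 1L]] <- list(worker = w, interval = iv)
    }
    if (nxt > length(intervals)) {
      for (w in idle) {
        if (!finish_sent[w]) { trace_event(tr, w, "FINISH"); finish_sent[w] <- TRUE }
      }
      idle <- integer(0)
    }
    if (!length(busy)) break
    job <- busy[[1]]; busy <- busy[-1]
    worker_body(bam, fasta, job$interval, config, verbose)
    trace_event(tr, job$worker, "DONE", job$interval)
    idle <- c(idle, job$worker)
  }
  invisible(NULL)
}

worker_body <- function(bam, fasta, interval, config, verbose = FALSE) {
  recs <- process_interval(bam, fasta, interval, config)
  tmp <- tmp_name(config$scratch, interval)
  write_site_table(recs, tmp, qcut = config$pileup$min_base_quality)
  if (verbose) {
    message(sprintf("interval %s:[%d,%d): %d record(s) -> %s",
                    interval$chrom, interval$start, interval$end,
                    nrow(recs), tmp))
  }
  tmp
}

# forked-process backend: one child per busy worker, polled for completion
run_workers_fork <- function(bam, fasta, intervals, config, tr, verbose) {
  nw <- config$workers
  jobs <- vector("list", nw)        # per-worker mcparallel job or NULL
  ivs <- vector("list", nw)
  nxt <- 1L
  launch <- function(w) {
    iv <- intervals[[nxt]]
    trace_event(tr, w, "COMPUTE", iv)
    ivs[[w]] <<- iv
    jobs[[w]] <<- parallel::mcparallel(
      worker_body(bam, fasta, iv, config, verbose = FALSE))
    nxt <<- nxt + 1L
  }
  for (w in seq_len(nw)) {
    if (nxt > length(intervals)) break
    launch(w)
  }
  for (w in seq_len(nw)) {
    if (is.null(jobs[[w]])) trace_event(tr, w, "FINISH")
  }
  while (any(!vapply(jobs, is.null, logical(1)))) {
    active <- which(!vapply(jobs, is.null, logical(1)))
    res <- parallel::mccollect(jobs[active], wait = FALSE)
    if (is.null(res) || all(vapply(res, is.null, logical(1)))) {
      Sys.sleep(0.01)
      next
    }
    done_pids <- as.integer(names(res))
    for (w in active) {
      if (!jobs[[w]]$pid %in% done_pids) next
      val <- res[[as.character(jobs[[w]]$pid)]]
      if (is.null(val)) next                      # not actually finished
      iv <- ivs[[w]]
      if (inherits(val, "try-error") || inherits(val, "error")) {
        rk_stop("redikit_worker_failed",
                "worker %d failed on interval %s:[%d,%d): %s",
                w, iv$chrom, iv$start, iv$end,
                conditionMessage(attr(val, "condition")))
      }
      trace_event(tr, w, "DONE", iv)
      jobs[w] <- list(NULL)
      if (nxt <= length(intervals)) {
        launch(w)
      } else {
        trace_event(tr, w, "FINISH")
      }
    }
  }
  invisible(NULL)
}

#' Message trace of a parallel run
#'
#' @param run The result of [run_parallel()].
#' @return A data.frame of ordered protocol events with columns `worker`,
#'   `kind` (`COMPUTE`/`DONE`/`FINISH`), `chrom`, `start`, `end`.  Every
#'   interval appears in exactly one COMPUTE and one DONE; every worker
#'   receives exactly one FINISH.
#' @export
schedule_trace <- function(run) {
  rk_assert(inherits(run, "redikit_run"), "redikit_bad_run",
            "not a redikit_run object")
  run$trace
}
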