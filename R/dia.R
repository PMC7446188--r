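# Dynamic Interval Analysis: cost-balanced genome partitioning.
#
# Per-position processing cost is modelled as t(i) = alpha + b * cov(i)^d
# (cubic in coverage by default).  The total genome cost GC is the sum of
# t(i) over all positions; AC = GC/n is the ideal per-interval cost for n
# workers.  A greedy scan in genome order closes an interval when its
# accumulated weight reaches AC (max-weight), when adding the next bin
# would exceed the width threshold (max-width), or at a chromosome end
# (single-chromosome-span) -- an interval never spans two chromosomes.

#' Per-position processing-time model
#'
#' @param alpha Constant floor cost per position (>= 0).  A positive floor
#'   gives empty regions nonzero cost, so sparse genomes still tile.
#' @param b Coefficient of the coverage term (> 0).
#' @param d Exponent of the coverage term (> 0); 3 by default, reflecting
#'   the empirically cubic growth of per-interval processing time with mean
#'   coverage.
#' @return An object of class `time_model`.
#' @export
time_model <- function(alpha = 1, b = 1, d = 3) {
  rk_assert(is.numeric(alpha) && alpha >= 0, "redikit_bad_model",
            "alpha must be >= 0")
  rk_assert(is.numeric(b) && b > 0, "redikit_bad_model", "b must be > 0")
  rk_assert(is.numeric(d) && d > 0, "redikit_bad_model", "d must be > 0")
  structure(list(alpha = alpha, b = b, d = d), class = "time_model")
}

#' Estimated processing cost of one position
#'
#' @param cov Coverage value(s), >= 0; vectorised.
#' @param model A [time_model()].
#' @return `alpha + b * cov^d`.
#' @export
position_cost <- function(cov, model = time_model()) {
  rk_assert(all(cov >= 0), "redikit_bad_coverage", "coverage must be >= 0")
  model$alpha + model$b * cov^model$d
}

#' Binned coverage track
#'
#' Container for per-bin mean depth across the genome.  [coverage_track()]
#' computes one from a BAM; this constructor builds one from explicit
#' values (synthetic tracks for partition experiments).
#'
#' @param values Named list, one numeric vector of per-bin mean coverages
#'   per chromosome, in genome order.
#' @param bin_size Positions per bin (>= 1).
#' @param chrom_lengths Named integer vector of chromosome lengths; each
#'   vector in `values` must have `ceiling(length / bin_size)` bins.
#'   Defaults to `lengths(values) * bin_size` (all bins full).
#' @return An object of class `coverage_track`.
#' @export
new_coverage_track <- function(values, bin_size,
                               chrom_lengths = lengths(values) * bin_size) {
  rk_assert(is_count(bin_size, 1L), "redikit_bad_track", "bin_size must be >= 1")
  rk_assert(is.list(values) && !is.null(names(values)) &&
              identical(names(values), names(chrom_lengths)),
            "redikit_bad_track", "values and chrom_lengths must share names")
  for (ch in names(values)) {
    rk_assert(length(values[[ch]]) == ceiling(chrom_lengths[[ch]] / bin_size),
              "redikit_bad_track",
              "chromosome %s: %d bins, expected ceiling(%d / %d)",
              ch, length(values[[ch]]), chrom_lengths[[ch]], bin_size)
    rk_assert(all(values[[ch]] >= 0), "redikit_bad_track",
              "negative coverage on %s", ch)
  }
  structure(list(bin_size = as.integer(bin_size),
                 chrom_lengths = setNames(as.integer(chrom_lengths),
                                          names(chrom_lengths)),
                 values = values),
            class = "coverage_track")
}

# widths of the bins of one chromosome (last bin may be short)
bin_widths <- function(track, chrom) {
  L <- track$chrom_lengths[[chrom]]
  nb <- length(track$values[[chrom]])
  w <- rep(track$bin_size, nb)
  w[nb] <- L - (nb - 1L) * track$bin_size
  w
}

#' Compute a coverage track from a BAM file
#'
#' Per-bin mean depth of passing reads' reference spans, computed per
#' chromosome with a start/end difference array in a single pass over the
#' reads.
#'
#' @param handle An [open_alignment()] handle.
#' @param bin_size Positions per bin (default 1000).
#' @param filters A [read_filters()] object.
#' @return A `coverage_track`.
#' @export
coverage_track <- function(handle, bin_size = 1000L,
                           filters = read_filters()) {
  rk_assert(is_count(bin_size, 1L), "redikit_bad_track", "bin_size must be >= 1")
  values <- list()
  for (ch in names(handle$chroms)) {
    L <- handle$chroms[[ch]]
    batch <- fetch_batch(handle, genomic_interval(ch, 0L, L))
    pass <- which(batch_passes(batch$flag, batch$mapq, filters))
    cov <- numeric(L)
    if (length(pass)) {
      spans <- batch_ref_spans(batch, pass)
      s <- pmax(spans$start, 0L)
      e <- pmin(spans$end, L)
      ok <- e > s
      diffs <- tabulate(s[ok] + 1L, nbins = L) - tabulate(e[ok] + 1L, nbins = L)
      cov <- cumsum(diffs)
    }
    binidx <- (seq_len(L) - 1L) %/% bin_size
    sums <- rowsum(cov, binidx)
    values[[ch]] <- as.numeric(sums[, 1] / tabulate(binidx + 1L))
  }
  new_coverage_track(values, bin_size,
                     chrom_lengths = setNames(as.integer(handle$chroms),
                                              names(handle$chroms)))
}

#' Estimated processing cost of the whole genome (GC)
#'
#' Sum over all bins of bin width times the per-position cost at the bin's
#' mean coverage; additive over chromosomes.
#'
#' @param track A `coverage_track`.
#' @param model A [time_model()].
#' @return Numeric scalar GC.
#' @export
total_cost <- function(track, model = time_model()) {
  sum(vapply(names(track$values), function(ch) {
    sum(bin_widths(track, ch) * position_cost(track$values[[ch]], model))
  }, numeric(1)))
}

new_interval_plan <- function(intervals, n_target, total_cost, ideal_cost,
                              max_width, chrom_lengths) {
  # plan invariants: sorted disjoint tiling of every chromosome, no
  # cross-chromosome interval, widths bounded
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    rk_assert(iv$start[1] == 0L &&
                all(iv$start[-1] == iv$end[-nrow(iv)]) &&
                iv$end[nrow(iv)] == chrom_lengths[[ch]],
              "redikit_bad_plan", "intervals do not tile chromosome %s", ch)
  }
  if (is.finite(max_width)) {
    rk_assert(all(intervals$end - intervals$start <= max_width),
              "redikit_bad_plan", "interval exceeds max_width")
  }
  structure(list(intervals = intervals, n_target = as.integer(n_target),
                 total_cost = total_cost, ideal_cost = ideal_cost,
                 max_width = max_width, chrom_lengths = chrom_lengths),
            class = "interval_plan")
}

#' @export
print.interval_plan <- function(x, ...) {
  w <- x$intervals$weight
  cat(sprintf(
    "<interval_plan> %d intervals (n_target %d), GC=%.4g AC=%.4g\n",
    nrow(x$intervals), x$n_target, x$total_cost, x$ideal_cost))
  cat(sprintf("  weights: min %.4g / mean %.4g / max %.4g\n",
              min(w), mean(w), max(w)))
  invisible(x)
}

#' Dynamic Interval Analysis partition
#'
#' Greedy construction of the interval set D: scan bins in genome order,
#' accumulating the estimated cost; close the current interval immediately
#' after the bin whose addition makes the weight reach AC = GC/n
#' (max-weight; the crossing bin is included), before a bin whose addition
#' would exceed `max_width` (max-width), and at every chromosome end
#' (single-chromosome-span).  The number of intervals produced need not
#' equal `n`.
#'
#' @param track A `coverage_track`.
#' @param n Requested number of processes (>= 1).
#' @param max_width Maximum interval width in positions, or `Inf`.  Default
#'   `2 * ceiling(genome length / n)`, bounding how much a sparse-region
#'   interval can stretch so that workers are recycled.
#' @param model A [time_model()].
#' @return An `interval_plan` whose `$intervals` data.frame has columns
#'   `chrom`, `start`, `end`, `weight`.
#' @export
dynamic_intervals <- function(track, n, max_width = NULL,
                              model = time_model()) {
  rk_assert(is_count(n, 1L), "redikit_bad_n", "n must be >= 1")
  genome_len <- sum(as.numeric(track$chrom_lengths))
  if (is.null(max_width)) max_width <- 2 * ceiling(genome_len / n)
  rk_assert(max_width >= track$bin_size, "redikit_bad_plan",
            "max_width (%s) must be at least one bin (%d)",
            format(max_width), track$bin_size)
  GC <- total_cost(track, model)
  AC <- GC / n

  rows <- list()
  for (ch in names(track$values)) {
    costs <- position_cost(track$values[[ch]], model)
    widths <- bin_widths(track, ch)
    weights <- widths * costs
    offs <- c(0L, cumsum(widths))      # bin boundaries in positions
    cur_start <- 0L
    cur_w <- 0
    nb <- length(weights)
    for (b in seq_len(nb)) {
      if (offs[b + 1L] - cur_start > max_width) {
        # max-width: close before the violating bin
        rows[[length(rows) + 1L]] <- list(ch, cur_start, offs[b], cur_w)
        cur_start <- offs[b]
        cur_w <- 0
      }
      cur_w <- cur_w + weights[b]
      if (cur_w >= AC && b < nb) {
        # max-weight: close after the crossing bin
        rows[[length(rows) + 1L]] <- list(ch, cur_start, offs[b + 1L], cur_w)
        cur_start <- offs[b + 1L]
        cur_w <- 0
      }
    }
    if (cur_start < offs[nb + 1L]) {
      # single-chromosome-span
      rows[[length(rows) + 1L]] <- list(ch, cur_start, offs[nb + 1L], cur_w)
    }
  }
  intervals <- data.frame(
    chrom = vapply(rows, `[[`, character(1), 1L),
    start = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
    end = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    weight = vapply(rows, `[[`, numeric(1), 4L),
    stringsAsFactors = FALSE)
  new_interval_plan(intervals, n, GC, AC, max_width, track$chrom_lengths)
}

#' Naive equal-width partition
#'
#' Splits the genome into intervals of width `ceiling(genome length / n)`,
#' tiling each chromosome independently (the last interval of a chromosome
#' may be short).  This is the baseline the balanced partitioner is
#' compared against.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param n Requested number of processes (>= 1).
#' @param track,model Optional; when given, interval weights are evaluated
#'   with [plan_weights()] so that balance can be compared.
#' @return An `interval_plan`.
#' @export
naive_intervals <- function(chrom_lengths, n, track = NULL,
                            model = time_model()) {
  rk_assert(is_count(n, 1L), "redikit_bad_n", "n must be >= 1")
  genome_len <- sum(as.numeric(chrom_lengths))
  width <- as.integer(ceiling(genome_len / n))
  rows <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    starts <- seq.int(0L, L - 1L, by = width)
    for (s in starts) {
      rows[[length(rows) + 1L]] <- list(ch, s, min(s + width, L))
    }
  }
  intervals <- data.frame(
    chrom = vapply(rows, `[[`, character(1), 1L),
    start = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
    end = vapply(rows, function(r) as.integer(r[[3]]), integer(1)),
    weight = NA_real_, stringsAsFactors = FALSE)
  GC <- if (!is.null(track)) total_cost(track, model) else NA_real_
  if (!is.null(track)) {
    intervals$weight <- plan_weights(intervals, track, model)
  }
  new_interval_plan(intervals, n, GC, if (!is.null(track)) GC / n else
    NA_real_, Inf, setNames(as.integer(chrom_lengths), names(chrom_lengths)))
}

#' Evaluate interval weights under a coverage track
#'
#' Estimated cost of each interval: positions of overlap with each bin times
#' the per-position cost at that bin's mean coverage.
#'
#' @param intervals A data.frame with `chrom`, `start`, `end`.
#' @param track A `coverage_track`.
#' @param model A [time_model()].
#' @return Numeric vector of weights.
#' @export
plan_weights <- function(intervals, track, model = time_model()) {
  vapply(seq_len(nrow(intervals)), function(i) {
    ch <- intervals$chrom[i]
    costs <- position_cost(track$values[[ch]], model)
    widths <- bin_widths(track, ch)
    offs <- c(0L, cumsum(widths))
    ov <- pmax(0L, pmin(offs[-1L], intervals$end[i]) -
                 pmax(offs[-length(offs)], intervals$start[i]))
    sum(ov * costs)
  }, numeric(1))
}

#' Fit the time model from (coverage, time) observations
#'
#' Least-squares fit of `log(time) = log(b) + d * log(cov)` over
#' observations with positive coverage and time; the floor `alpha` is the
#' mean time of zero-coverage observations when present, otherwise
#' `default_alpha`.
#'
#' @param observations A data.frame (or list) with numeric `cov` and `time`.
#' @param default_alpha Floor used when no zero-coverage observations exist.
#' @return A [time_model()] with fitted `b` and `d`.
#' @export
fit_time_model <- function(observations, default_alpha = 1) {
  cov <- observations$cov
  tim <- observations$time
  rk_assert(length(cov) == length(tim) && length(cov) >= 2L,
            "redikit_bad_fit", "need at least 2 observations")
  pos <- cov > 0 & tim > 0
  rk_assert(length(unique(cov[pos])) >= 2L, "redikit_degenerate_fit",
            "need at least 2 distinct positive coverage values")
  fit <- lm(log(tim[pos]) ~ log(cov[pos]))
  alpha <- if (any(cov == 0)) mean(tim[cov == 0]) else default_alpha
  time_model(alpha = alpha, b = exp(unname(coef(fit)[1])),
             d = unname(coef(fit)[2]))
}

#' Export an interval plan as BED
#'
#' BED5: chrom, start, end, an `iv<k>` name, and the interval weight in the
#' score column.  [read_bed_intervals()] (or [read_plan_bed()]) reads it
#' back, so user-supplied plans can drive the parallel runner.
#'
#' @param plan An `interval_plan`.
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_plan_bed <- function(plan, path) {
  iv <- plan$intervals
  writeLines(sprintf("%s\t%d\t%d\tiv%d\t%.6g", iv$chrom, iv$start, iv$end,
                     seq_len(nrow(iv)), iv$weight), path)
  invisible(path)
}

#' Read an interval plan from BED
#'
#' @param path BED file (3+ columns; numeric 5th column used as weight).
#' @param chrom_lengths Named integer vector of chromosome lengths the plan
#'   must tile.
#' @return An `interval_plan` (with `n_target` set to the interval count).
#' @export
read_plan_bed <- function(path, chrom_lengths) {
  ivs <- read_bed_intervals(path)
  intervals <- data.frame(
    chrom = vapply(ivs, `[[`, character(1), "chrom"),
    start = vapply(ivs, `[[`, integer(1), "start"),
    end = vapply(ivs, `[[`, integer(1), "end"),
    weight = vapply(ivs, `[[`, numeric(1), "weight"),
    stringsAsFactors = FALSE)
  new_interval_plan(intervals, nrow(intervals), NA_real_, NA_real_, Inf,
                    setNames(as.integer(chrom_lengths), names(chrom_lengths)))
}
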