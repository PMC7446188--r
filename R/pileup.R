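# Single-load pileup traversal.
#
# The classical per-position mpileup strategy re-loads every read once per
# covered position (l disk accesses for a read of length l).  Here each
# interval triggers exactly one indexed fetch: every overlapping record is
# retrieved from storage once, expanded along its CIGAR once, and
# conceptually held in an active-read buffer that drops a read as soon as
# its reference span falls behind the sweep position.  The buffer occupancy
# at position p is therefore the number of passing reads whose span covers
# p, and its peak is reported by peak_active_reads().

#' Pileup configuration
#'
#' @param min_base_quality Minimum Phred score for a base to be counted
#'   (default 25; the output coverage column is named `Coverage-q<Q>` after
#'   this threshold).
#' @param read_filters A [read_filters()] object.
#' @param count_soft_clipped Reserved; soft-clipped bases are never counted
#'   and only `FALSE` is supported.
#' @return An object of class `pileup_config`.
#' @export
pileup_config <- function(min_base_quality = 25L,
                          read_filters = redikit::read_filters(),
                          count_soft_clipped = FALSE) {
  rk_assert(is_count(min_base_quality), "redikit_bad_config",
            "min_base_quality must be >= 0")
  rk_assert(isFALSE(count_soft_clipped), "redikit_bad_config",
            "count_soft_clipped = TRUE is not supported")
  structure(list(min_base_quality = as.integer(min_base_quality),
                 read_filters = read_filters,
                 count_soft_clipped = count_soft_clipped),
            class = "pileup_config")
}

#' Traverse an interval and tally per-position base counts
#'
#' Emits one row per position in `[start, end)` in increasing order, tallying
#' A/C/G/T counts, the summed Phred quality of counted bases, and
#' forward/reverse read-orientation counts.  Reads starting before `start`
#' contribute at the positions they cover inside the interval.  Only bases
#' with quality `>= min_base_quality` and base in A,C,G,T from reads passing
#' the read filters are counted; deletions and N skips contribute nothing.
#'
#' Each read record is retrieved from storage exactly once per traversal;
#' instrumentation recording per-read load counts and the peak size of the
#' active-read buffer is attached to the result (see [traverse_stats()] and
#' [peak_active_reads()]).
#'
#' @param handle An [open_alignment()] handle.
#' @param interval A [genomic_interval()].
#' @param config A [pileup_config()].
#' @param dense If `FALSE` (default, "sparse" mode) positions with zero
#'   passing coverage are omitted; if `TRUE` every position is emitted.
#' @return A data.frame of class `redikit_pileup` with columns `chrom`,
#'   `pos` (0-based), `A`, `C`, `G`, `T`, `qual_sum`, `fwd`, `rev`.
#' @export
traverse <- function(handle, interval, config = pileup_config(),
                     dense = FALSE) {
  batch <- fetch_batch(handle, interval)
  pass <- which(batch_passes(batch$flag, batch$mapq, config$read_filters))
  width <- interval_width(interval)

  # one load per retrieved record; loads are counted per query name so the
  # single-load contract can be audited read by read
  load_counts <- table(batch$qname)

  ex <- expand_batch(batch, rows = pass)
  keep <- ex$gpos >= interval$start & ex$gpos < interval$end &
    ex$code > 0L & ex$qual >= config$min_base_quality
  rel  <- ex$gpos[keep] - interval$start          # 0-based offset in interval
  code <- ex$code[keep]
  qual <- ex$qual[keep]
  rev  <- bitwAnd(batch$flag[ex$row[keep]], FLAG_BITS[["reverse"]]) > 0L

  counts <- matrix(tabulate(rel * 4L + code, nbins = width * 4L),
                   ncol = 4L, byrow = TRUE,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  qs <- numeric(width)
  if (length(rel)) {
    agg <- rowsum(as.numeric(qual), rel)
    qs[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  }
  fwd <- tabulate(rel[!rev] + 1L, nbins = width)
  rvs <- tabulate(rel[rev] + 1L, nbins = width)

  # active-read buffer occupancy: passing reads stabbed by each position
  peak <- 0L
  if (length(pass)) {
    spans <- batch_ref_spans(batch, pass)
    s <- pmax(spans$start, interval$start) - interval$start
    e <- pmin(spans$end, interval$end) - interval$start
    ok <- e > s
    if (any(ok)) {
      ds <- tabulate(s[ok] + 1L, nbins = width + 1L)
      de <- tabulate(e[ok] + 1L, nbins = width + 1L)
      peak <- max(cumsum(ds - de)[seq_len(width)])
    }
  }

  df <- data.frame(chrom = rep(interval$chrom, width),
                   pos = interval$start + seq_len(width) - 1L,
                   A = counts[, 1], C = counts[, 2],
                   G = counts[, 3], T = counts[, 4],
                   qual_sum = qs, fwd = fwd, rev = rvs,
                   stringsAsFactors = FALSE)
  if (!dense) df <- df[df$A + df$C + df$G + df$T > 0L, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            class = c("redikit_pileup", "data.frame"),
            stats = list(interval = interval,
                         n_records_fetched = batch$n,
                         n_passing = length(pass),
                         load_counts = load_counts,
                         peak_active_reads = peak))
}

# reference spans (0-based half-open) of selected batch rows, CIGAR-derived
batch_ref_spans <- function(batch, rows = seq_len(batch$n)) {
  if (!length(rows)) return(list(start = integer(0), end = integer(0)))
  toks <- regmatches(batch$cigar[rows],
                     gregexpr("[0-9]+[MIDNSHP=X]", batch$cigar[rows]))
  rlen <- vapply(toks, function(tk) {
    op <- substring(tk, nchar(tk), nchar(tk))
    sum(as.integer(substring(tk, 1L, nchar(tk) - 1L))[op %in% CIGAR_REF])
  }, integer(1))
  list(start = batch$start[rows], end = batch$start[rows] + rlen)
}

#' Traversal instrumentation
#'
#' @param pileup The result of [traverse()].
#' @return A list with `n_records_fetched`, `n_passing`, `load_counts`
#'   (loads per query name; all 1 under the single-load contract) and
#'   `peak_active_reads`.
#' @export
traverse_stats <- function(pileup) {
  s <- attr(pileup, "stats")
  rk_assert(!is.null(s), "redikit_no_stats",
            "object carries no traversal instrumentation")
  s
}

#' Peak size of the active-read buffer
#'
#' Maximum number of reads simultaneously held during a traversal, i.e. the
#' maximum over interval positions of the number of passing reads whose
#' reference span covers the position.
#'
#' @param pileup The result of [traverse()].
#' @return Integer.
#' @export
peak_active_reads <- function(pileup) {
  traverse_stats(pileup)$peak_active_reads
}
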