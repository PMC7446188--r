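# Independent oracles.  These deliberately use the naive strategy the
# engine replaces: every position re-scans the read list (one "load" per
# read per covered position) and resolves its base with the scalar CIGAR
# walk base_at().  They share no code path with the vectorised engine.

# Brute-force fetch: all reads whose reference span intersects [start,end),
# kept in input order.
oracle_fetch <- function(reads, interval) {
  keep <- vapply(reads, function(r) {
    r$chrom == interval$chrom && r$start < interval$end &&
      read_end(r) > interval$start
  }, logical(1))
  reads[keep]
}

# Naive per-position recount.  Returns list(pileup = dense data.frame,
# loads = named integer vector of per-read load counts).
oracle_pileup <- function(reads, interval, config = pileup_config()) {
  pass <- Filter(function(r) read_passes_filters(r, config$read_filters),
                 reads)
  starts <- vapply(pass, `[[`, integer(1), "start")
  ends <- vapply(pass, read_end, integer(1))
  chroms <- vapply(pass, `[[`, character(1), "chrom")
  loads <- setNames(integer(length(pass)),
                    vapply(pass, `[[`, character(1), "qname"))
  width <- interval$end - interval$start
  out <- data.frame(chrom = rep(interval$chrom, width),
                    pos = interval$start + seq_len(width) - 1L,
                    A = 0L, C = 0L, G = 0L, T = 0L, qual_sum = 0,
                    fwd = 0L, rev = 0L, stringsAsFactors = FALSE)
  for (k in seq_len(width)) {
    gpos <- interval$start + k - 1L
    hit <- which(chroms == interval$chrom & starts <= gpos & ends > gpos)
    loads[hit] <- loads[hit] + 1L   # a naive traversal re-loads each one
    for (i in hit) {
      bq <- base_at(pass[[i]], gpos)
      if (is.null(bq)) next                       # deletion / N skip
      if (!bq$base %in% c("A", "C", "G", "T")) next
      if (bq$qual < config$min_base_quality) next
      out[k, bq$base] <- out[k, bq$base] + 1L
      out$qual_sum[k] <- out$qual_sum[k] + bq$qual
      if (pass[[i]]$is_reverse) out$rev[k] <- out$rev[k] + 1L
      else out$fwd[k] <- out$fwd[k] + 1L
    }
  }
  list(pileup = out, loads = loads)
}

# interval-stabbing oracle: max over positions of passing-read span overlap
oracle_peak <- function(reads, interval, config = pileup_config()) {
  pass <- Filter(function(r) read_passes_filters(r, config$read_filters),
                 reads)
  if (!length(pass)) return(0L)
  starts <- vapply(pass, `[[`, integer(1), "start")
  ends <- vapply(pass, read_end, integer(1))
  chroms <- vapply(pass, `[[`, character(1), "chrom")
  best <- 0L
  for (gpos in seq.int(interval$start, interval$end - 1L)) {
    best <- max(best, sum(chroms == interval$chrom & starts <= gpos &
                            ends > gpos))
  }
  best
}

strip_stats <- function(pu) {
  df <- as.data.frame(pu)
  attr(df, "stats") <- NULL
  rownames(df) <- NULL
  df
}
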