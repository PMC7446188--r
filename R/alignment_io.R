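# Alignment and reference I/O: BAM handles, interval-addressable read
# fetches, read filters, reference windows.  Coordinates are 0-based
# half-open everywhere inside the package; only the output table and the
# CLI region dialect are 1-based.

FLAG_BITS <- c(unmapped = 4L, reverse = 16L, secondary = 256L,
               qcfail = 512L, duplicate = 1024L, supplementary = 2048L)

#' Genomic interval (0-based, half-open)
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param weight Optional non-negative cost estimate attached by the
#'   partitioner.
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr1", 0, 100)
#' @export
genomic_interval <- function(chrom, start, end, weight = NA_real_) {
  rk_assert(is.character(chrom) && length(chrom) == 1L && nzchar(chrom),
            "redikit_bad_interval", "chrom must be a single non-empty string")
  rk_assert(is_count(start) && is_count(end),
            "redikit_bad_interval", "start/end must be non-negative integers")
  rk_assert(start < end, "redikit_bad_interval",
            "empty or inverted interval: %s:[%d,%d)", chrom, start, end)
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), weight = weight),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:[%d,%d) width=%d%s\n", x$chrom, x$start, x$end,
              x$end - x$start,
              if (is.na(x$weight)) "" else sprintf(" weight=%.4g", x$weight)))
  invisible(x)
}

interval_width <- function(interval) interval$end - interval$start

#' Read-level filters
#'
#' Defaults mirror q25-style gating: mapping quality at least 25 and
#' exclusion of unmapped, secondary, supplementary, duplicate and QC-fail
#' records.  Unmapped reads never pass, whether or not listed.
#'
#' @param min_mapq Minimum mapping quality (>= 0).
#' @param exclude Character vector of flag names to drop, a subset of
#'   `c("unmapped","secondary","supplementary","duplicate","qcfail")`.
#' @return An object of class `read_filters`.
#' @export
read_filters <- function(min_mapq = 25L,
                         exclude = c("unmapped", "secondary", "supplementary",
                                     "duplicate", "qcfail")) {
  rk_assert(is_count(min_mapq), "redikit_bad_filters", "min_mapq must be >= 0")
  exclude <- as.character(exclude)
  bad <- setdiff(exclude, setdiff(names(FLAG_BITS), "reverse"))
  rk_assert(length(bad) == 0L, "redikit_bad_filters",
            "unknown flag name(s): %s", paste(bad, collapse = ", "))
  structure(list(min_mapq = as.integer(min_mapq), exclude = exclude),
            class = "read_filters")
}

#' Single alignment record
#'
#' A lightweight record used by the CIGAR-walking operations and the test
#' oracles.  The pileup engine itself works on the columnar batches returned
#' by the fetch layer.
#'
#' @param qname Query name.
#' @param chrom Reference sequence name.
#' @param start 0-based leftmost reference position.
#' @param cigar CIGAR string, e.g. `"3M2I5M"`.
#' @param seq Base string over A,C,G,T,N.
#' @param qual Integer Phred scores, one per `seq` base.
#' @param mapq Mapping quality.
#' @param flag SAM flag integer (encodes strand and the filterable states).
#' @return An object of class `aligned_read`.
#' @export
aligned_read <- function(qname, chrom, start, cigar, seq, qual,
                         mapq = 60L, flag = 0L) {
  ops <- parse_cigar(cigar)
  qlen <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  rk_assert(qlen == nchar(seq), "redikit_bad_read",
            "CIGAR query length %d != seq length %d (%s)",
            qlen, nchar(seq), qname)
  rk_assert(length(qual) == nchar(seq), "redikit_bad_read",
            "qual length != seq length (%s)", qname)
  flag <- as.integer(flag)
  structure(list(
    qname = qname, chrom = chrom, start = as.integer(start),
    cigar = cigar, ops = ops, seq = seq, qual = as.integer(qual),
    mapq = as.integer(mapq), flag = flag,
    is_reverse       = bitwAnd(flag, FLAG_BITS[["reverse"]]) > 0L,
    is_unmapped      = bitwAnd(flag, FLAG_BITS[["unmapped"]]) > 0L,
    is_secondary     = bitwAnd(flag, FLAG_BITS[["secondary"]]) > 0L,
    is_supplementary = bitwAnd(flag, FLAG_BITS[["supplementary"]]) > 0L,
    is_duplicate     = bitwAnd(flag, FLAG_BITS[["duplicate"]]) > 0L,
    is_qcfail        = bitwAnd(flag, FLAG_BITS[["qcfail"]]) > 0L),
    class = "aligned_read")
}

#' Reference span of a read
#'
#' End coordinate (0-based, exclusive) of the alignment on the reference:
#' start plus the summed lengths of reference-consuming CIGAR operations.
#'
#' @param read An [aligned_read()].
#' @return Integer end coordinate.
#' @export
read_end <- function(read) {
  read$start + sum(read$ops$len[read$ops$op %in% c("M", "D", "N", "=", "X")])
}

#' Does a read pass the filters?
#'
#' False iff the read is unmapped, carries any excluded flag, or has mapping
#' quality below the threshold.
#'
#' @param read An [aligned_read()].
#' @param filters A [read_filters()] object.
#' @return Logical scalar.
#' @export
read_passes_filters <- function(read, filters = read_filters()) {
  if (read$is_unmapped) return(FALSE)
  if (read$mapq < filters$min_mapq) return(FALSE)
  for (f in filters$exclude) {
    if (isTRUE(read[[paste0("is_", f)]])) return(FALSE)
  }
  TRUE
}

# Vectorised flag/mapq filter over a columnar batch.
batch_passes <- function(flag, mapq, filters) {
  drop_bits <- FLAG_BITS[["unmapped"]]
  for (f in filters$exclude) drop_bits <- bitwOr(drop_bits, FLAG_BITS[[f]])
  bitwAnd(flag, drop_bits) == 0L & mapq >= filters$min_mapq
}

#' Open a coordinate-sorted, indexed BAM file
#'
#' @param path Path to a BAM file; a companion `.bai` index must exist.
#' @return An `alignment_handle` exposing `$chroms` (named integer vector of
#'   chromosome lengths, in header order) and `$path`.
#' @section Errors: `redikit_missing_file`, `redikit_missing_index`,
#'   `redikit_unsorted`, `redikit_io_error` are signalled as distinct
#'   condition classes.
#' @export
open_alignment <- function(path) {
  rk_assert(file.exists(path), "redikit_missing_file",
            "BAM file not found: %s", path)
  idx <- c(paste0(path, ".bai"), sub("\\.bam$", ".bai", path))
  rk_assert(any(file.exists(idx)), "redikit_missing_index",
            "index required: no .bai found for %s", path)
  hdr <- tryCatch(Rsamtools::scanBamHeader(path)[[1]],
                  error = function(e)
                    rk_stop("redikit_io_error",
                            "cannot read BAM header of %s: %s",
                            path, conditionMessage(e)))
  so <- "unknown"
  if ("@HD" %in% names(hdr$text)) {
    hd <- hdr$text[["@HD"]]
    soi <- grep("^SO:", hd, value = TRUE)
    if (length(soi)) so <- sub("^SO:", "", soi[1])
  }
  rk_assert(identical(so, "coordinate"), "redikit_unsorted",
            "BAM is not coordinate-sorted (SO:%s): %s", so, path)
  structure(list(path = path, chroms = hdr$targets),
            class = "alignment_handle")
}

#' @export
print.alignment_handle <- function(x, ...) {
  cat(sprintf("<alignment_handle> %s (%d chromosomes, %s bp)\n", x$path,
              length(x$chroms), format(sum(as.numeric(x$chroms)),
                                       big.mark = ",")))
  invisible(x)
}

check_chrom <- function(handle, chrom) {
  rk_assert(chrom %in% names(handle$chroms), "redikit_unknown_chrom",
            "chromosome '%s' not in BAM header", chrom)
}

# Columnar fetch used by the engine.  One scanBam call per interval: this IS
# the single disk access per read.  Returns reads whose reference span
# intersects [start,end), in file (coordinate) order.
fetch_batch <- function(handle, interval) {
  check_chrom(handle, interval$chrom)
  which <- GenomicRanges::GRanges(interval$chrom,
                                  IRanges::IRanges(interval$start + 1L,
                                                   interval$end))
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    which = which)
  b <- Rsamtools::scanBam(handle$path, param = param)[[1]]
  n <- length(b$qname)
  list(n = n,
       qname = b$qname,
       flag  = as.integer(b$flag),
       chrom = as.character(b$rname),
       start = as.integer(b$pos) - 1L,   # to 0-based
       mapq  = as.integer(b$mapq),
       cigar = as.character(b$cigar),
       seq   = as.character(b$seq),
       qual  = as.character(b$qual))
}

batch_read <- function(batch, i) {
  aligned_read(qname = batch$qname[i], chrom = batch$chrom[i],
               start = batch$start[i], cigar = batch$cigar[i],
               seq = batch$seq[i],
               qual = utf8ToInt(batch$qual[i]) - 33L,
               mapq = batch$mapq[i], flag = batch$flag[i])
}

#' Fetch reads overlapping an interval
#'
#' Yields every stored record whose reference span intersects
#' `[start, end)`, in non-decreasing start order (file order of a
#' coordinate-sorted BAM), each exactly once.
#'
#' @param handle An [open_alignment()] handle.
#' @param interval A [genomic_interval()].
#' @return A list of [aligned_read()] records.
#' @export
fetch_overlapping <- function(handle, interval) {
  batch <- fetch_batch(handle, interval)
  lapply(seq_len(batch$n), function(i) batch_read(batch, i))
}

#' Extract an upper-cased reference window
#'
#' @param fasta Path to an indexed FASTA file (`.fai` present or creatable).
#' @param interval A [genomic_interval()]; must lie within the chromosome.
#' @return A list with `interval` and `bases` (upper-case string of length
#'   `end - start`; soft-masked lower-case input is upper-cased, N kept).
#' @export
reference_window <- function(fasta, interval) {
  rk_assert(file.exists(fasta), "redikit_missing_file",
            "FASTA not found: %s", fasta)
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  fa <- Rsamtools::FaFile(fasta)
  idx <- Rsamtools::scanFaIndex(fa)
  lens <- setNames(BiocGenerics::width(idx),
                   as.character(GenomeInfoDb::seqnames(idx)))
  rk_assert(interval$chrom %in% names(lens), "redikit_unknown_chrom",
            "chromosome '%s' not in FASTA", interval$chrom)
  clen <- lens[[interval$chrom]]
  rk_assert(interval$end <= clen, "redikit_out_of_bounds",
            "interval %s:[%d,%d) exceeds chromosome length %d",
            interval$chrom, interval$start, interval$end, clen)
  gr <- GenomicRanges::GRanges(interval$chrom,
                               IRanges::IRanges(interval$start + 1L,
                                                interval$end))
  bases <- toupper(as.character(Rsamtools::scanFa(fa, gr)[[1]]))
  structure(list(interval = interval, bases = bases),
            class = "reference_window")
}

#' Parse a samtools-style region string
#'
#' `chrom:start-end` with 1-based inclusive coordinates (samtools dialect),
#' converted to the package's 0-based half-open convention; a bare `chrom`
#' means the whole chromosome (requires `chrom_lengths`).
#'
#' @param region Region string.
#' @param chrom_lengths Named integer vector of chromosome lengths, used for
#'   bare-chromosome regions and bounds checks.
#' @return A [genomic_interval()].
#' @export
parse_region <- function(region, chrom_lengths = NULL) {
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) == 4L) {
    s1 <- as.integer(gsub(",", "", m[3]))
    e1 <- as.integer(gsub(",", "", m[4]))
    rk_assert(s1 >= 1L && e1 >= s1, "redikit_bad_region",
              "bad region coordinates: %s", region)
    return(genomic_interval(m[2], s1 - 1L, e1))
  }
  rk_assert(!grepl(":", region), "redikit_bad_region",
            "cannot parse region: %s", region)
  rk_assert(!is.null(chrom_lengths) && region %in% names(chrom_lengths),
            "redikit_bad_region",
            "bare-chromosome region '%s' needs a known chromosome", region)
  genomic_interval(region, 0L, chrom_lengths[[region]])
}

#' Read a 3+ column BED file as a list of intervals
#'
#' BED is 0-based half-open, matching the internal convention.  A numeric
#' 5th column, when present, is attached as the interval weight.
#'
#' @param path BED file path.
#' @return List of [genomic_interval()].
#' @export
read_bed_intervals <- function(path) {
  rk_assert(file.exists(path), "redikit_missing_file",
            "BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    rk_assert(length(f) >= 3L, "redikit_bad_bed", "BED line too short: %s", ln)
    w <- if (length(f) >= 5L) suppressWarnings(as.numeric(f[5])) else NA_real_
    genomic_interval(f[1], as.integer(f[2]), as.integer(f[3]), weight = w)
  })
}
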