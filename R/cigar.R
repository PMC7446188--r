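# CIGAR parsing and genomic-position -> query-offset resolution.

CIGAR_QUERY <- c("M", "I", "S", "=", "X")   # consume query bases
CIGAR_REF   <- c("M", "D", "N", "=", "X")   # consume reference positions
CIGAR_ALN   <- c("M", "=", "X")             # consume both (aligned bases)

#' Parse a CIGAR string
#'
#' @param cigar CIGAR string such as `"2M2I3M"`; `"*"` is rejected.
#' @return A data.frame with columns `op` (character) and `len` (integer),
#'   in alignment order.
#' @export
parse_cigar <- function(cigar) {
  rk_assert(is.character(cigar) && length(cigar) == 1L && cigar != "*" &&
              grepl("^([0-9]+[MIDNSHP=X])+$", cigar),
            "redikit_bad_cigar", "malformed CIGAR: %s", cigar)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  data.frame(op = substring(toks, nchar(toks), nchar(toks)),
             len = as.integer(substring(toks, 1L, nchar(toks) - 1L)),
             stringsAsFactors = FALSE)
}

#' Resolve a genomic position to a read base
#'
#' Walks the CIGAR of one read.  When `gpos` falls in an aligned (M/=/X)
#' segment the query base and its Phred quality are returned; when it falls
#' in a deletion (D) or reference skip (N) the position has no read base and
#' `NULL` (a gap) is returned.  Insertions and soft clips consume query only
#' and can never map to a genomic position.
#'
#' @param read An [aligned_read()].
#' @param gpos 0-based genomic coordinate inside the read's reference span.
#' @return `list(base=, qual=)`, or `NULL` for a gap.
#' @export
base_at <- function(read, gpos) {
  rend <- read_end(read)
  rk_assert(gpos >= read$start && gpos < rend, "redikit_out_of_span",
            "position %d outside read span [%d,%d)", gpos, read$start, rend)
  rpos <- read$start
  qpos <- 0L
  for (i in seq_len(nrow(read$ops))) {
    op <- read$ops$op[i]
    len <- read$ops$len[i]
    if (op %in% CIGAR_ALN) {
      if (gpos < rpos + len) {
        off <- qpos + (gpos - rpos) + 1L
        return(list(base = substring(read$seq, off, off),
                    qual = read$qual[off]))
      }
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (gpos < rpos + len) return(NULL)
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    }
    # H and P consume nothing we track
  }
  rk_stop("redikit_internal", "CIGAR walk fell through at %d", gpos)
}

# --- vectorised expansion used by the engine --------------------------------
#
# Expands a columnar batch of reads into parallel vectors of
# (read row, genomic position, base code, quality, reverse flag), covering
# every aligned (M/=/X) base of every read.  Each read is touched once;
# everything below is C-level vectorised.
#
# Base codes: A=1 C=2 G=3 T=4, anything else 0.
BASE_CODE <- local({
  v <- integer(256)
  v[utf8ToInt("A") + 1L] <- 1L; v[utf8ToInt("a") + 1L] <- 1L
  v[utf8ToInt("C") + 1L] <- 2L; v[utf8ToInt("c") + 1L] <- 2L
  v[utf8ToInt("G") + 1L] <- 3L; v[utf8ToInt("g") + 1L] <- 3L
  v[utf8ToInt("T") + 1L] <- 4L; v[utf8ToInt("t") + 1L] <- 4L
  v
})

expand_batch <- function(batch, rows = seq_len(batch$n)) {
  if (length(rows) == 0L) {
    return(list(row = integer(0), gpos = integer(0), code = integer(0),
                qual = integer(0)))
  }
  cig <- batch$cigar[rows]
  toks <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))
  nop <- lengths(toks)
  toks <- unlist(toks, use.names = FALSE)
  op  <- substring(toks, nchar(toks), nchar(toks))
  len <- as.integer(substring(toks, 1L, nchar(toks) - 1L))
  ridx <- rep.int(seq_along(rows), nop)          # index into `rows`

  qcons <- ifelse(op %in% CIGAR_QUERY, len, 0L)
  rcons <- ifelse(op %in% CIGAR_REF, len, 0L)
  qend <- cumsum(qcons); rend <- cumsum(rcons)
  qoff <- qend - qcons;  roff <- rend - rcons
  first <- c(0L, cumsum(nop))[seq_along(rows)] + 1L  # first op of each read
  qoff <- qoff - rep.int(qoff[first], nop)           # 0-based within read
  roff <- roff - rep.int(roff[first], nop)

  aln <- op %in% CIGAR_ALN
  alen <- len[aln]
  if (!length(alen) || sum(alen) == 0L) {
    return(list(row = integer(0), gpos = integer(0), code = integer(0),
                qual = integer(0)))
  }
  within <- sequence(alen) - 1L
  arow <- rep.int(ridx[aln], alen)
  gpos <- rep.int(batch$start[rows][ridx[aln]] + roff[aln], alen) + within
  qidx <- rep.int(qoff[aln], alen) + within      # 0-based query offset

  # per-read query sequences/qualities concatenated once
  seqraw <- charToRaw(paste0(batch$seq[rows], collapse = ""))
  qraw   <- charToRaw(paste0(batch$qual[rows], collapse = ""))
  seqlen <- nchar(batch$seq[rows])
  seq0 <- c(0L, cumsum(seqlen))[seq_along(rows)]  # offset of read's seq
  flat <- seq0[arow] + qidx + 1L
  list(row  = rows[arow],
       gpos = gpos,
       code = BASE_CODE[as.integer(seqraw[flat]) + 1L],
       qual = as.integer(qraw[flat]) - 33L)
}
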