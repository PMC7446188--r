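# Read simulation with planted A-to-G editing sites.
#
# The simulator emulates what the detector faces in practice: several
# chromosomes, uneven coverage with hotspots, reads with realistic CIGARs
# (plain matches, splices with N gaps, small insertions/deletions, soft
# clips), per-base Phred qualities, sequencing errors, and editing sites
# planted at known per-site frequencies (A->G on the plus strand, T->C on
# the minus strand, both written in reference orientation as SAM records
# are).  All randomness is governed by a single seed.

#' Coverage profile
#'
#' @param baseline Expected baseline depth (>= 0).
#' @param hotspots List of `list(interval =, fold =)` entries; expected
#'   depth inside a hotspot is multiplied by `fold` (>= 1).  Overlapping
#'   hotspots multiply.
#' @return An object of class `coverage_profile`.
#' @export
coverage_profile <- function(baseline, hotspots = list()) {
  rk_assert(is.numeric(baseline) && baseline >= 0, "redikit_bad_profile",
            "baseline depth must be >= 0")
  for (h in hotspots) {
    rk_assert(inherits(h$interval, "genomic_interval") &&
                is.numeric(h$fold) && h$fold >= 1,
              "redikit_bad_profile",
              "each hotspot needs an interval and a fold >= 1")
  }
  structure(list(baseline = baseline, hotspots = hotspots),
            class = "coverage_profile")
}

#' Expected depth at positions
#'
#' Baseline depth times the product of the fold-increases of every hotspot
#' containing the position.
#'
#' @param profile A [coverage_profile()].
#' @param chrom Chromosome name.
#' @param pos Vector of 0-based positions.
#' @return Numeric vector of expected depths.
#' @export
expected_depth <- function(profile, chrom, pos) {
  d <- rep(profile$baseline, length(pos))
  for (h in profile$hotspots) {
    if (h$interval$chrom != chrom) next
    inside <- pos >= h$interval$start & pos < h$interval$end
    d[inside] <- d[inside] * h$fold
  }
  d
}

#' Generate a random reference genome
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (names
#'   default to `chr1`, `chr2`, ...).
#' @param gc_fraction Expected G+C fraction in `[0, 1]`.
#' @param seed Integer seed; the output is deterministic per seed.
#' @param path Output FASTA path; a `.fai` index is created next to it.
#' @return Invisibly, `path`.
#' @export
generate_reference <- function(chrom_lengths, gc_fraction = 0.4, seed = 1L,
                               path = tempfile(fileext = ".fa")) {
  rk_assert(all(chrom_lengths >= 1L), "redikit_bad_config",
            "chromosome lengths must be >= 1")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  set.seed(seed)
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
             gc_fraction / 2, (1 - gc_fraction) / 2)
  seqs <- vapply(chrom_lengths, function(L) {
    paste(sample(BASES, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(chrom_lengths)
  Biostrings::writeXStringSet(dna, path)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Plant editing sites into a truth table
#'
#' Draws `n_sites` positions without replacement among A bases (plus-strand
#' sites) and T bases (minus-strand sites) of the reference, assigning each
#' a target editing frequency uniform in `freq_range`.
#'
#' @param fasta Reference FASTA path.
#' @param n_sites Number of sites.
#' @param freq_range Length-2 numeric vector in `(0, 1]`.
#' @param seed Integer seed.
#' @param margin Exclude positions closer than this to a chromosome end,
#'   where simulated coverage ramps down (0 disables).
#' @return A data.frame of class `truth_table` with columns `chrom`, `pos`
#'   (0-based), `ref` (A or T), `strand` (`+`/`-`), `freq`.
#' @export
plant_sites <- function(fasta, n_sites, freq_range = c(0.1, 1.0), seed = 1L,
                        margin = 0L) {
  rk_assert(is_count(n_sites), "redikit_bad_config", "n_sites must be >= 0")
  rk_assert(length(freq_range) == 2L && freq_range[1] > 0 &&
              freq_range[2] <= 1 && freq_range[1] <= freq_range[2],
            "redikit_bad_config", "freq_range must lie in (0,1]")
  set.seed(seed)
  dna <- Biostrings::readDNAStringSet(fasta)
  names(dna) <- sub("\\s.*$", "", names(dna))
  cand <- do.call(rbind, lapply(names(dna), function(ch) {
    s <- as.character(dna[[ch]])
    chars <- strsplit(s, "")[[1]]
    pos <- which(chars %in% c("A", "T")) - 1L
    pos <- pos[pos >= margin & pos < nchar(s) - margin]
    if (!length(pos)) return(NULL)
    data.frame(chrom = ch, pos = pos, ref = chars[pos + 1L],
               stringsAsFactors = FALSE)
  }))
  rk_assert(!is.null(cand) && nrow(cand) >= n_sites,
            "redikit_no_eligible_sites",
            "only %d eligible A/T positions for %d sites",
            if (is.null(cand)) 0L else nrow(cand), n_sites)
  pick <- cand[sample.int(nrow(cand), n_sites), , drop = FALSE]
  pick$strand <- ifelse(pick$ref == "A", "+", "-")
  pick$freq <- runif(n_sites, freq_range[1], freq_range[2])
  pick <- pick[order(match(pick$chrom, names(dna)), pick$pos), , drop = FALSE]
  rownames(pick) <- NULL
  class(pick) <- c("truth_table", "data.frame")
  pick
}

#' Write / read a truth table as TSV
#'
#' @param truth A `truth_table`.
#' @param path TSV path.
#' @return `write_truth_table()`: invisibly `path`; `read_truth_table()`:
#'   the table.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("truth_table", "data.frame")
  out
}

# draw a CIGAR layout for one read; every layout consumes exactly
# read_length query bases.  Returns list(cigar=, segs=data.frame) where
# segs rows are aligned M segments as (qoff 0-based, roff 0-based, len).
sim_layout <- function(kind, read_length) {
  L <- read_length
  if (kind == "splice") {
    m1 <- sample.int(L - 20L, 1L) + 10L - 1L      # 10..L-10
    gap <- sample(20:200, 1L)
    list(cigar = sprintf("%dM%dN%dM", m1, gap, L - m1),
         segs = data.frame(qoff = c(0L, m1), roff = c(0L, m1 + gap),
                           len = c(m1, L - m1)))
  } else if (kind == "ins") {
    ins <- sample(1:3, 1L)
    m1 <- sample.int(L - ins - 10L, 1L) + 5L - 1L
    m2 <- L - ins - m1
    list(cigar = sprintf("%dM%dI%dM", m1, ins, m2),
         segs = data.frame(qoff = c(0L, m1 + ins), roff = c(0L, m1),
                           len = c(m1, m2)))
  } else if (kind == "del") {
    del <- sample(1:3, 1L)
    m1 <- sample.int(L - 10L, 1L) + 5L - 1L
    m2 <- L - m1
    list(cigar = sprintf("%dM%dD%dM", m1, del, m2),
         segs = data.frame(qoff = c(0L, m1), roff = c(0L, m1 + del),
                           len = c(m1, m2)))
  } else if (kind == "clip") {
    s1 <- sample(3:10, 1L)
    list(cigar = sprintf("%dS%dM", s1, L - s1),
         segs = data.frame(qoff = s1, roff = 0L, len = L - s1))
  } else {
    list(cigar = sprintf("%dM", L),
         segs = data.frame(qoff = 0L, roff = 0L, len = L))
  }
}

#' Simulate aligned reads with planted edits
#'
#' Read start positions are drawn in proportion to the expected-depth
#' profile, so realised per-position depth follows it (smoothed over a read
#' length).  At every truth site each overlapping read independently
#' carries the edited base (G for plus-strand sites, C for minus-strand
#' sites) with probability `target_frequency`; sequencing errors then hit
#' every base independently at `error_rate`.  Fractions of reads receive a
#' spliced (N gap), small-indel or soft-clipped CIGAR.  Base qualities are
#' drawn in 30..40 except for a `low_q_frac` fraction drawn in 2..24.
#'
#' @param fasta Reference FASTA (from [generate_reference()]).
#' @param truth A `truth_table` (possibly empty) from [plant_sites()].
#' @param profile A [coverage_profile()], or a single number used as a
#'   uniform baseline.
#' @param read_length Read length in bases (default 100).
#' @param error_rate Per-base substitution error probability (default
#'   0.001).
#' @param frac_spliced,frac_indel,frac_softclip Fractions of reads with a
#'   spliced, indel or soft-clipped CIGAR (defaults 0.05 each).
#' @param low_q_frac Fraction of bases with quality below 25 (default 0).
#' @param reverse_prob Probability a read is reverse-oriented (default
#'   0.5).
#' @param seed Integer seed; output is deterministic per seed.
#' @param path Output BAM path (without temporaries); the file is
#'   coordinate-sorted and indexed.
#' @return Invisibly, the BAM path.
#' @export
simulate_alignments <- function(fasta, truth, profile, read_length = 100L,
                                error_rate = 0.001, frac_spliced = 0.05,
                                frac_indel = 0.05, frac_softclip = 0.05,
                                low_q_frac = 0, reverse_prob = 0.5,
                                seed = 1L,
                                path = tempfile(fileext = ".bam")) {
  if (is.numeric(profile)) profile <- coverage_profile(profile)
  set.seed(seed)
  dna <- Biostrings::readDNAStringSet(fasta)
  names(dna) <- sub("\\s.*$", "", names(dna))
  chrom_lengths <- setNames(Biostrings::width(dna), names(dna))
  rk_assert(read_length <= min(chrom_lengths), "redikit_bad_config",
            "read_length exceeds the shortest chromosome")

  sam_lines <- c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                         chrom_lengths))
  rid <- 0L
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    refstr <- as.character(dna[[ch]])
    w <- expected_depth(profile, ch, seq_len(L) - 1L)
    n_reads <- round(sum(w) / read_length)
    if (n_reads == 0L) next

    kinds <- sample(c("plain", "splice", "ins", "del", "clip"), n_reads,
                    replace = TRUE,
                    prob = c(1 - frac_spliced - frac_indel - frac_softclip,
                             frac_spliced, frac_indel / 2, frac_indel / 2,
                             frac_softclip))
    starts <- sample.int(L, n_reads, replace = TRUE, prob = w) - 1L

    cigars <- character(n_reads)
    seqs <- character(n_reads)
    site_rows <- truth[truth$chrom == ch, , drop = FALSE]
    plain <- kinds == "plain"

    # plain reads in bulk
    pstart <- pmin(starts[plain], L - read_length)
    starts[plain] <- pstart
    cigars[plain] <- sprintf("%dM", read_length)
    seqs[plain] <- substring(refstr, pstart + 1L, pstart + read_length)

    # structured CIGARs one by one (a small fraction of reads)
    spans <- rep(read_length, n_reads)
    for (i in which(!plain)) {
      lay <- sim_layout(kinds[i], read_length)
      span <- max(lay$segs$roff + lay$segs$len)
      spans[i] <- span
      s <- min(starts[i], L - span)
      starts[i] <- s
      cigars[i] <- lay$cigar
      piece <- character(nrow(lay$segs) + 1L)
      # soft-clipped / inserted bases are random, aligned segments copy ref
      qcursor <- 0L
      out <- character(0)
      for (k in seq_len(nrow(lay$segs))) {
        seg <- lay$segs[k, ]
        if (seg$qoff > qcursor) {
          out <- c(out, paste(sample(BASES, seg$qoff - qcursor,
                                     replace = TRUE), collapse = ""))
        }
        out <- c(out, substring(refstr, s + seg$roff + 1L,
                                s + seg$roff + seg$len))
        qcursor <- seg$qoff + seg$len
      }
      if (qcursor < read_length) {
        out <- c(out, paste(sample(BASES, read_length - qcursor,
                                   replace = TRUE), collapse = ""))
      }
      seqs[i] <- paste(out, collapse = "")
    }

    # plant edits: per covering read, independently with prob freq
    if (nrow(site_rows)) {
      layouts <- vector("list", n_reads)
      for (i in which(!plain)) layouts[[i]] <- sim_layout_cached(cigars[i])
      for (r in seq_len(nrow(site_rows))) {
        p <- site_rows$pos[r]
        edited <- if (site_rows$strand[r] == "+") "G" else "C"
        # plain reads covering p
        cov_plain <- which(plain & starts <= p & starts + read_length > p)
        if (length(cov_plain)) {
          hit <- cov_plain[runif(length(cov_plain)) < site_rows$freq[r]]
          off <- p - starts[hit] + 1L
          for (j in seq_along(hit)) {
            substr(seqs[hit[j]], off[j], off[j]) <- edited
          }
        }
        # structured reads whose span covers p: locate the aligned segment
        for (i in which(!plain & starts <= p & starts + spans > p)) {
          segs <- layouts[[i]]
          roff <- p - starts[i]
          k <- which(segs$roff <= roff & roff < segs$roff + segs$len)
          if (!length(k)) next
          if (runif(1L) < site_rows$freq[r]) {
            off <- segs$qoff[k] + (roff - segs$roff[k]) + 1L
            substr(seqs[i], off, off) <- edited
          }
        }
      }
    }

    # sequencing errors: flip to one of the three other bases
    if (error_rate > 0) {
      total <- n_reads * read_length
      nerr <- rbinom(1L, total, error_rate)
      if (nerr > 0L) {
        at <- sample.int(total, nerr)
        ri <- (at - 1L) %/% read_length + 1L
        off <- (at - 1L) %% read_length + 1L
        for (j in seq_len(nerr)) {
          old <- substr(seqs[ri[j]], off[j], off[j])
          new <- sample(setdiff(BASES, old), 1L)
          substr(seqs[ri[j]], off[j], off[j]) <- new
        }
      }
    }

    # qualities: high by default, a configurable low-quality fraction
    q <- sample(30:40, n_reads * read_length, replace = TRUE)
    if (low_q_frac > 0) {
      lo <- which(runif(length(q)) < low_q_frac)
      q[lo] <- sample(2:24, length(lo), replace = TRUE)
    }
    qbig <- rawToChar(as.raw(q + 33L))
    quals <- substring(qbig, seq.int(1L, by = read_length,
                                     length.out = n_reads),
                       seq.int(read_length, by = read_length,
                               length.out = n_reads))

    flags <- ifelse(runif(n_reads) < reverse_prob, 16L, 0L)
    sam_lines <- c(sam_lines, paste(
      sprintf("r%s_%07d", ch, rid + seq_len(n_reads)),
      flags, ch, starts + 1L, 60L, cigars, "*", 0L, 0L, seqs, quals,
      sep = "\t"))
    rid <- rid + n_reads
  }

  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  writeLines(sam_lines, sam)
  dest <- sub("\\.bam$", "", path)
  bam <- Rsamtools::asBam(sam, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  invisible(bam)
}

# re-derive aligned segments from a CIGAR string (for edit planting)
sim_layout_cached <- function(cigar) {
  ops <- parse_cigar(cigar)
  qoff <- 0L; roff <- 0L
  segs <- list()
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% CIGAR_ALN) {
      segs[[length(segs) + 1L]] <- data.frame(qoff = qoff, roff = roff,
                                              len = len)
      qoff <- qoff + len; roff <- roff + len
    } else if (op %in% c("D", "N")) {
      roff <- roff + len
    } else if (op %in% c("I", "S")) {
      qoff <- qoff + len
    }
  }
  do.call(rbind, segs)
}
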