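# Editing-site calling and the REDItools tabular format.
#
# One output row per candidate site:
#   Region  Position  Reference  Strand  Coverage-q<Q>  MeanQ
#   BaseCount[A,C,G,T]  AllSubs  Frequency
# Position is 1-based; Strand is 1 (plus), 0 (minus) or 2 (undefined);
# Frequency is the editing level of the dominant substitution.

BASES <- c("A", "C", "G", "T")

#' Caller configuration
#'
#' @param min_coverage Minimum quality-filtered coverage at a position
#'   (default 10).
#' @param min_alt_reads Minimum supporting reads for a substitution
#'   (default 3).
#' @param min_frequency Minimum substitution frequency (default 0.10).
#' @param strandedness `"unstranded"` (strand code always 2), `"forward"`
#'   (read orientation encodes transcript strand) or `"reverse"` (opposite
#'   protocol).
#' @param emit_all If `TRUE`, every position meeting `min_coverage` is
#'   reported, with `AllSubs = "-"` and frequency 0 when no substitution
#'   qualifies.
#' @return An object of class `caller_config`.
#' @export
caller_config <- function(min_coverage = 10L, min_alt_reads = 3L,
                          min_frequency = 0.10,
                          strandedness = c("unstranded", "forward", "reverse"),
                          emit_all = FALSE) {
  rk_assert(is_count(min_coverage, 1L), "redikit_bad_config",
            "min_coverage must be >= 1")
  rk_assert(is_count(min_alt_reads, 1L), "redikit_bad_config",
            "min_alt_reads must be >= 1")
  rk_assert(is.numeric(min_frequency) && min_frequency >= 0 &&
              min_frequency <= 1, "redikit_bad_config",
            "min_frequency must lie in [0,1]")
  structure(list(min_coverage = as.integer(min_coverage),
                 min_alt_reads = as.integer(min_alt_reads),
                 min_frequency = min_frequency,
                 strandedness = match.arg(strandedness),
                 emit_all = isTRUE(emit_all)),
            class = "caller_config")
}

#' Observed substitutions at a position
#'
#' @param base_count Integer vector of 4 counts in A,C,G,T order.
#' @param reference Reference base, one of A,C,G,T.
#' @return A data.frame with columns `label` (e.g. `"AG"`), `count` and
#'   `frequency` (count / total), one row per non-reference base with a
#'   positive count, ordered by descending count then alphabetical label.
#' @export
substitution_frequencies <- function(base_count, reference) {
  rk_assert(length(base_count) == 4L && all(base_count >= 0),
            "redikit_bad_counts", "base_count must be 4 non-negative counts")
  rk_assert(reference %in% BASES, "redikit_bad_reference",
            "reference must be one of A,C,G,T, got '%s'", reference)
  total <- sum(base_count)
  rk_assert(total > 0, "redikit_zero_coverage",
            "no counted bases at this position")
  alt <- setdiff(seq_len(4L), match(reference, BASES))
  alt <- alt[base_count[alt] > 0L]
  if (!length(alt)) {
    return(data.frame(label = character(0), count = integer(0),
                      frequency = numeric(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(label = paste0(reference, BASES[alt]),
                    count = as.integer(base_count[alt]),
                    frequency = base_count[alt] / total,
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$label), , drop = FALSE]
}

#' Infer the transcript strand code at a position
#'
#' Codes follow the output convention: 1 plus strand, 0 minus strand,
#' 2 not defined.  Unstranded libraries always yield 2.  For stranded
#' protocols the majority read orientation decides, with ties and zero
#' coverage mapping to 2; the `"reverse"` protocol flips the
#' orientation-to-strand correspondence.
#'
#' @param forward,reverse Counts of forward- and reverse-oriented counted
#'   reads.
#' @param strandedness One of `"unstranded"`, `"forward"`, `"reverse"`.
#' @return Integer strand code in `{0, 1, 2}`.
#' @export
infer_strand <- function(forward, reverse,
                         strandedness = c("unstranded", "forward", "reverse")) {
  strandedness <- match.arg(strandedness)
  rk_assert(all(forward >= 0) && all(reverse >= 0), "redikit_bad_counts",
            "strand counts must be non-negative")
  if (strandedness == "unstranded") return(rep(2L, length(forward)))
  plus_is_fwd <- strandedness == "forward"
  out <- rep(2L, length(forward))
  out[forward > reverse] <- if (plus_is_fwd) 1L else 0L
  out[reverse > forward] <- if (plus_is_fwd) 0L else 1L
  out
}

#' Call one position
#'
#' Converts a pileup row plus its reference base into an editing-site
#' record, or `NULL` when the position does not qualify: reference N, or
#' coverage below `min_coverage`, or (unless `emit_all`) no substitution
#' with at least `min_alt_reads` supporting reads and frequency at least
#' `min_frequency`.
#'
#' @param pileup One row of a [traverse()] result (or any list with fields
#'   `chrom`, `pos`, `A`, `C`, `G`, `T`, `qual_sum`, `fwd`, `rev`).
#' @param reference Reference base at the position (A,C,G,T or N).
#' @param config A [caller_config()].
#' @return A one-row data.frame (see [write_site_table()] for columns) or
#'   `NULL`.
#' @export
call_site <- function(pileup, reference, config = caller_config()) {
  rk_assert(reference %in% c(BASES, "N"), "redikit_bad_reference",
            "invalid reference symbol '%s'", reference)
  if (reference == "N") return(NULL)
  counts <- c(pileup$A, pileup$C, pileup$G, pileup$T)
  cov <- sum(counts)
  if (cov < config$min_coverage) return(NULL)
  subs <- substitution_frequencies(counts, reference)
  qual <- subs[subs$count >= config$min_alt_reads &
                 subs$frequency >= config$min_frequency, , drop = FALSE]
  if (nrow(qual) == 0L && !config$emit_all) return(NULL)
  all_subs <- if (nrow(qual)) paste(qual$label, collapse = " ") else "-"
  freq <- if (nrow(qual)) qual$frequency[1] else 0
  data.frame(region = pileup$chrom,
             position = pileup$pos + 1L,
             reference = reference,
             strand = infer_strand(pileup$fwd, pileup$rev,
                                   config$strandedness),
             coverage = cov,
             mean_q = pileup$qual_sum / cov,
             A = counts[1], C = counts[2], G = counts[3], T = counts[4],
             all_subs = all_subs,
             frequency = freq,
             stringsAsFactors = FALSE)
}

#' Call every qualifying position of a traversed interval
#'
#' Vectorised equivalent of applying [call_site()] to each pileup row with
#' its reference base (the equivalence is exercised by the test suite).
#'
#' @param pileup A [traverse()] result.
#' @param refwin The matching [reference_window()].
#' @param config A [caller_config()].
#' @return A data.frame of editing-site records, possibly empty, sorted by
#'   position.
#' @export
call_sites <- function(pileup, refwin, config = caller_config()) {
  empty <- empty_sites()
  if (nrow(pileup) == 0L) return(empty)
  iv <- refwin$interval
  rk_assert(identical(iv$chrom, pileup$chrom[1]) &&
              all(pileup$pos >= iv$start & pileup$pos < iv$end),
            "redikit_window_mismatch",
            "pileup positions fall outside the reference window")
  refb <- substring(refwin$bases, pileup$pos - iv$start + 1L,
                    pileup$pos - iv$start + 1L)
  m <- as.matrix(pileup[, BASES])
  cov <- rowSums(m)
  cand <- which(refb %in% BASES & cov >= config$min_coverage)
  if (!length(cand)) return(empty)

  ref_idx <- match(refb[cand], BASES)
  altm <- m[cand, , drop = FALSE]
  altm[cbind(seq_along(cand), ref_idx)] <- 0L
  altf <- altm / cov[cand]
  qual <- altm >= config$min_alt_reads & altf >= config$min_frequency
  has <- rowSums(qual) > 0L
  if (!config$emit_all) {
    cand <- cand[has]
    if (!length(cand)) return(empty)
    ref_idx <- ref_idx[has]
    altm <- altm[has, , drop = FALSE]
    qual <- qual[has, , drop = FALSE]
    has <- has[has]
  }

  qcnt <- altm * qual
  # dominant qualifying substitution: max count, alphabetical tie-break
  dom <- max.col(qcnt, ties.method = "first")
  freq <- ifelse(has, qcnt[cbind(seq_along(dom), dom)] / cov[cand], 0)
  all_subs <- vapply(seq_along(dom), function(i) {
    j <- which(qual[i, ])
    if (!length(j)) return("-")
    j <- j[order(-qcnt[i, j], BASES[j])]
    paste0(refb[cand][i], BASES[j], collapse = " ")
  }, character(1))

  data.frame(region = pileup$chrom[cand],
             position = pileup$pos[cand] + 1L,
             reference = refb[cand],
             strand = infer_strand(pileup$fwd[cand], pileup$rev[cand],
                                   config$strandedness),
             coverage = as.integer(cov[cand]),
             mean_q = pileup$qual_sum[cand] / cov[cand],
             A = m[cand, 1], C = m[cand, 2], G = m[cand, 3], T = m[cand, 4],
             all_subs = all_subs,
             frequency = freq,
             stringsAsFactors = FALSE, row.names = NULL)
}

empty_sites <- function() {
  data.frame(region = character(0), position = integer(0),
             reference = character(0), strand = integer(0),
             coverage = integer(0), mean_q = numeric(0),
             A = integer(0), C = integer(0), G = integer(0), T = integer(0),
             all_subs = character(0), frequency = numeric(0),
             stringsAsFactors = FALSE)
}

site_header <- function(qcut) {
  paste("Region", "Position", "Reference", "Strand",
        sprintf("Coverage-q%d", qcut), "MeanQ", "BaseCount[A,C,G,T]",
        "AllSubs", "Frequency", sep = "\t")
}

format_site_rows <- function(records) {
  if (nrow(records) == 0L) return(character(0))
  paste(records$region, records$position, records$reference, records$strand,
        records$coverage,
        formatC(records$mean_q, format = "f", digits = 2),
        sprintf("[%d, %d, %d, %d]", records$A, records$C,
                records$G, records$T),
        records$all_subs,
        formatC(records$frequency, format = "f", digits = 2),
        sep = "\t")
}

check_site_order <- function(records, what = "records") {
  if (nrow(records) < 2L) return(invisible(TRUE))
  chrom <- factor(records$region, levels = unique(records$region))
  rk_assert(!is.unsorted(as.integer(chrom)) &&
              all(diff(records$position)[diff(as.integer(chrom)) == 0L] >= 0L),
            "redikit_unsorted_records",
            "%s are not sorted by (chromosome, position)", what)
  invisible(TRUE)
}

#' Write editing-site records in the REDItools tabular format
#'
#' @param records A data.frame of records as produced by [call_sites()],
#'   sorted by (chromosome appearance order, position).
#' @param path Output file path.
#' @param qcut Base-quality threshold used for counting; becomes the
#'   `Coverage-q<Q>` column name.
#' @return Invisibly, the number of data rows written.
#' @export
write_site_table <- function(records, path, qcut = 25L) {
  check_site_order(records)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(site_header(qcut), format_site_rows(records)), con)
  invisible(nrow(records))
}

#' Read a REDItools-format table back
#'
#' Companion reader for [write_site_table()]; round-trips everything the
#' writer emits (frequencies and mean qualities at 2 decimals).
#'
#' @param path File path.
#' @return A data.frame with the same columns as [call_sites()]; the quality
#'   threshold parsed from the header is attached as attribute `qcut`.
#' @export
read_site_table <- function(path) {
  rk_assert(file.exists(path), "redikit_missing_file",
            "site table not found: %s", path)
  lines <- readLines(path)
  rk_assert(length(lines) >= 1L && startsWith(lines[1], "Region\t"),
            "redikit_bad_table", "not a site table: %s", path)
  qcut <- as.integer(sub(".*Coverage-q([0-9]+).*", "\\1", lines[1]))
  body <- lines[-1]
  if (!length(body)) {
    out <- empty_sites()
    attr(out, "qcut") <- qcut
    return(out)
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  bc <- gsub("\\[|\\]| ", "", f[, 7])
  bcm <- do.call(rbind, lapply(strsplit(bc, ",", fixed = TRUE), as.integer))
  out <- data.frame(region = f[, 1], position = as.integer(f[, 2]),
                    reference = f[, 3], strand = as.integer(f[, 4]),
                    coverage = as.integer(f[, 5]), mean_q = as.numeric(f[, 6]),
                    A = bcm[, 1], C = bcm[, 2], G = bcm[, 3], T = bcm[, 4],
                    all_subs = f[, 8], frequency = as.numeric(f[, 9]),
                    stringsAsFactors = FALSE)
  attr(out, "qcut") <- qcut
  out
}

#' Merge per-interval tables into one unified file
#'
#' Concatenates the bodies of per-interval temporary files (already in
#' genomic order, each internally sorted) under a single header and checks
#' that the result is globally sorted.
#'
#' @param paths Character vector of per-interval files, ordered by their
#'   intervals' genomic order.
#' @param sink Output file path.
#' @param remove If `TRUE`, delete the input temporaries after a successful
#'   merge.
#' @return Invisibly, the number of data rows in the merged file.
#' @export
merge_outputs <- function(paths, sink, remove = FALSE) {
  missing <- paths[!file.exists(paths)]
  rk_assert(length(missing) == 0L, "redikit_missing_temp",
            "missing temporary file(s): %s", paste(missing, collapse = ", "))
  header <- NULL
  body <- character(0)
  for (p in paths) {
    lines <- readLines(p)
    rk_assert(length(lines) >= 1L && startsWith(lines[1], "Region\t"),
              "redikit_bad_table", "not a site table: %s", p)
    if (is.null(header)) header <- lines[1]
    rk_assert(identical(lines[1], header), "redikit_bad_table",
              "inconsistent headers across temporaries (%s)", p)
    if (length(lines) > 1L) body <- c(body, lines[-1])
  }
  if (is.null(header)) header <- site_header(25L)
  writeLines(c(header, body), sink)
  check_site_order(read_site_table(sink), what = "merged records")
  if (remove) unlink(paths)
  invisible(length(body))
}
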