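# Fixture builders.  Everything is generated in code at test time; no
# binary files ship with the package.

# Write a BAM (sorted + indexed) from hand-specified read tuples.
# reads: data.frame with qname, flag, chrom, pos1 (1-based), mapq, cigar,
# seq, qual (string, Phred+33).  Returns the BAM path.
write_test_bam <- function(reads, chrom_lengths,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "t.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                       as.integer(chrom_lengths)),
               paste(reads$qname, reads$flag, reads$chrom, reads$pos1,
                     reads$mapq, reads$cigar, "*", 0L, 0L, reads$seq,
                     reads$qual, sep = "\t")),
             sam)
  Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE,
                   indexDestination = TRUE)
}

qstring <- function(quals) rawToChar(as.raw(quals + 33L))

# uniform-quality read tuple helper
read_tuple <- function(qname, chrom, pos1, cigar, seq, qual = 35L,
                       flag = 0L, mapq = 60L) {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos1 = pos1,
             mapq = mapq, cigar = cigar, seq = seq,
             qual = qstring(rep(qual, nchar(seq))),
             stringsAsFactors = FALSE)
}

# Random simulated fixture: reference + truth + BAM, deterministic per seed.
make_fixture <- function(seed, chrom_lengths = c(chrA = 1500L, chrB = 900L),
                         depth = 15, n_sites = 5, freq_range = c(0.2, 0.9),
                         read_length = 60L, error_rate = 0.002,
                         low_q_frac = 0.05, margin = 0L,
                         dir = withr::local_tempdir(.local_envir = parent.frame()),
                         ...) {
  fasta <- file.path(dir, "ref.fa")
  generate_reference(chrom_lengths, gc_fraction = 0.45, seed = seed,
                     path = fasta)
  truth <- plant_sites(fasta, n_sites, freq_range = freq_range,
                       seed = seed + 1000L, margin = margin)
  bam <- simulate_alignments(fasta, truth, depth,
                             read_length = read_length,
                             error_rate = error_rate,
                             low_q_frac = low_q_frac,
                             seed = seed + 2000L,
                             path = file.path(dir, "reads.bam"), ...)
  list(fasta = fasta, bam = bam, truth = truth,
       handle = open_alignment(bam), chrom_lengths = chrom_lengths)
}
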