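---
title: "redikit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{redikit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A-to-I RNA editing — deamination of adenosine by ADAR enzymes — is read by
sequencers as guanosine, so edited positions appear in plus-strand RNA-seq
alignments as A→G mismatches (T→C for transcripts on the minus strand).
Detecting editing genome-wide therefore amounts to a careful pileup: at
every reference position, count the qualifying read bases, compare them to
the reference base, and report positions where a substitution is supported
well enough to be a candidate editing event. The computation is simple per
position but must be done at hundreds of millions of positions against
billions of read bases, which makes the traversal strategy and the way work
is split across processes the real engineering content. redikit implements
both, plus the tabular output format and a simulator that makes the whole
stack verifiable without external data.

## Output record

One row per candidate site:

| column | meaning |
|---|---|
| Region, Position | chromosome and 1-based coordinate |
| Reference | genome base (always plus-strand letters; never complemented) |
| Strand | 1 plus, 0 minus, 2 not defined |
| Coverage-q\<Q\> | count of bases with Phred ≥ Q supporting the position |
| MeanQ | mean Phred of counted bases |
| BaseCount[A,C,G,T] | the four counts, e.g. `[7, 0, 3, 0]` |
| AllSubs | qualifying substitutions (`AG`, `TC`, ...) or `-` |
| Frequency | dominant substitution count / Coverage-q\<Q\> |

Internally every coordinate is 0-based half-open; only this table and the
CLI region dialect (`chrom:start-end`, 1-based inclusive) are 1-based.

## Single-load traversal

The classical mpileup-style scan asks the alignment index once per
*position*, so a read of length *l* is deserialised *l* times. `traverse()`
instead fetches each interval once: every overlapping record is retrieved
from storage exactly once, its CIGAR is resolved once into (position, base,
quality) triples, and the read is conceptually held in an active buffer
until the sweep position passes its reference span, at which point it is
dropped. Instrumentation records per-read load counts (all 1 by
construction; audited per query name in the tests against real
per-position re-fetching) and the buffer's peak occupancy, which equals the
maximum read-span stabbing count over the interval.

Counting rules: only bases in A,C,G,T with quality ≥ `min_base_quality`
(default 25, reflected in the `Coverage-q25` column name) from reads that
are mapped, have mapping quality ≥ 25 and carry none of the excluded flags
(secondary, supplementary, duplicate, QC-fail — all configurable).
Deletions and N skips (splices) contribute nothing; soft-clipped and
inserted bases have no genomic position and are never counted. Mates
overlapping the same position are counted independently — a documented
limitation, as fragment-level de-duplication is out of scope. The default
sparse mode omits zero-coverage positions; dense mode emits every position
and is what the recount oracle compares against.

## Caller thresholds

A position becomes a record when the reference base is not N, quality
coverage is ≥ `min_coverage` (10), and — unless `emit_all` — at least one
substitution has ≥ `min_alt_reads` (3) supporting bases and frequency ≥
`min_frequency` (0.10). The source method publishes no thresholds; these
are the original tool's documented conventions and are CLI-configurable.
When several substitutions qualify, the `Frequency` column reports the one
with the highest count, ties broken alphabetically; `AllSubs` lists them
all. The frequency denominator is total qualifying coverage (not reference
+ alternate only) — the alternative denominator would only differ at
multi-allelic positions, which are rare and usually artefactual.

Strand: unstranded libraries always get code 2. For stranded protocols the
majority orientation of counted reads decides (ties and zero coverage → 2),
with the `reverse` protocol flipping the orientation-to-strand map.
Reference and substitution letters are always reported in plus-strand
(genome FASTA) orientation, so a minus-strand editing site reads `TC`;
complementing is deferred to downstream tools to keep records comparable to
the reference.

## Dynamic Interval Analysis

Equal-width genome splits balance badly because RNA-seq coverage is
extremely uneven: one hotspot interval can take longer than the rest of the
genome combined. DIA balances estimated *cost*, not width. Per-position
cost is modelled as

$$t(i) = \alpha + b \cdot \mathrm{cov}(i)^d$$

with defaults α = 1, b = 1, d = 3: processing time grows cubically with
coverage (the empirical log–log fit of per-interval runtime against mean
coverage), and a positive floor gives empty regions nonzero cost so sparse
genomes still tile into finitely many intervals. `fit_time_model()`
re-estimates b and d from (coverage, time) observations by least squares on
logs; whether the cubic law should be taken in raw or log coverage is
ambiguous in the source description, so the exponent is a parameter and 3
is the default.

The partitioner computes the genome cost GC = Σ t(i), the ideal
per-interval cost AC = GC/n for n processes, and scans bins in genome
order, closing the current interval when:

* **max-weight** — its weight reaches AC. The bin that crosses AC is
  *included* (weights overshoot slightly rather than undershoot), bounding
  every interval by AC + the largest single-bin weight and avoiding
  degenerate one-bin-short intervals.
* **max-width** — adding the next bin would exceed `max_width` (default
  2 × ceil(genome/n)), which stops near-empty regions from collapsing into
  one enormous interval and keeps workers recycling;
* **single-chromosome-span** — a chromosome ends; intervals never span
  chromosomes.

AC is fixed once up front; remaining-budget rebalancing after each closure
is deliberately not applied. For tractability DIA operates on coverage bins
(default 1 000 bp, mean depth per bin from a single difference-array pass
over read spans) rather than single positions; bin cost is
width × t(mean coverage), which equals the per-position sum whenever
coverage is uniform within a bin. The plan exports/imports as BED5 with the
weight in the score column, so hand-crafted plans can drive the runner.

## Coordinator/worker protocol

A coordinator owns the interval queue. Each idle worker receives one
interval in a COMPUTE message, writes its records to
`<chrom>_<start>_<end>.tmp.tsv` in the scratch directory, and reports DONE;
the coordinator immediately reassigns it until the queue empties, then
sends every worker FINISH. Temporaries are merged in plan order under a
single header and deleted; because dispatch order and merge order are both
the plan's genomic order, the merged file is byte-identical to a serial run
regardless of worker count or completion order. A worker failure aborts the
run naming the interval and preserves the temporaries for diagnosis.

The protocol is a message contract, not a transport: the package ships a
forked-multiprocess backend (`parallel::mcparallel`) and a deterministic
in-process backend used by the protocol tests. The coordinator only
dispatches; it processes no intervals itself, so its availability to answer
DONE messages never depends on its own workload.

## The simulator's stated world

`generate_reference()` → `plant_sites()` → `simulate_alignments()` emulate
what the detector consumes: multi-chromosome references; editing sites
planted at A (plus) or T (minus) bases with per-site target frequencies;
reads whose starts are drawn proportionally to an expected-depth profile
with multiplicative hotspots; per-read CIGARs that are 85% plain matches
and ~5% each spliced (20–200 bp N gaps), small-indel (1–3 bp) and
soft-clipped (3–10 bp); per-base qualities in 30–40 with an optional
low-quality fraction below 25 (default 0, so quality filtering is exercised
only deliberately); sequencing errors at a configurable per-base rate
(default 0.001); 50/50 read orientation. Edits are planted per read,
independently with probability f — the binomial model the caller's
frequency estimator assumes. Everything is deterministic per seed.

What it does not emulate: transcript structure (reads are genomic),
PCR duplicates, mate pairs, quality–error correlation, mapping ambiguity.
A green end-to-end test therefore establishes the counting, calling,
partitioning and merging machinery — not robustness to alignment artefacts,
which the upstream aligner and the configurable filters must handle.

Two experiment-design choices deserve a note:

* **Recovery depth.** The exact-recovery experiment plants frequencies down
  to 0.15 against the caller's 0.10 threshold. The margin is 0.05, so the
  binomial standard error sqrt(f(1−f)/depth) must be well below it:
  at depth 30 it is ≈ 0.065 (misses near-certain over 500 site-draws), at
  depth 500 it is ≈ 0.016 (≈3 SE, miss probability ~10⁻³ per boundary
  site). The experiment uses depth 500 — a power calculation made before
  the tests were run, not a tuned value.
* **End margins.** Simulated coverage ramps from 0 to the target depth over
  one read length at each chromosome end. Sites for recovery experiments
  are planted ≥ 400 bp from the ends so realised coverage matches the
  nominal depth the error bound assumes.

## Numerical and formatting choices

Frequencies and mean qualities are written with two decimals (the
round-trip reader recovers them at that precision); base counts render as
`[a, c, g, t]`. Zero-coverage positions raise a distinct error in
`substitution_frequencies()` rather than yielding NaN. Records must arrive
at the writer sorted by (header chromosome order, position); the writer and
merger both verify this. All classed errors share the `redikit_error`
ancestor so callers can trap the package's failures specifically.

## Known limitations

No CRAM or remote access; no realignment, indel calling or base-quality
recalibration; no annotation/dbSNP/homopolymer filtering (candidate sites
only); fragment-level mate de-duplication absent; the fork backend requires
a Unix R with `parallel` fork support (the in-process backend is the
portable fallback).
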