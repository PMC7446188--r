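track1 <- function(costsource, bin_size = 1L, name = "chr1") {
  new_coverage_track(setNames(list(costsource), name), bin_size)
}

test_that("position_cost is the power-law floor model and is monotone", {
  expect_identical(position_cost(0, time_model(alpha = 1, b = 1, d = 3)), 1)
  expect_identical(position_cost(2, time_model(alpha = 0, b = 1, d = 3)), 8)
  expect_equal(position_cost(3, time_model(alpha = 2, b = 0.5, d = 2)), 6.5)
  set.seed(8)
  cov <- runif(1000, 0, 500)
  m <- time_model(alpha = runif(1, 0, 5), b = runif(1, 0.1, 2),
                  d = runif(1, 0.5, 4))
  expect_true(all(position_cost(cov + 1, m) >= position_cost(cov, m)))
})

test_that("total_cost sums bin width times per-position cost", {
  # all-zero track, alpha = 1: GC equals the genome length
  tr <- new_coverage_track(list(c1 = rep(0, 10), c2 = rep(0, 3)),
                           bin_size = 100L,
                           chrom_lengths = c(c1 = 1000L, c2 = 250L))
  expect_identical(total_cost(tr, time_model(alpha = 1, b = 1, d = 3)), 1250)
  # hand sum with identity cost
  expect_identical(total_cost(track1(c(1, 2, 3)),
                              time_model(alpha = 0, b = 1, d = 1)), 6)
  # random track equals direct per-position summation
  set.seed(21)
  v <- runif(57, 0, 40)
  m <- time_model(alpha = 0.5, b = 2, d = 3)
  expect_equal(total_cost(track1(v), m), sum(0.5 + 2 * v^3))
})

test_that("coverage_track matches the per-position stabbing oracle", {
  dir <- withr::local_tempdir()
  # empty BAM -> all-zero track
  sam_reads <- read_tuple("a", "chr1", 1, "5M", "AAAAA", mapq = 5L)
  h <- open_alignment(write_test_bam(sam_reads, c(chr1 = 100L), dir = dir))
  tr <- coverage_track(h, bin_size = 10L)   # the only read fails min_mapq
  expect_true(all(tr$values$chr1 == 0))
  expect_length(tr$values$chr1, 10L)

  # one full-span read at bin_size 1: depth 1 everywhere it covers
  h2 <- open_alignment(write_test_bam(
    read_tuple("b", "chr1", 1, "100M", strrep("A", 100)),
    c(chr1 = 100L), dir = withr::local_tempdir()))
  tr2 <- coverage_track(h2, bin_size = 1L)
  expect_identical(unname(tr2$values$chr1), rep(1, 100))

  fx <- make_fixture(13, depth = 9)
  tr3 <- coverage_track(fx$handle, bin_size = 1L)
  for (ch in names(fx$chrom_lengths)) {
    iv <- genomic_interval(ch, 0L, fx$chrom_lengths[[ch]])
    reads <- fetch_overlapping(fx$handle, iv)
    pass <- Filter(function(r) read_passes_filters(r, read_filters()), reads)
    starts <- vapply(pass, `[[`, integer(1), "start")
    ends <- vapply(pass, read_end, integer(1))
    want <- vapply(seq_len(fx$chrom_lengths[[ch]]) - 1L, function(g)
      sum(starts <= g & ends > g), numeric(1))
    expect_equal(unname(tr3$values[[ch]]), want)
  }
})

test_that("dynamic_intervals reproduces hand-run greedy partitions", {
  m <- time_model(alpha = 0, b = 1, d = 1)
  # uniform 100 bins of cost 1, n = 4 -> four intervals of weight 25
  p <- dynamic_intervals(track1(rep(1, 100)), 4, max_width = Inf, model = m)
  expect_identical(p$intervals$start, c(0L, 25L, 50L, 75L))
  expect_identical(p$intervals$end, c(25L, 50L, 75L, 100L))
  expect_equal(p$intervals$weight, rep(25, 4))
  expect_equal(p$ideal_cost, 25)

  # hotspot profile [1 x50, 1000, 1 x49], n = 2: AC = 549.5; the greedy
  # rule closes after the crossing bin
  p <- dynamic_intervals(track1(c(rep(1, 50), 1000, rep(1, 49))), 2,
                         max_width = Inf, model = m)
  expect_identical(p$intervals$start, c(0L, 51L))
  expect_identical(p$intervals$end, c(51L, 100L))
  expect_equal(p$intervals$weight, c(1050, 49))
  expect_equal(p$ideal_cost, 549.5)

  # two chromosomes, n = 1: at least one interval per chromosome, none
  # crossing the boundary
  tr <- new_coverage_track(list(c1 = rep(1, 10), c2 = rep(1, 5)),
                           bin_size = 1L)
  p <- dynamic_intervals(tr, 1, max_width = Inf, model = m)
  expect_gte(nrow(p$intervals), 2L)
  expect_setequal(unique(p$intervals$chrom), c("c1", "c2"))
  for (i in seq_len(nrow(p$intervals))) {
    ch <- p$intervals$chrom[i]
    expect_lte(p$intervals$end[i], tr$chrom_lengths[[ch]])
  }
  expect_error(dynamic_intervals(tr, 0), class = "redikit_bad_n")
})

test_that("plans tile the genome, respect max_width and bound overshoot", {
  set.seed(33)
  m <- time_model()
  for (k in 1:8) {
    nbin <- sample(50:200, 1)
    v <- runif(nbin, 0, 5)
    # add hotspots
    for (j in seq_len(sample(1:3, 1))) {
      i0 <- sample(nbin - 5, 1)
      v[i0:(i0 + 4)] <- v[i0:(i0 + 4)] * sample(c(10, 100), 1)
    }
    L2 <- sample(20:80, 1)
    tr <- new_coverage_track(list(cA = v, cB = runif(L2, 0, 5)),
                             bin_size = 10L)
    n <- sample(2:9, 1)
    mw <- if (k %% 2 == 0) sample(20:60, 1) * 10 else Inf
    p <- dynamic_intervals(tr, n, max_width = mw, model = m)
    iv <- p$intervals
    # tiling invariants are re-checked here independently of the
    # constructor's own validation
    for (ch in c("cA", "cB")) {
      s <- iv[iv$chrom == ch, ]
      expect_identical(s$start[1], 0L)
      expect_identical(s$end[nrow(s)], tr$chrom_lengths[[ch]])
      expect_identical(s$start[-1], s$end[-nrow(s)])
    }
    expect_true(all(iv$end - iv$start <= mw))
    # greedy overshoot bound: no interval exceeds AC + max single-bin weight
    maxbin <- max(c(redikit::position_cost(v, m) * 10,
                    position_cost(tr$values$cB, m) * 10))
    expect_true(all(iv$weight <= p$ideal_cost + maxbin + 1e-9))
    # weights sum to GC and match an independent evaluation
    expect_equal(sum(iv$weight), p$total_cost)
    expect_equal(iv$weight, plan_weights(iv, tr, m))
    expect_gte(nrow(iv), min(n, 2L))
  }
})

test_that("uniform cost with finite max_width reduces to ceil tiling", {
  m <- time_model(alpha = 1, b = 1, d = 1)
  tr <- track1(rep(0, 100), bin_size = 10L)   # 1000 bp, uniform cost
  p <- dynamic_intervals(tr, 1, max_width = 300, model = m)
  expect_identical(p$intervals$end - p$intervals$start,
                   c(300L, 300L, 300L, 100L))
})

test_that("naive_intervals uses the ceil rule and is less balanced on hotspots", {
  p <- naive_intervals(c(chr1 = 100L), 4)
  expect_identical(p$intervals$end - p$intervals$start, rep(25L, 4))
  p <- naive_intervals(c(chr1 = 10L), 3)
  expect_identical(p$intervals$end - p$intervals$start, c(4L, 4L, 2L))

  m <- time_model()
  v <- c(rep(1, 40), rep(50, 5), rep(1, 55))   # hotspot track
  tr <- track1(v, bin_size = 10L)
  dia <- dynamic_intervals(tr, 5, max_width = Inf, model = m)
  nv <- naive_intervals(tr$chrom_lengths, 5, track = tr, model = m)
  ratio <- function(p) max(p$intervals$weight) / mean(p$intervals$weight)
  expect_lte(ratio(dia), ratio(nv))
  expect_gte(max(nv$intervals$weight), max(dia$intervals$weight))
})

test_that("fit_time_model recovers power-law exponents", {
  # noiseless cubic: exact within numerical tolerance
  x <- 1:10
  m <- fit_time_model(data.frame(cov = x, time = x^3))
  expect_equal(m$d, 3, tolerance = 1e-9)
  expect_equal(m$b, 1, tolerance = 1e-9)
  # two points interpolate exactly
  m <- fit_time_model(data.frame(cov = c(1, 2), time = c(1, 8)))
  expect_equal(m$d, 3, tolerance = 1e-12)
  expect_equal(m$b, 1, tolerance = 1e-12)
  # zero-coverage observations set the floor
  m <- fit_time_model(data.frame(cov = c(0, 0, 1, 2), time = c(2, 4, 1, 8)))
  expect_equal(m$alpha, 3)
  # lognormal noise around y = 2 x^3
  set.seed(1234)
  x <- exp(runif(1000, 0, 5))
  y <- 2 * x^3 * exp(rnorm(1000, 0, 0.1))
  m <- fit_time_model(data.frame(cov = x, time = y))
  expect_gt(m$d, 2.8); expect_lt(m$d, 3.2)
  expect_error(fit_time_model(data.frame(cov = c(2, 2, 2),
                                         time = c(8, 8, 8))),
               class = "redikit_degenerate_fit")
})

test_that("interval plans round-trip through BED", {
  dir <- withr::local_tempdir()
  tr <- new_coverage_track(list(c1 = runif(20, 0, 3), c2 = runif(10, 0, 3)),
                           bin_size = 50L)
  p <- dynamic_intervals(tr, 3)
  bed <- file.path(dir, "plan.bed")
  write_plan_bed(p, bed)
  back <- read_plan_bed(bed, tr$chrom_lengths)
  expect_identical(back$intervals[, c("chrom", "start", "end")],
                   p$intervals[, c("chrom", "start", "end")])
  expect_equal(back$intervals$weight, p$intervals$weight, tolerance = 1e-5)
  # a plan that fails to tile is rejected
  writeLines("c1\t0\t500", bed)
  expect_error(read_plan_bed(bed, tr$chrom_lengths),
               class = "redikit_bad_plan")
})
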