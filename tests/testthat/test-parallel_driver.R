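test_that("run_serial output is independent of how the genome is cut", {
  fx <- make_fixture(41, n_sites = 6, depth = 40, freq_range = c(0.3, 1),
                     error_rate = 0, low_q_frac = 0, margin = 60L)
  dir <- withr::local_tempdir()
  cfg <- run_config(scratch = file.path(dir, "s"))
  whole <- lapply(names(fx$chrom_lengths), function(ch)
    genomic_interval(ch, 0L, fx$chrom_lengths[[ch]]))
  o1 <- file.path(dir, "one.tsv")
  run_serial(fx$bam, fx$fasta, whole, cfg, out = o1)
  fine <- naive_intervals(fx$chrom_lengths, 10)
  o2 <- file.path(dir, "ten.tsv")
  run_serial(fx$bam, fx$fasta, fine, cfg, out = o2)
  expect_identical(readLines(o1), readLines(o2))

  # zero-error run recovers exactly the planted sites
  got <- read_site_table(o1)
  expect_identical(nrow(got), nrow(fx$truth))
  expect_identical(got$position, fx$truth$pos + 1L)
  expect_identical(got$all_subs,
                   ifelse(fx$truth$strand == "+", "AG", "TC"))
})

test_that("run_serial on an empty BAM writes a header-only file", {
  dir <- withr::local_tempdir()
  bam <- write_test_bam(read_tuple("a", "chr1", 1, "5M", "AAAAA",
                                   mapq = 0L),
                        c(chr1 = 400L), dir = dir)
  fa <- file.path(dir, "ref.fa")
  generate_reference(c(chr1 = 400L), seed = 3, path = fa)
  out <- file.path(dir, "o.tsv")
  res <- run_serial(bam, fa, list(genomic_interval("chr1", 0L, 400L)),
                    run_config(), out = out)
  expect_identical(res$n_records, 0L)
  expect_identical(length(readLines(out)), 1L)
})

test_that("parallel runs are byte-identical to serial for all worker counts and plans", {
  fx <- make_fixture(43, n_sites = 8, depth = 20,
                     chrom_lengths = c(chrA = 2000L, chrB = 1200L))
  dir <- withr::local_tempdir()
  serial_out <- file.path(dir, "serial.tsv")
  run_serial(fx$bam, fx$fasta,
             naive_intervals(fx$chrom_lengths, 7),
             run_config(), out = serial_out)
  serial_lines <- readLines(serial_out)

  track <- coverage_track(fx$handle, bin_size = 200L)
  plans <- list(naive = naive_intervals(fx$chrom_lengths, 7),
                dia = dynamic_intervals(track, 7))
  k <- 0L
  for (pname in names(plans)) {
    for (w in c(1L, 3L)) {
      for (backend in c("inprocess", "fork")) {
        k <- k + 1L
        out <- file.path(dir, sprintf("par%d.tsv", k))
        cfg <- run_config(workers = w, backend = backend,
                          scratch = file.path(dir, sprintf("scr%d", k)))
        res <- run_parallel(fx$bam, fx$fasta, plans[[pname]], cfg, out = out)
        expect_identical(readLines(out), serial_lines,
                         label = sprintf("%s plan, %d workers, %s backend",
                                         pname, w, backend))
        # temporaries removed on success
        expect_length(list.files(cfg$scratch, pattern = "tmp\\.tsv$"), 0)
        tr <- schedule_trace(res)
        n_iv <- nrow(plans[[pname]]$intervals)
        expect_identical(sum(tr$kind == "COMPUTE"), n_iv)
        expect_identical(sum(tr$kind == "DONE"), n_iv)
        expect_identical(sum(tr$kind == "FINISH"), w)
      }
    }
  }
})

test_that("the message protocol dispatches, recycles and terminates correctly", {
  fx <- make_fixture(47, n_sites = 0, depth = 5,
                     chrom_lengths = c(chrA = 600L))
  dir <- withr::local_tempdir()

  # 2 intervals, 1 worker: COMPUTE DONE COMPUTE DONE FINISH
  cfg <- run_config(workers = 1L, backend = "inprocess",
                    scratch = file.path(dir, "s1"))
  res <- run_parallel(fx$bam, fx$fasta,
                      naive_intervals(c(chrA = 600L), 2), cfg,
                      out = file.path(dir, "a.tsv"))
  tr <- schedule_trace(res)
  expect_identical(tr$kind, c("COMPUTE", "DONE", "COMPUTE", "DONE", "FINISH"))
  expect_identical(tr$worker, rep(1L, 5))

  # 0 intervals, k workers: k FINISH messages and a header-only output
  cfg <- run_config(workers = 4L, backend = "inprocess",
                    scratch = file.path(dir, "s2"))
  res <- run_parallel(fx$bam, fx$fasta, list(), cfg,
                      out = file.path(dir, "b.tsv"))
  tr <- schedule_trace(res)
  expect_identical(tr$kind, rep("FINISH", 4))
  expect_identical(length(readLines(file.path(dir, "b.tsv"))), 1L)

  # workers >= intervals: nobody gets a second COMPUTE before a DONE;
  # each interval COMPUTEd exactly once
  cfg <- run_config(workers = 5L, backend = "inprocess",
                    scratch = file.path(dir, "s3"))
  plan <- naive_intervals(c(chrA = 600L), 3)
  res <- run_parallel(fx$bam, fx$fasta, plan, cfg,
                      out = file.path(dir, "c.tsv"))
  tr <- schedule_trace(res)
  comp <- tr[tr$kind == "COMPUTE", ]
  expect_identical(nrow(comp), 3L)
  expect_identical(anyDuplicated(comp$worker), 0L)
  expect_identical(anyDuplicated(comp[, c("chrom", "start", "end")]), 0L)

  # more intervals than workers: pigeonhole forces recycling
  cfg <- run_config(workers = 2L, backend = "inprocess",
                    scratch = file.path(dir, "s4"))
  res <- run_parallel(fx$bam, fx$fasta,
                      naive_intervals(c(chrA = 600L), 6), cfg,
                      out = file.path(dir, "d.tsv"))
  comp <- schedule_trace(res)
  comp <- comp[comp$kind == "COMPUTE", ]
  expect_gte(max(table(comp$worker)), 2L)
})

test_that("protocol conservation holds across randomized runs", {
  fx <- make_fixture(53, n_sites = 3, depth = 8,
                     chrom_lengths = c(chrA = 900L, chrB = 500L))
  dir <- withr::local_tempdir()
  set.seed(7)
  for (k in 1:6) {
    w <- sample(1:6, 1)
    n <- sample(1:9, 1)
    cfg <- run_config(workers = w, backend = "inprocess",
                      scratch = file.path(dir, sprintf("s%d", k)))
    plan <- naive_intervals(fx$chrom_lengths, n)
    res <- run_parallel(fx$bam, fx$fasta, plan, cfg,
                        out = file.path(dir, sprintf("o%d.tsv", k)))
    tr <- schedule_trace(res)
    n_iv <- nrow(plan$intervals)
    expect_identical(sum(tr$kind == "COMPUTE"), n_iv)
    expect_identical(sum(tr$kind == "DONE"), n_iv)
    expect_identical(sum(tr$kind == "FINISH"), w)
    comp <- tr[tr$kind == "COMPUTE", c("chrom", "start", "end")]
    expect_identical(anyDuplicated(comp), 0L)
  }
})

test_that("a failing worker aborts with the interval named and keeps temps", {
  fx <- make_fixture(59, n_sites = 2, depth = 20,
                     chrom_lengths = c(chrA = 800L, chrB = 800L),
                     freq_range = c(0.5, 1), error_rate = 0, margin = 80L)
  dir <- withr::local_tempdir()
  # a reference FASTA lacking chrB makes any chrB interval fail
  short_fa <- file.path(dir, "short.fa")
  dna <- Biostrings::readDNAStringSet(fx$fasta)
  Biostrings::writeXStringSet(dna["chrA"], short_fa)
  Rsamtools::indexFa(short_fa)
  for (backend in c("inprocess", "fork")) {
    cfg <- run_config(workers = 2L, backend = backend,
                      scratch = file.path(dir, paste0("s_", backend)))
    err <- tryCatch(
      run_parallel(fx$bam, short_fa, naive_intervals(fx$chrom_lengths, 4),
                   cfg, out = file.path(dir, "x.tsv")),
      error = function(e) e)
    expect_s3_class(err, "error")
    expect_match(conditionMessage(err), "chrB")
    # chrA temporaries survive for diagnosis
    expect_gt(length(list.files(cfg$scratch, pattern = "tmp\\.tsv$")), 0)
  }
})

test_that("the CLI drives simulate and serial detection end to end", {
  dir <- withr::local_tempdir()
  simdir <- file.path(dir, "fx")
  expect_identical(redikit_main(c("simulate", "--chroms", "1x3000",
                                  "--depth", "25", "--sites", "4",
                                  "--freq", "0.5:1.0", "--error", "0",
                                  "--seed", "5", "--read-length", "60",
                                  "-o", simdir)),
                   0L)
  expect_true(file.exists(file.path(simdir, "reads.bam")))
  out <- file.path(dir, "cli.tsv")
  suppressMessages(
    redikit_main(c("serial", "-f", file.path(simdir, "reads.bam"),
                   "-r", file.path(simdir, "reference.fa"),
                   "-o", out, "-q", "25", "-c", "10")))
  truth <- read_truth_table(file.path(simdir, "truth.tsv"))
  got <- read_site_table(out)
  expect_identical(got$position, truth$pos + 1L)
  expect_error(redikit_main(c("bogus")), class = "redikit_cli_error")
})
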