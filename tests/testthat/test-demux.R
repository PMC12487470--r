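test_that("zero-error synthetic reads are fully recovered and reconstructible", {
  sim <- simulate_reads(sim_params(n_reads = 48, seed = 3))
  out <- withr::local_tempdir()
  run <- quiet_demux(sim$reads, "builtin24", demux_config(), out)

  # partition: every read in exactly one routing class
  expect_equal(sum(run$summary$n_reads), nrow(sim$reads))
  expect_equal(sum(run$summary$fraction), 1, tolerance = 1e-9)
  expect_true(all(run$ledger$status == "assigned"))
  expect_equal(run$ledger$barcode_id, sim$truth$true_barcode)

  # trimming conservation: prefix + trimmed reconstructs the original
  tr <- read_fastq(file.path(out, "BC01.trimmed.fastq.gz"))
  qc <- read_fastq(file.path(out, "BC01.untrimmed.fastq.gz"))
  orig <- sim$reads[sim$truth$true_barcode == "BC01", ]
  expect_equal(qc$sequence, orig$sequence)
  led <- run$ledger[run$ledger$barcode_id == "BC01", ]
  expect_equal(paste0(substr(orig$sequence, 1, led$cut), tr$sequence),
               orig$sequence)
  expect_equal(paste0(substr(orig$quality, 1, led$cut), tr$quality),
               orig$quality)
  # barcode ends at 70, no adapter tail: trimmed read is flank + insert
  expect_equal(unique(led$cut), 70L)
  expect_true(all(startsWith(tr$sequence, sim_flank())))

  # summary table round-trips
  s <- read.delim(file.path(out, "summary.tsv"))
  expect_equal(s$label, run$summary$label)
  expect_equal(s$n_reads, run$summary$n_reads)
  # constant Phred 12 qualities give mean quality 12
  expect_equal(run$summary$mean_quality[run$summary$label == "BC01"], 12)
})

test_that("length filter splits exactly at the 550-nt boundary before alignment", {
  bc <- load_barcode_set("builtin24")
  set.seed(53)
  reads <- make_reads(c(make_barcoded_read(bc$sequence[1], 46L, 549L),
                        make_barcoded_read(bc$sequence[2], 46L, 550L)),
                      ids = c("short549", "ok550"))
  run <- quiet_demux(reads, bc, demux_config())
  expect_equal(run$ledger$status, c("too_short", "assigned"))
  expect_equal(run$ledger$reject_reason[1], "read_too_short")
  # the too-short read never reached the aligner: no alignment evidence
  expect_true(is.na(run$ledger$score[1]))
  expect_equal(run$summary$n_reads[run$summary$label == "too_short"], 1L)
})

test_that("unclassified and too-short reads are written untouched", {
  bc <- load_barcode_set("builtin24")
  set.seed(59)
  reads <- make_reads(c(random_seq(600), random_seq(100)),
                      ids = c("noise600", "tiny100"))
  out <- withr::local_tempdir()
  run <- quiet_demux(reads, bc, demux_config(), out)
  expect_equal(sum(run$summary$n_reads), 2L)
  if (run$ledger$status[1] == "unclassified") {
    u <- read_fastq(file.path(out, "unclassified.fastq.gz"))
    expect_equal(u$sequence, reads$sequence[1])
  }
  ts <- read_fastq(file.path(out, "too_short.fastq.gz"))
  expect_equal(ts$read_id, "tiny100")
  expect_equal(ts$sequence, reads$sequence[2])
})

test_that("outputs are byte-identical across runs and thread counts", {
  sim <- simulate_reads(sim_params(n_reads = 60, p_sub = 0.05, p_ins = 0.03,
                                   p_del = 0.03, seed = 61))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d4 <- withr::local_tempdir()
  r1 <- quiet_demux(sim$reads, "builtin24", demux_config(threads = 1L), d1)
  r2 <- quiet_demux(sim$reads, "builtin24", demux_config(threads = 1L), d2)
  r4 <- quiet_demux(sim$reads, "builtin24", demux_config(threads = 4L), d4)
  expect_identical(dir_md5(d1), dir_md5(d2))
  expect_identical(dir_md5(d1), dir_md5(d4))
  expect_identical(r1$ledger, r4$ledger)
})

test_that("decisions are invariant to barcode set order", {
  bc <- load_barcode_set("builtin24")
  sim <- simulate_reads(sim_params(n_reads = 60, p_sub = 0.08, p_ins = 0.04,
                                   p_del = 0.04, seed = 67))
  r1 <- quiet_demux(sim$reads, bc, demux_config())
  r2 <- quiet_demux(sim$reads, bc[rev(seq_len(24)), ], demux_config())
  expect_equal(r1$ledger$status, r2$ledger$status)
  expect_equal(r1$ledger$barcode_id, r2$ledger$barcode_id)
  expect_equal(r1$ledger$reject_reason, r2$ledger$reject_reason)
})

test_that("trim_read cuts after the barcode and keeps the full QC record", {
  read <- make_reads("AAACCCGGGTTT", ids = "r1")
  tr <- trim_read(read, read_end = 6L)
  expect_equal(tr$trimmed$sequence, "GGGTTT")
  expect_equal(tr$qc$sequence, read$sequence)
  expect_equal(paste0(substr(read$sequence, 1, 6), tr$trimmed$sequence),
               read$sequence)
  tr <- trim_read(read, read_end = 6L, adapter_tail = 3L)
  expect_equal(tr$trimmed$sequence, "TTT")
  # cut at or past the read end leaves an empty trimmed record
  tr <- trim_read(read, read_end = 12L)
  expect_equal(tr$trimmed$sequence, "")
  expect_equal(tr$qc$sequence, read$sequence)
})

test_that("adapter_tail and qc_full_read options shape the outputs", {
  sim <- simulate_reads(sim_params(n_reads = 24, seed = 71))
  out <- withr::local_tempdir()
  cfg <- demux_config(adapter_tail = 30L, qc_full_read = FALSE)
  run <- quiet_demux(sim$reads, "builtin24", cfg, out)
  led <- run$ledger[run$ledger$barcode_id == "BC01", ]
  expect_equal(led$cut, 100L)  # 46 leader + 24 barcode + 30 flank
  tr <- read_fastq(file.path(out, "BC01.trimmed.fastq.gz"))
  orig <- sim$reads[sim$truth$true_barcode == "BC01", ]
  expect_equal(tr$sequence, substring(orig$sequence, 101L))
  qc <- read_fastq(file.path(out, "BC01.untrimmed.fastq.gz"))
  expect_equal(qc$sequence, substr(orig$sequence, 1L, 100L))
})

test_that("degenerate inputs give well-defined summaries and errors", {
  empty <- make_reads(character(0))
  run <- quiet_demux(empty, "builtin24", demux_config())
  expect_equal(sum(run$summary$n_reads), 0L)
  expect_true(all(run$summary$fraction == 0))
  expect_equal(nrow(run$summary), 26L)  # 24 barcodes + unclassified + too_short

  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(quiet_demux(empty, f, demux_config()), "no records")
})
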