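aln_row <- function(barcode_id, score, read_start,
                    read_end = read_start + 23L) {
  data.frame(barcode_id = barcode_id, score = as.integer(score),
             read_start = as.integer(read_start),
             read_end = as.integer(read_end), stringsAsFactors = FALSE)
}

test_that("window_for_score implements the default score-tiered map", {
  map <- window_map()
  expect_equal(window_for_score(13, map), c(36L, 51L))
  expect_equal(window_for_score(14, map), c(30L, 75L))
  expect_equal(window_for_score(15, map), c(5L, 85L))
  expect_equal(window_for_score(20, map), c(5L, 85L))
  expect_null(window_for_score(12, map))
})

test_that("window map text form parses to the default map", {
  map <- parse_window_map("13:36:51,14:30:75,15:5:85")
  expect_equal(map$tiers, window_map()$tiers)
  expect_equal(map$min_score_floor, 13L)
  expect_error(parse_window_map("13:36"), "min_score:start:end")
})

test_that("positional filter accepts and rejects exactly at the tier boundaries", {
  cases <- rbind(
    c(13, 35, FALSE), c(13, 36, TRUE), c(13, 51, TRUE), c(13, 52, FALSE),
    c(14, 30, TRUE), c(14, 76, FALSE), c(15, 5, TRUE), c(15, 85, TRUE))
  for (k in seq_len(nrow(cases))) {
    d <- decide(aln_row("BC01", cases[k, 1], cases[k, 2]))
    expect_equal(d$status == "assigned", as.logical(cases[k, 3]),
                 info = paste(cases[k, 1], cases[k, 2]))
    if (!cases[k, 3]) expect_equal(d$reject_reason, "outside_window")
  }
})

test_that("margin rule requires the winner to lead by at least 2", {
  two <- rbind(aln_row("BC01", 16, 40), aln_row("BC02", 15, 60))
  d <- decide(two)
  expect_equal(d$status, "unclassified")
  expect_equal(d$reject_reason, "margin_too_small")
  expect_equal(d$runner_up_score, 15L)

  d <- decide(rbind(aln_row("BC01", 16, 40), aln_row("BC02", 14, 60)))
  expect_equal(d$status, "assigned")  # difference of exactly 2 passes
  expect_equal(d$barcode_id, "BC01")

  d <- decide(rbind(aln_row("BC01", 16, 40), aln_row("BC02", 10, 60)))
  expect_equal(d$status, "assigned")
  expect_equal(d$runner_up_score, 10L)

  # equal best scores of distinct barcodes are never assigned
  d <- decide(rbind(aln_row("BC01", 16, 40), aln_row("BC02", 16, 41)))
  expect_equal(d$status, "unclassified")
  expect_equal(d$reject_reason, "margin_too_small")
})

test_that("a barcode does not compete with itself in the margin rule", {
  a <- rbind(aln_row("BC01", 16, 40), aln_row("BC01", 15, 80),
             aln_row("BC02", 10, 60))
  d <- decide(a)
  expect_equal(d$status, "assigned")
  expect_equal(d$barcode_id, "BC01")
  expect_equal(d$runner_up_score, 10L)
})

test_that("score floor and empty candidate lists are rejected with reasons", {
  d <- decide(aln_row("BC01", 12, 40))
  expect_equal(d$reject_reason, "below_min_score")
  d <- decide(aln_row("BC01", 13, 40))
  expect_equal(d$status, "assigned")
  d <- decide(aln_row("BC01", 13, 35))
  expect_equal(d$reject_reason, "outside_window")
  d <- decide(aln_row("BC01", 13, 36))
  expect_equal(d$status, "assigned")
  d <- decide(aln_row("x", 5, 1)[0, ])
  expect_equal(d$reject_reason, "no_alignment")
})

test_that("decisions are invariant to barcode input order", {
  set.seed(31)
  for (case in seq_len(40)) {
    n <- sample(1:6, 1)
    a <- aln_row(sample(sprintf("BC%02d", 1:10), n),
                 sample(8:20, n, replace = TRUE),
                 sample(1:100, n, replace = TRUE))
    d1 <- decide(a)
    d2 <- decide(a[sample(n), , drop = FALSE])
    expect_equal(d1$status, d2$status)
    expect_equal(d1$barcode_id, d2$barcode_id)
    expect_equal(d1$reject_reason, d2$reject_reason)
    expect_equal(d1$runner_up_score, d2$runner_up_score)
  }
})

test_that("rank-then-filter is the default; prefilter variant rescues in-window runners-up", {
  # winner outside every window, runner-up inside its tier window
  a <- rbind(aln_row("BC01", 16, 100), aln_row("BC02", 13, 40))
  d <- decide(a)
  expect_equal(d$status, "unclassified")
  expect_equal(d$reject_reason, "outside_window")
  d2 <- decide(a, prefilter_window = TRUE)
  expect_equal(d2$status, "assigned")
  expect_equal(d2$barcode_id, "BC02")
})

test_that("scan_read clamps to short reads and finds embedded barcodes", {
  bc <- load_barcode_set("builtin24")
  set.seed(37)
  short <- substr(bc$sequence[3], 3, 20)  # 18-nt read, shorter than window
  hits <- scan_read(short, bc)
  expect_true("BC03" %in% hits$barcode_id)
  expect_equal(max(hits$score), 18L)

  target <- make_barcoded_read(bc$sequence[1], 46L, 400L)
  hits <- scan_read(target, bc)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$barcode_id, "BC01")
  expect_equal(top$score, 24L)
  expect_equal(top$read_start, 47L)

  # adversarial read: no A/C/G barcode content
  poly <- strrep("T", 200)
  hits <- scan_read(poly, bc)
  expect_true(nrow(hits) == 0L || all(hits$score < 13L))
})

test_that("reverse-complement scanning finds flipped barcodes when enabled", {
  bc <- load_barcode_set("builtin24")
  set.seed(41)
  target <- make_barcoded_read(reverse_complement(bc$sequence[5]), 46L, 300L)
  fwd <- scan_read(target, bc)
  expect_false(any(fwd$barcode_id == "BC05" & fwd$score >= 13L))
  both <- scan_read(target, bc, scan_revcomp = TRUE)
  hit <- both[both$barcode_id == "BC05", ]
  expect_equal(hit$score, 24L)
  expect_equal(hit$orient, "-")
  expect_equal(hit$read_start, 47L)
})

test_that("vectorized classification matches per-read scan_read + decide", {
  bc <- load_barcode_set("builtin24")
  cfg <- demux_config()
  set.seed(43)
  sim <- simulate_reads(sim_params(n_reads = 40, p_sub = 0.05, p_ins = 0.03,
                                   p_del = 0.03, seed = 43))
  neg <- simulate_negative(40, 300, seed = 44)
  seqs <- c(sim$reads$sequence, neg$reads$sequence)
  batch <- classify_reads(seqs, bc, cfg)
  for (i in seq_along(seqs)) {
    a <- scan_read(seqs[i], bc, cfg$scheme, cfg$scan_window)
    d <- decide(a, cfg$map, cfg$margin)
    expect_equal(batch$status[i], d$status, info = i)
    expect_equal(batch$reject_reason[i], d$reject_reason, info = i)
    if (d$status == "assigned") {
      expect_equal(batch$barcode_id[i], d$barcode_id, info = i)
      expect_equal(batch$score[i], d$best$score, info = i)
      expect_equal(batch$read_start[i], d$best$read_start, info = i)
    }
  }
})

test_that("every unclassified decision carries exactly one machine-readable reason", {
  set.seed(47)
  neg <- simulate_negative(300, 400, seed = 47)
  cls <- classify_reads(neg$reads$sequence, "builtin24", demux_config())
  uncl <- cls$status == "unclassified"
  expect_true(all(cls$reject_reason[uncl] %in%
    c("no_alignment", "below_min_score", "margin_too_small",
      "outside_window")))
  expect_true(all(cls$reject_reason[!uncl] == "none"))
  expect_equal(sum(table(cls$reject_reason[uncl])), sum(uncl))
})

test_that("scan window shorter than the longest barcode is a configuration error", {
  expect_error(classify_reads("ACGT", "builtin24",
                              demux_config(scan_window = 10L)),
               "scan_window")
})
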