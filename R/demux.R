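#' Demultiplexing configuration
#'
#' All tunable parameters of the pipeline with their defaults: scan the
#' first 110 nt of each read, require a winning score of at least 13 and a
#' margin of 2 over the runner-up, discard reads shorter than 550 nt before
#' any alignment, and apply the default score-tiered positional window map.
#'
#' @param scan_window Read prefix length scanned, nt (default 110; must be at
#'   least as long as the longest barcode).
#' @param min_score Lower score cutoff; overrides the map's floor.
#' @param margin Minimum winner-vs-runner-up score difference (default 2).
#' @param min_length Minimum raw read length, nt (default 550); shorter reads
#'   are routed to the too-short output before any alignment.
#' @param map A [window_map()].
#' @param scheme A [scoring_scheme()].
#' @param adapter_tail Bases trimmed beyond the barcode end (default 0).
#' @param threads Worker processes for classification (default 1). Outputs
#'   are identical for any thread count.
#' @param scan_revcomp Also scan reverse-complemented barcodes.
#' @param prefilter_window Apply floor and positional filter before ranking
#'   instead of after (default FALSE: rank, margin, then filter the winner).
#' @param qc_full_read If `TRUE` (default) the per-barcode QC file holds the
#'   full untrimmed read; if `FALSE`, only the clipped prefix up to the cut
#'   point (barcode plus any adapter tail).
#' @return An object of class `demux_config`.
#' @export
demux_config <- function(scan_window = 110L, min_score = 13L, margin = 2L,
                         min_length = 550L, map = window_map(),
                         scheme = scoring_scheme(), adapter_tail = 0L,
                         threads = 1L, scan_revcomp = FALSE,
                         prefilter_window = FALSE, qc_full_read = TRUE) {
  stopifnot(inherits(map, "window_map"), inherits(scheme, "scoring_scheme"),
            scan_window >= 1L, margin >= 0L, min_length >= 0L,
            adapter_tail >= 0L, threads >= 1L)
  map$min_score_floor <- as.integer(min_score)
  structure(list(scan_window = as.integer(scan_window),
                 margin = as.integer(margin),
                 min_length = as.integer(min_length),
                 map = map, scheme = scheme,
                 adapter_tail = as.integer(adapter_tail),
                 threads = as.integer(threads),
                 scan_revcomp = isTRUE(scan_revcomp),
                 prefilter_window = isTRUE(prefilter_window),
                 qc_full_read = isTRUE(qc_full_read)),
            class = "demux_config")
}

#' @export
print.demux_config <- function(x, ...) {
  cat(sprintf(paste0("demux config: scan window %d nt, score floor %d, ",
                     "margin %d, min length %d nt, adapter tail %d, ",
                     "threads %d%s\n"),
              x$scan_window, x$map$min_score_floor, x$margin, x$min_length,
              x$adapter_tail, x$threads,
              if (x$scan_revcomp) ", revcomp scan" else ""))
  print(x$scheme)
  print(x$map)
  invisible(x)
}

#' Trim an assigned read after its barcode
#'
#' The cut point is the winning alignment's `read_end` plus `adapter_tail`,
#' clamped to the read length. The trimmed record is the suffix after the
#' cut with matching qualities; the QC record is the full original read, so
#' prefix-to-cut plus trimmed sequence reconstructs the original exactly.
#'
#' @param read One-row `data.frame` (columns of [read_fastq()]).
#' @param read_end Last read position of the winning barcode alignment.
#' @param adapter_tail Extra bases removed after the barcode (default 0).
#' @return `list(trimmed = , qc = )` of one-row read `data.frame`s.
#' @export
trim_read <- function(read, read_end, adapter_tail = 0L) {
  stopifnot(is.data.frame(read), nrow(read) == 1L, read_end >= 1L)
  len <- nchar(read$sequence)
  cut <- min(read_end + adapter_tail, len)
  trimmed <- read
  trimmed$sequence <- substring(read$sequence, cut + 1L)
  trimmed$quality <- substring(read$quality, cut + 1L)
  list(trimmed = trimmed, qc = read)
}

#' Demultiplex reads into per-barcode FASTQ outputs
#'
#' Streams reads from a FASTQ file or directory, routes reads shorter than
#' `min_length` to the too-short output before any alignment, classifies the
#' rest ([classify_reads()]), trims assigned reads after the barcode, and
#' writes per-barcode trimmed (`<id>.trimmed.fastq.gz`) and QC
#' (`<id>.untrimmed.fastq.gz`) files plus `unclassified.fastq.gz`,
#' `too_short.fastq.gz` and `summary.tsv` into `out_dir`. Every input read is
#' written to exactly one routing class. Outputs are deterministic:
#' byte-identical across runs and thread counts.
#'
#' @param input FASTQ(.gz) file or directory, or a reads `data.frame` from
#'   [read_fastq()] / [simulate_reads()].
#' @param barcodes Barcode set (FASTA path, builtin name, or `data.frame`).
#' @param config A [demux_config()].
#' @param out_dir Output directory, created if needed; `NULL` skips all file
#'   output and only returns the in-memory result.
#' @return An object of class `demux_run`: `summary` (one row per barcode
#'   plus `unclassified` and `too_short`), `ledger` (per-read routing with
#'   evidence), `config`, `n_trim_warnings` (assigned reads whose cut point
#'   reached the read end), `out_dir`.
#' @examples
#' sim <- simulate_reads(sim_params(n_reads = 24, seed = 1))
#' run <- demux(sim$reads, "builtin24")
#' head(run$summary)
#' @export
demux <- function(input, barcodes, config = demux_config(), out_dir = NULL) {
  bc <- as_barcode_set(barcodes)
  check_scan_window(config, bc)
  reads <- if (is.data.frame(input)) input else read_fastq(input)
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  n <- nrow(reads)
  len <- nchar(reads$sequence)

  ledger <- data.frame(read_id = reads$read_id,
                       source = if ("source" %in% names(reads))
                         reads$source else NA_character_,
                       length = len,
                       status = rep("too_short", n),
                       barcode_id = rep(NA_character_, n),
                       score = rep(NA_integer_, n),
                       read_start = rep(NA_integer_, n),
                       read_end = rep(NA_integer_, n),
                       runner_up_score = rep(NA_integer_, n),
                       reject_reason = rep("read_too_short", n),
                       cut = rep(NA_integer_, n),
                       stringsAsFactors = FALSE)

  keep <- which(len >= config$min_length)
  if (length(keep)) {
    cls <- classify_chunked(reads$sequence[keep], bc, config)
    ledger$status[keep] <- cls$status
    ledger$barcode_id[keep] <- cls$barcode_id
    ledger$score[keep] <- cls$score
    ledger$read_start[keep] <- cls$read_start
    ledger$read_end[keep] <- cls$read_end
    ledger$runner_up_score[keep] <- cls$runner_up_score
    ledger$reject_reason[keep] <- cls$reject_reason
  }
  assigned <- ledger$status == "assigned"
  ledger$cut[assigned] <- pmin(ledger$read_end[assigned] + config$adapter_tail,
                               len[assigned])
  n_trim_warn <- sum(assigned & ledger$cut >= len, na.rm = TRUE)

  trimmed_seq <- trimmed_qual <- rep(NA_character_, n)
  trimmed_seq[assigned] <- substring(reads$sequence[assigned],
                                     ledger$cut[assigned] + 1L)
  trimmed_qual[assigned] <- substring(reads$quality[assigned],
                                      ledger$cut[assigned] + 1L)

  summary <- summarize_routing(ledger, reads, trimmed_seq, trimmed_qual, bc)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    sub <- function(i) reads[i, , drop = FALSE]
    for (b in bc$barcode_id) {
      i <- which(assigned & ledger$barcode_id == b)
      tr <- sub(i)
      tr$sequence <- trimmed_seq[i]
      tr$quality <- trimmed_qual[i]
      write_fastq(tr, file.path(out_dir, paste0(b, ".trimmed.fastq.gz")))
      qc <- sub(i)
      if (!config$qc_full_read) {
        qc$sequence <- substring(qc$sequence, 1L, ledger$cut[i])
        qc$quality <- substring(qc$quality, 1L, ledger$cut[i])
      }
      write_fastq(qc, file.path(out_dir, paste0(b, ".untrimmed.fastq.gz")))
    }
    write_fastq(sub(which(ledger$status == "unclassified")),
                file.path(out_dir, "unclassified.fastq.gz"))
    write_fastq(sub(which(ledger$status == "too_short")),
                file.path(out_dir, "too_short.fastq.gz"))
    write.table(summary, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  counts <- table(factor(ledger$status,
                         c("assigned", "unclassified", "too_short")))
  message(sprintf("demux: %d reads -> %d assigned, %d unclassified, %d too short",
                  n, counts[["assigned"]], counts[["unclassified"]],
                  counts[["too_short"]]))
  structure(list(summary = summary, ledger = ledger, config = config,
                 barcodes = bc, n_trim_warnings = n_trim_warn,
                 out_dir = out_dir),
            class = "demux_run")
}

# Chunked (optionally parallel) classification; chunk order is restored so
# results are independent of the worker count.
classify_chunked <- function(sequences, bc, config, chunk_size = 20000L) {
  n <- length(sequences)
  if (n == 0L) return(classify_reads(character(0), bc, config))
  starts <- seq.int(1L, n, by = chunk_size)
  chunks <- lapply(starts, function(s)
    sequences[s:min(s + chunk_size - 1L, n)])
  worker <- function(ch) classify_reads(ch, bc, config)
  res <- if (config$threads > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(chunks, worker, mc.cores = config$threads,
                       mc.preschedule = TRUE)
  else lapply(chunks, worker)
  do.call(rbind, res)
}

summarize_routing <- function(ledger, reads, trimmed_seq, trimmed_qual, bc) {
  n_total <- nrow(ledger)
  labels <- c(bc$barcode_id, "unclassified", "too_short")
  rows <- lapply(labels, function(lab) {
    if (lab %in% c("unclassified", "too_short")) {
      i <- which(ledger$status == lab)
      seqs <- reads$sequence[i]; quals <- reads$quality[i]
    } else {
      i <- which(ledger$status == "assigned" & ledger$barcode_id == lab)
      seqs <- trimmed_seq[i]; quals <- trimmed_qual[i]
    }
    nb <- sum(nchar(seqs))
    data.frame(label = lab, n_reads = length(i),
               fraction = if (n_total > 0L) length(i) / n_total else 0,
               total_bases = nb,
               mean_length = if (length(i)) nb / length(i) else NA_real_,
               mean_quality = mean_read_quality(quals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.demux_run <- function(x, ...) {
  s <- x$summary
  n <- sum(s$n_reads)
  asg <- s[!s$label %in% c("unclassified", "too_short"), ]
  cat(sprintf("demux run: %d reads, %d barcodes\n", n, nrow(asg)))
  cat(sprintf("  assigned:     %7d (%.2f%%)\n", sum(asg$n_reads),
              100 * sum(asg$n_reads) / max(n, 1)))
  for (lab in c("unclassified", "too_short")) {
    r <- s[s$label == lab, ]
    cat(sprintf("  %-12s %8d (%.2f%%)\n", paste0(lab, ":"), r$n_reads,
                100 * r$fraction))
  }
  if (!is.null(x$out_dir)) cat("  outputs in: ", x$out_dir, "\n", sep = "")
  invisible(x)
}
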