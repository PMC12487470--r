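#' Remove the first n bases of every read
#'
#' Head-cropping destroys any residual barcode/adapter content near the read
#' start; it is how a composite public read set is turned into a
#' negative control (the mock-community protocol crops 150 nt). Reads left
#' empty are dropped and counted.
#'
#' @param reads Reads `data.frame` ([read_fastq()] columns).
#' @param n Number of leading bases to remove (default 150).
#' @return `list(reads = cropped data.frame, n_dropped = count)`.
#' @export
head_crop <- function(reads, n = 150L) {
  stopifnot(is.data.frame(reads), n >= 0L)
  out <- reads
  out$sequence <- substring(reads$sequence, n + 1L)
  out$quality <- substring(reads$quality, n + 1L)
  keep <- nchar(out$sequence) > 0L
  list(reads = out[keep, , drop = FALSE], n_dropped = sum(!keep))
}

calls_ledger <- function(calls) {
  if (inherits(calls, "demux_run")) return(calls$ledger)
  stopifnot(is.data.frame(calls),
            all(c("read_id", "status") %in% names(calls)))
  if (!"barcode_id" %in% names(calls)) calls$barcode_id <- NA_character_
  calls
}

#' Score demultiplexing calls against ground truth
#'
#' Builds the confusion matrix keyed (truth, call) over the barcode labels
#' plus `"unclassified"`, and the classification rate
#' `n_classified / n_total`. Too-short reads are excluded from the matrix
#' and reported separately. Every called read must appear in the truth
#' table.
#'
#' @param calls A `demux_run` or its ledger (`read_id`, `status`,
#'   `barcode_id`).
#' @param truth `data.frame` with `read_id` and `true_barcode` (use
#'   `"none"` for barcode-free reads).
#' @return An object of class `eval_report`: `n_total`, `n_too_short`,
#'   `n_classified`, `classification_rate`, `n_correct`, `recovery_rate`
#'   (correctly assigned / total), `confusion`.
#' @export
score_against_truth <- function(calls, truth) {
  led <- calls_ledger(calls)
  stopifnot(is.data.frame(truth),
            all(c("read_id", "true_barcode") %in% names(truth)))
  m <- match(led$read_id, truth$read_id)
  if (anyNA(m))
    stop("read '", led$read_id[which(is.na(m))[1]],
         "' is missing from the truth table", call. = FALSE)
  n_total <- nrow(led)
  too_short <- led$status == "too_short"
  call_lab <- ifelse(led$status == "assigned", led$barcode_id, "unclassified")
  truth_lab <- truth$true_barcode[m]
  labs <- sort(unique(c(truth_lab, call_lab[!too_short], "unclassified")))
  confusion <- table(truth = factor(truth_lab[!too_short], labs),
                     call = factor(call_lab[!too_short], labs))
  n_classified <- sum(led$status == "assigned")
  n_correct <- sum(led$status == "assigned" &
                     led$barcode_id == truth_lab, na.rm = TRUE)
  structure(list(n_total = n_total, n_too_short = sum(too_short),
                 n_classified = n_classified,
                 classification_rate = if (n_total) n_classified / n_total
                   else NA_real_,
                 n_correct = n_correct,
                 recovery_rate = if (n_total) n_correct / n_total
                   else NA_real_,
                 confusion = confusion),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation over %d reads (%d too short):\n", x$n_total,
              x$n_too_short))
  cat(sprintf("  classified: %d (%.3g%%)\n", x$n_classified,
              100 * x$classification_rate))
  cat(sprintf("  correct:    %d (%.3g%%)\n", x$n_correct,
              100 * x$recovery_rate))
  invisible(x)
}

#' False-positive rate on a barcode-free negative control
#'
#' On a read set known to contain no barcodes, every assignment is a false
#' positive. The total FPR is assigned/total; the per-barcode FPR follows
#' the convention of dividing the total uniformly by the number of barcodes,
#' and the empirical per-barcode assigned fractions are reported alongside
#' since uniform division hides skew.
#'
#' @param calls A `demux_run` or its ledger.
#' @param n_barcodes Number of barcodes in the set; taken from a `demux_run`
#'   automatically.
#' @return `list(n_total, n_assigned, n_too_short, fpr_total,
#'   fpr_per_barcode, per_barcode)` where rates are fractions (not %) and
#'   `per_barcode` maps each observed barcode to its empirical fraction.
#' @examples
#' # 410 of 100,000 assigned over 24 barcodes: 0.41% total, ~0.017% each
#' @export
negative_control_fpr <- function(calls, n_barcodes = NULL) {
  led <- calls_ledger(calls)
  if (is.null(n_barcodes)) {
    if (inherits(calls, "demux_run")) n_barcodes <- nrow(calls$barcodes)
    else stop("n_barcodes is required when 'calls' is a plain ledger",
              call. = FALSE)
  }
  n_total <- nrow(led)
  if (n_total == 0L)
    stop("false-positive rate is undefined for zero reads", call. = FALSE)
  assigned <- led$status == "assigned"
  n_assigned <- sum(assigned)
  per <- table(led$barcode_id[assigned]) / n_total
  list(n_total = n_total, n_assigned = n_assigned,
       n_too_short = sum(led$status == "too_short"),
       fpr_total = n_assigned / n_total,
       fpr_per_barcode = n_assigned / n_total / n_barcodes,
       per_barcode = per)
}

#' Write an evaluation report as JSON
#'
#' Machine-readable form of [score_against_truth()] /
#' [negative_control_fpr()] output: rates at full precision, confusion
#' matrix as a nested mapping.
#'
#' @param report An `eval_report` or the list from [negative_control_fpr()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  x <- unclass(report)
  if (!is.null(x$confusion)) {
    cm <- x$confusion
    x$confusion <- lapply(seq_len(nrow(cm)), function(i)
      as.list(stats::setNames(as.integer(cm[i, ]), colnames(cm))))
    names(x$confusion) <- rownames(cm)
  }
  if (!is.null(x$per_barcode))
    x$per_barcode <- as.list(x$per_barcode)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
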