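#' Alignment scoring scheme
#'
#' Parameters of the local aligner. Defaults score a perfect 24-nt barcode at
#' 24, so the default score floor of 13 demands more than half an intact
#' barcode. `run_bonus` enables a non-linear mode in which each maximal run
#' of at least `run_min` consecutive matches earns a one-off bonus, which
#' favours alignments whose matches are split by short nanopore-style indels;
#' it is disabled (0) by default.
#'
#' @param match Integer reward per matched base (> 0).
#' @param mismatch Integer penalty per mismatched base (<= 0).
#' @param gap Integer penalty per gapped base, linear (<= 0).
#' @param run_bonus Non-negative bonus per maximal match run of length >=
#'   `run_min`; 0 disables the non-linear mode.
#' @param run_min Minimum run length that earns `run_bonus` (>= 2).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L, gap = -1L,
                           run_bonus = 0L, run_min = 4L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap <- as.integer(gap); run_bonus <- as.integer(run_bonus)
  run_min <- as.integer(run_min)
  if (match <= 0L) stop("match reward must be positive", call. = FALSE)
  if (mismatch > 0L) stop("mismatch penalty must be <= 0", call. = FALSE)
  if (gap > 0L) stop("gap penalty must be <= 0", call. = FALSE)
  if (run_bonus < 0L) stop("run_bonus must be >= 0", call. = FALSE)
  if (run_min < 2L) stop("run_min must be >= 2", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap = gap,
                 run_bonus = run_bonus, run_min = run_min),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("scoring scheme: match %+d, mismatch %+d, gap %+d", x$match,
              x$mismatch, x$gap))
  if (x$run_bonus > 0L)
    cat(sprintf(", run bonus +%d per match run >= %d", x$run_bonus, x$run_min))
  cat("\n")
  invisible(x)
}

#' Best local alignment of a barcode within a read prefix
#'
#' Finds the maximum-scoring local alignment of `query` in `target` under
#' `scheme`. When several alignments attain the maximum score, the one with
#' the smallest `read_start` is returned, then the smallest `read_end`;
#' alignments never begin or end with an indel. Bases outside A/C/G/T in the
#' target (e.g. N) mismatch every query base.
#'
#' @param query Barcode sequence (non-empty A/C/G/T string).
#' @param target Read (prefix) sequence.
#' @param scheme A [scoring_scheme()].
#' @param barcode_id Optional label carried into the result.
#' @return An object of class `alignment` (fields `barcode_id`, `score`,
#'   `read_start`, `read_end`, `barcode_start`, `barcode_end`, `ops` over
#'   M/X/I/D where I is an insertion in the read and D a deletion from the
#'   barcode), or `NULL` when no alignment scores above 0.
#' @examples
#' local_align("ACGT", "TTACGTTT")
#' @export
local_align <- function(query, target, scheme = scoring_scheme(),
                        barcode_id = NULL) {
  stopifnot(is.character(query), length(query) == 1L, nchar(query) > 0L,
            is.character(target), length(target) == 1L,
            inherits(scheme, "scoring_scheme"))
  if (!grepl("^[ACGTacgt]+$", query))
    stop("query must contain only A/C/G/T", call. = FALSE)
  res <- sw_align_pair_cpp(query, target, scheme$match, scheme$mismatch,
                           scheme$gap, scheme$run_bonus, scheme$run_min)
  if (res$score <= 0L) return(NULL)
  structure(c(list(barcode_id = barcode_id), res, list(scheme = scheme)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("local alignment%s: score %d, read %d-%d, barcode %d-%d\n  %s\n",
              if (is.null(x$barcode_id)) "" else paste0(" [", x$barcode_id, "]"),
              x$score, x$read_start, x$read_end, x$barcode_start,
              x$barcode_end, x$ops))
  invisible(x)
}

# Recompute an alignment's score from its ops string (self-consistency
# check used in tests): matches, mismatches, gaps, plus run_bonus once per
# maximal M-run of length >= run_min.
score_from_ops <- function(ops, scheme) {
  op <- strsplit(ops, "")[[1]]
  base <- sum((op == "M") * scheme$match) +
    sum((op == "X") * scheme$mismatch) +
    sum((op %in% c("I", "D")) * scheme$gap)
  if (scheme$run_bonus > 0L) {
    runs <- rle(op)
    n_runs <- sum(runs$values == "M" & runs$lengths >= scheme$run_min)
    base <- base + n_runs * scheme$run_bonus
  }
  base
}

#' Reverse complement of DNA sequences
#'
#' Vectorized; IUPAC ambiguity codes are complemented (N stays N).
#'
#' @param sequence Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC")
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence))
  if (length(sequence) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence)))
}
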