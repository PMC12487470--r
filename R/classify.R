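#' Score-tiered positional window map
#'
#' Barcode alignments in rapid-kit libraries start near read position 47, so
#' an alignment is only trusted when its start coordinate lies inside a
#' window that widens with the alignment score: weak alignments (score 13,
#' the default floor) must start between positions 36 and 51, score-14
#' alignments between 30 and 75, and higher-scoring alignments between 5 and
#' 85. Scores below `min_score_floor` are always rejected.
#'
#' @param tiers `data.frame` with columns `min_score`, `window_start`,
#'   `window_end`, sorted by ascending `min_score`; windows are 1-based,
#'   inclusive on both ends.
#' @param min_score_floor Global lower score cutoff (default 13).
#' @return An object of class `window_map`.
#' @export
window_map <- function(tiers = data.frame(min_score = c(13L, 14L, 15L),
                                          window_start = c(36L, 30L, 5L),
                                          window_end = c(51L, 75L, 85L)),
                       min_score_floor = 13L) {
  stopifnot(is.data.frame(tiers),
            all(c("min_score", "window_start", "window_end") %in% names(tiers)),
            nrow(tiers) >= 1L)
  tiers <- data.frame(min_score = as.integer(tiers$min_score),
                      window_start = as.integer(tiers$window_start),
                      window_end = as.integer(tiers$window_end))
  if (is.unsorted(tiers$min_score, strictly = TRUE))
    stop("tiers must be sorted by strictly increasing min_score", call. = FALSE)
  if (any(tiers$window_start > tiers$window_end) ||
      any(tiers$window_start < 1L))
    stop("each tier needs 1 <= window_start <= window_end", call. = FALSE)
  structure(list(tiers = tiers, min_score_floor = as.integer(min_score_floor)),
            class = "window_map")
}

#' @export
print.window_map <- function(x, ...) {
  cat("positional window map (score floor ", x$min_score_floor, "):\n",
      sep = "")
  for (k in seq_len(nrow(x$tiers)))
    cat(sprintf("  score >= %d: start in [%d, %d]\n", x$tiers$min_score[k],
                x$tiers$window_start[k], x$tiers$window_end[k]))
  invisible(x)
}

#' Parse a window map from its compact text form
#'
#' The text form is comma-separated `min_score:start:end` triples, e.g. the
#' default map `"13:36:51,14:30:75,15:5:85"`. The floor defaults to the
#' lowest tier score.
#'
#' @param text Compact tier specification.
#' @param min_score_floor Optional explicit floor.
#' @return A [window_map()].
#' @export
parse_window_map <- function(text, min_score_floor = NULL) {
  parts <- strsplit(strsplit(text, ",")[[1]], ":")
  if (any(lengths(parts) != 3L))
    stop("window map entries must be 'min_score:start:end'", call. = FALSE)
  m <- vapply(parts, function(p) as.integer(p), integer(3))
  if (anyNA(m)) stop("non-integer value in window map", call. = FALSE)
  tiers <- data.frame(min_score = m[1, ], window_start = m[2, ],
                      window_end = m[3, ])
  tiers <- tiers[order(tiers$min_score), , drop = FALSE]
  window_map(tiers, min_score_floor %||% min(tiers$min_score))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Valid start window for an alignment score
#'
#' Returns the window of the highest tier whose `min_score` does not exceed
#' `score`, or `NULL` when the score is below the floor (or below every
#' tier).
#'
#' @param score Integer alignment score.
#' @param map A [window_map()].
#' @return `c(start, end)` or `NULL`.
#' @examples
#' window_for_score(13, window_map())  # c(36, 51)
#' window_for_score(12, window_map())  # NULL
#' @export
window_for_score <- function(score, map = window_map()) {
  stopifnot(inherits(map, "window_map"), length(score) == 1L)
  if (is.na(score) || score < map$min_score_floor) return(NULL)
  k <- findInterval(score, map$tiers$min_score)
  if (k == 0L) return(NULL)
  c(map$tiers$window_start[k], map$tiers$window_end[k])
}

#' Align every barcode of a set against a read prefix
#'
#' Aligns each barcode (optionally also its reverse complement, keeping the
#' better orientation) against the first `scan_window` bases of the read, or
#' the whole read if shorter. Reads are scanned untrimmed.
#'
#' @param sequence Read sequence (single string).
#' @param barcodes Barcode set: FASTA path, builtin name, or `data.frame`
#'   (see [load_barcode_set()]).
#' @param scheme A [scoring_scheme()].
#' @param scan_window Prefix length scanned (default 110 nt).
#' @param scan_revcomp Also scan reverse-complemented barcodes.
#' @return A `data.frame` with one row per barcode that produced a
#'   positive-score alignment: `barcode_id`, `score`, `read_start`,
#'   `read_end`, `orient` ("+" or "-").
#' @export
scan_read <- function(sequence, barcodes, scheme = scoring_scheme(),
                      scan_window = 110L, scan_revcomp = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, scan_window >= 1L)
  bc <- as_barcode_set(barcodes)
  res <- sw_scan_batch_cpp(sequence, bc$sequence, as.integer(scan_window),
                           scheme$match, scheme$mismatch, scheme$gap,
                           scheme$run_bonus, scheme$run_min, scan_revcomp)
  keep <- which(res$score[1, ] > 0L)
  data.frame(barcode_id = bc$barcode_id[keep],
             score = res$score[1, keep],
             read_start = res$read_start[1, keep],
             read_end = res$read_end[1, keep],
             orient = c("+", "-")[res$orient[1, keep] + 1L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify one read from its per-barcode alignments
#'
#' Ranks the per-barcode best alignments by score (ties broken by smaller
#' `read_start`, then `read_end`, then barcode ID, so the decision is
#' independent of barcode input order), requires the best score to reach the
#' map's floor and to exceed the second-best distinct barcode's score by at
#' least `margin`, then applies the positional filter to the winner's start
#' coordinate. With `prefilter_window = TRUE` the score floor and positional
#' filter are instead applied to every candidate before ranking.
#'
#' @param alignments `data.frame` from [scan_read()] (may have zero rows).
#' @param map A [window_map()].
#' @param margin Minimum score difference to the runner-up (default 2; a
#'   difference of exactly `margin` passes).
#' @param prefilter_window Filter candidates before ranking instead of after.
#' @return An object of class `classification`: `status` ("assigned" or
#'   "unclassified"), `barcode_id`, `best` (winning alignment row or `NULL`),
#'   `runner_up_score`, and `reject_reason` (one of "none", "no_alignment",
#'   "below_min_score", "margin_too_small", "outside_window").
#' @export
decide <- function(alignments, map = window_map(), margin = 2L,
                   prefilter_window = FALSE) {
  stopifnot(is.data.frame(alignments), inherits(map, "window_map"),
            margin >= 0L)
  rej <- function(reason, best = NULL, runner = NA_integer_)
    structure(list(status = "unclassified", barcode_id = NA_character_,
                   best = best, runner_up_score = runner,
                   reject_reason = reason), class = "classification")
  if (nrow(alignments) == 0L) return(rej("no_alignment"))

  a <- alignments
  # collapse multiple alignments of the same barcode to the best one
  o <- order(a$score, -a$read_start, -a$read_end, decreasing = TRUE)
  a <- a[o, , drop = FALSE]
  a <- a[!duplicated(a$barcode_id), , drop = FALSE]

  if (prefilter_window) {
    ok <- vapply(seq_len(nrow(a)), function(k) {
      w <- window_for_score(a$score[k], map)
      !is.null(w) && a$read_start[k] >= w[1] && a$read_start[k] <= w[2]
    }, logical(1))
    if (!any(ok)) {
      if (all(a$score < map$min_score_floor)) return(rej("below_min_score"))
      return(rej("outside_window"))
    }
    a <- a[ok, , drop = FALSE]
  }

  o <- order(a$score, -a$read_start, -a$read_end,
             -xtfrm(a$barcode_id), decreasing = TRUE)
  a <- a[o, , drop = FALSE]
  best <- a[1, , drop = FALSE]
  runner <- if (nrow(a) >= 2L) a$score[2] else NA_integer_

  if (best$score < map$min_score_floor)
    return(rej("below_min_score", best, runner))
  if (!is.na(runner) && best$score - runner < margin)
    return(rej("margin_too_small", best, runner))
  if (!prefilter_window) {
    w <- window_for_score(best$score, map)
    if (is.null(w) || best$read_start < w[1] || best$read_start > w[2])
      return(rej("outside_window", best, runner))
  }
  structure(list(status = "assigned", barcode_id = best$barcode_id,
                 best = best, runner_up_score = runner,
                 reject_reason = "none"), class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  if (x$status == "assigned")
    cat(sprintf("assigned to %s (score %d at read position %d-%d)\n",
                x$barcode_id, x$best$score, x$best$read_start, x$best$read_end))
  else
    cat(sprintf("unclassified (%s)\n", x$reject_reason))
  invisible(x)
}

#' Classify many reads at once
#'
#' Vectorized equivalent of [scan_read()] + [decide()] for every read;
#' this is the path [demux()] uses. Decisions are identical to the per-read
#' functions.
#'
#' @param sequences Character vector of read sequences.
#' @param barcodes Barcode set (any form accepted by [load_barcode_set()]).
#' @param config A [demux_config()].
#' @return A `data.frame` with one row per read: `status`, `barcode_id`,
#'   `score`, `read_start`, `read_end`, `runner_up_score`, `reject_reason`.
#' @export
classify_reads <- function(sequences, barcodes, config = demux_config()) {
  bc <- as_barcode_set(barcodes)
  check_scan_window(config, bc)
  n <- length(sequences)
  out <- data.frame(status = rep("unclassified", n),
                    barcode_id = rep(NA_character_, n),
                    score = rep(NA_integer_, n),
                    read_start = rep(NA_integer_, n),
                    read_end = rep(NA_integer_, n),
                    runner_up_score = rep(NA_integer_, n),
                    reject_reason = rep("no_alignment", n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  sch <- config$scheme
  res <- sw_scan_batch_cpp(sequences, bc$sequence,
                           as.integer(config$scan_window), sch$match,
                           sch$mismatch, sch$gap, sch$run_bonus, sch$run_min,
                           config$scan_revcomp)
  S <- res$score; RS <- res$read_start; RE <- res$read_end
  map <- config$map
  floor_ <- map$min_score_floor

  if (config$prefilter_window) {
    k <- matrix(findInterval(S, map$tiers$min_score), nrow = n)
    ok <- S >= floor_ & k >= 1L
    ws <- matrix(map$tiers$window_start[pmax(k, 1L)], nrow = n)
    we <- matrix(map$tiers$window_end[pmax(k, 1L)], nrow = n)
    ok <- ok & !is.na(RS) & RS >= ws & RS <= we
    had_floor <- rowSums(S >= floor_, na.rm = TRUE) > 0L
    S2 <- S; S2[!ok] <- 0L
    pref <- list(S = S2, had_floor = had_floor)
  } else pref <- NULL

  Sx <- if (is.null(pref)) S else pref$S
  # deterministic ranking key: score desc, read_start asc, read_end asc,
  # barcode_id asc (lexicographic rank)
  bcrank <- rank(bc$barcode_id, ties.method = "first")
  key <- (Sx * 1e4 - ifelse(is.na(RS), 0, RS)) * 1e4 -
    ifelse(is.na(RE), 0, RE)
  key <- key * 128 - matrix(rep(bcrank, each = n), nrow = n)
  key[Sx <= 0L] <- -Inf
  any_pos <- rowSums(Sx > 0L) > 0L
  bestc <- max.col(key, ties.method = "first")
  idx <- cbind(seq_len(n), bestc)
  b_score <- Sx[idx]; b_rs <- RS[idx]; b_re <- RE[idx]
  S2 <- Sx; S2[idx] <- 0L
  runner <- do.call(pmax, as.data.frame(S2))

  out$score[any_pos] <- b_score[any_pos]
  out$read_start[any_pos] <- b_rs[any_pos]
  out$read_end[any_pos] <- b_re[any_pos]
  out$runner_up_score[any_pos & runner > 0L] <-
    runner[any_pos & runner > 0L]

  if (is.null(pref)) {
    k <- findInterval(b_score, map$tiers$min_score)
    in_win <- k >= 1L & !is.na(b_rs) &
      b_rs >= map$tiers$window_start[pmax(k, 1L)] &
      b_rs <= map$tiers$window_end[pmax(k, 1L)]
    below <- any_pos & b_score < floor_
    margin_fail <- any_pos & !below & runner > 0L &
      (b_score - runner) < config$margin
    outside <- any_pos & !below & !margin_fail & !in_win
    assigned <- any_pos & !below & !margin_fail & !outside
  } else {
    had_aln <- rowSums(S > 0L) > 0L
    # no survivor of the prefilter: report why the candidates fell
    below <- had_aln & !any_pos & !pref$had_floor
    outside <- had_aln & !any_pos & pref$had_floor
    margin_fail <- any_pos & runner > 0L & (b_score - runner) < config$margin
    assigned <- any_pos & !margin_fail
  }

  out$reject_reason[below] <- "below_min_score"
  out$reject_reason[margin_fail] <- "margin_too_small"
  out$reject_reason[outside] <- "outside_window"
  out$status[assigned] <- "assigned"
  out$reject_reason[assigned] <- "none"
  out$barcode_id[assigned] <- bc$barcode_id[bestc[assigned]]
  out
}

check_scan_window <- function(config, bc) {
  if (config$scan_window < max(nchar(bc$sequence)))
    stop("scan_window (", config$scan_window,
         ") is shorter than the longest barcode (",
         max(nchar(bc$sequence)), ")", call. = FALSE)
  invisible(TRUE)
}
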