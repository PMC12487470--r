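# Independent oracles for the aligner tests.

# Global (Needleman-Wunsch) score of two short integer-encoded sequences,
# linear gaps. Plain R DP, structurally unrelated to the package's scanner.
nw_score <- function(q, t, match, mismatch, gap) {
  m <- length(q); n <- length(t)
  prev <- (0:n) * gap
  for (i in seq_len(m)) {
    cur <- numeric(n + 1)
    cur[1] <- i * gap
    for (j in seq_len(n)) {
      s <- if (!is.na(q[i]) && !is.na(t[j]) && q[i] == t[j]) match else mismatch
      cur[j + 1] <- max(prev[j] + s, prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[n + 1]
}

enc <- function(s) match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))

# Definitional local alignment: the best global alignment over all pairs of
# (query substring, target substring); ties resolved by smallest target
# start, then smallest target end. Valid for schemes with strictly negative
# mismatch and gap penalties (no zero-cost boundary ops).
brute_local <- function(query, target, scheme) {
  q <- enc(query); t <- enc(target)
  nq <- length(q); nt <- length(t)
  best <- list(score = 0L, read_start = NA_integer_, read_end = NA_integer_)
  for (a in seq_len(nt)) for (b in a:nt) {
    tt <- t[a:b]
    for (qs in seq_len(nq)) for (qe in qs:nq) {
      sc <- nw_score(q[qs:qe], tt, scheme$match, scheme$mismatch, scheme$gap)
      if (sc > best$score ||
          (sc == best$score && sc > 0 &&
           (a < best$read_start ||
            (a == best$read_start && b < best$read_end)))) {
        best <- list(score = sc, read_start = a, read_end = b)
      }
    }
  }
  best
}

# Exhaustive enumeration of local alignments as op strings (M/X/I/D paths
# that begin and end with a diagonal op), scored including the run bonus.
# Exponential: only for very short strings.
enum_best_score <- function(query, target, scheme) {
  q <- enc(query); t <- enc(target)
  nq <- length(q); nt <- length(t)
  score_ops <- function(ops) {
    base <- sum(ifelse(ops == "M", scheme$match,
                       ifelse(ops == "X", scheme$mismatch, scheme$gap)))
    if (scheme$run_bonus > 0) {
      r <- rle(ops)
      base <- base + scheme$run_bonus *
        sum(r$values == "M" & r$lengths >= scheme$run_min)
    }
    base
  }
  best <- 0L
  rec <- function(i, j, ops) {
    if (length(ops) && ops[length(ops)] %in% c("M", "X")) {
      sc <- score_ops(ops)
      if (sc > best) best <<- sc
    }
    if (i <= nq && j <= nt)
      rec(i + 1L, j + 1L, c(ops, if (q[i] == t[j]) "M" else "X"))
    if (length(ops)) {
      if (i <= nq) rec(i + 1L, j, c(ops, "D"))
      if (j <= nt) rec(i, j + 1L, c(ops, "I"))
    }
  }
  for (a in seq_len(nt)) for (qs in seq_len(nq)) rec(qs, a, character(0))
  best
}

# Biostrings local alignment scores: one pattern set against one subject.
bios_scores <- function(queries, subject, match, mismatch, gap) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  as.integer(Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), subject, type = "local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap)))
}

package_score <- function(query, target, scheme) {
  a <- local_align(query, target, scheme)
  if (is.null(a)) 0L else a$score
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
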