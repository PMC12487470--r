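# Generates the bundled synthetic barcode sets (inst/extdata).
#
# 96 random 24-nt barcodes accepted greedily under separation constraints:
# best local alignment score (match +1, mismatch -1, gap -1) between any two
# distinct barcodes, and between any barcode and any reverse complement,
# stays <= 11 (below the default score floor of 13), and no homopolymer
# exceeds 4 nt. The 24-set is the first 24 of the 96-set. Run from the
# package root after building; deterministic under the fixed seed.
pkgload::load_all(".", quiet = TRUE)

set.seed(20260921)
target_n <- 96L
len <- 24L
max_cross <- 11L
accepted <- character(0)

max_sw <- function(a, b) {
  r <- sw_align_pair_cpp(a, b, 1L, -1L, -1L, 0L, 4L)
  r$score
}

while (length(accepted) < target_n) {
  cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
  if (grepl("AAAAA|CCCCC|GGGGG|TTTTT", cand)) next
  rc <- reverse_complement(cand)
  ok <- TRUE
  for (b in accepted) {
    if (max_sw(cand, b) > max_cross || max_sw(rc, b) > max_cross ||
        max_sw(cand, reverse_complement(b)) > max_cross) {
      ok <- FALSE; break
    }
  }
  if (max_sw(cand, rc) > max_cross) ok <- FALSE
  if (ok) accepted <- c(accepted, cand)
}

dir.create("inst/extdata", showWarnings = FALSE, recursive = TRUE)
write_set <- function(seqs, path) {
  ids <- sprintf("BC%02d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
}
write_set(accepted[1:24], "inst/extdata/barcodes_24_synthetic.fasta")
write_set(accepted, "inst/extdata/barcodes_96_synthetic.fasta")
cat("wrote", length(accepted), "barcodes\n")
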