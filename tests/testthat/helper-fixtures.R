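# Shared fixture builders.

make_reads <- function(seqs, ids = sprintf("read-%03d", seq_along(seqs)),
                       q = 30L) {
  data.frame(read_id = ids, desc = rep("", length(seqs)), sequence = seqs,
             quality = strrep(intToUtf8(q + 33L), nchar(seqs)),
             source = rep("fixture", length(seqs)), stringsAsFactors = FALSE)
}

# A read with `barcode` embedded after `leader_length` random bases,
# followed by enough random sequence to reach `total_length`.
make_barcoded_read <- function(barcode, leader_length = 46L,
                               total_length = 1000L) {
  tail_len <- total_length - leader_length - nchar(barcode)
  stopifnot(tail_len >= 0L)
  paste0(random_seq(leader_length), barcode, random_seq(tail_len))
}

quiet_demux <- function(...) suppressMessages(demux(...))

dir_md5 <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  m <- tools::md5sum(files)
  names(m) <- basename(files)
  m
}
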