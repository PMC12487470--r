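#' Fixed adapter-like flank used by the simulator
#'
#' A constant 30-nt sequence appended after the barcode in simulated reads,
#' so trimming tests have a known suffix. It is an arbitrary fixed constant,
#' not a kit adapter sequence.
#' @return A 30-character DNA string.
#' @export
sim_flank <- function() "GCTTGGGTGTTTAACCGTTGGTGCTGATAT"

#' Parameters for the synthetic read generator
#'
#' Simulated reads emulate rapid-barcoding-kit structure: a random leader
#' (default 46 nt, so the barcode starts at position 47), the barcode, a
#' fixed 30-nt adapter-like flank, then a random genomic-like insert
#' (default 1,000 nt). Substitution / insertion / deletion errors are applied
#' independently per base; the defaults of 0 give error-free reads, and 0.02
#' each approximates R10.4.1-class error rates.
#'
#' @param n_reads Number of reads.
#' @param barcodes Barcode set (any form accepted by [load_barcode_set()]).
#' @param leader_length Random leader length, nt (default 46).
#' @param flank Fixed sequence between barcode and insert ([sim_flank()]).
#' @param insert_length Random insert length, nt (default 1000).
#' @param p_sub,p_ins,p_del Per-base error probabilities (defaults 0).
#' @param q_const Constant Phred score written for every base (default 12).
#' @param jitter Maximum uniform jitter of the barcode start, nt (default 0).
#' @param seed RNG seed; all outputs are pure functions of the parameters.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_reads = 2400L, barcodes = "builtin24",
                       leader_length = 46L, flank = sim_flank(),
                       insert_length = 1000L, p_sub = 0, p_ins = 0, p_del = 0,
                       q_const = 12L, jitter = 0L, seed = 1L) {
  stopifnot(n_reads >= 0L, leader_length >= 0L, insert_length >= 0L,
            jitter >= 0L, q_const >= 0L, q_const <= 93L,
            p_sub >= 0, p_ins >= 0, p_del >= 0, p_sub + p_ins + p_del <= 1)
  structure(list(n_reads = as.integer(n_reads),
                 barcodes = as_barcode_set(barcodes),
                 leader_length = as.integer(leader_length),
                 flank = toupper(flank),
                 insert_length = as.integer(insert_length),
                 p_sub = p_sub, p_ins = p_ins, p_del = p_del,
                 q_const = as.integer(q_const), jitter = as.integer(jitter),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# Random A/C/G/T strings of the given lengths, drawn from the current RNG.
# Works in bounded chunks so very large simulations stay memory-friendly.
random_dna <- function(lengths, chunk_bases = 1e7) {
  if (length(lengths) == 0L) return(character(0))
  grp <- cumsum(as.numeric(lengths)) %/% chunk_bases
  unlist(lapply(split(lengths, grp), function(lens) {
    total <- sum(lens)
    if (total == 0L) return(rep("", length(lens)))
    codes <- c(65L, 67L, 71L, 84L)[sample.int(4L, total, replace = TRUE)]
    big <- intToUtf8(codes)
    ends <- cumsum(lens)
    substring(big, ends - lens + 1L, ends)
  }), use.names = FALSE)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Apply independent per-base sequencing errors
#'
#' For every position, independently: delete the base with probability
#' `p_del`, otherwise substitute it (with a uniformly chosen different base)
#' with probability `p_sub`; and insert a random base after the position with
#' probability `p_ins`. With all rates 0 the sequence is returned unchanged;
#' the expected length change is `length * (p_ins - p_del)`.
#'
#' @param sequence Character vector of DNA strings.
#' @param p_sub,p_ins,p_del Per-base error probabilities.
#' @return Character vector of mutated sequences.
#' @export
apply_errors <- function(sequence, p_sub = 0, p_ins = 0, p_del = 0) {
  stopifnot(p_sub >= 0, p_ins >= 0, p_del >= 0,
            p_sub <= 1, p_ins <= 1, p_del <= 1)
  if (p_sub == 0 && p_ins == 0 && p_del == 0) return(sequence)
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    del <- runif(n) < p_del
    sub <- runif(n) < p_sub
    ins <- runif(n) < p_ins
    idx <- match(chars, c("A", "C", "G", "T"))
    do_sub <- which(sub & !del)
    if (length(do_sub)) {
      shift <- sample.int(3L, length(do_sub), replace = TRUE)
      orig <- idx[do_sub]
      orig[is.na(orig)] <- sample.int(4L, sum(is.na(orig)), replace = TRUE)
      chars[do_sub] <- c("A", "C", "G", "T")[((orig - 1L + shift) %% 4L) + 1L]
    }
    slots <- character(2L * n)
    slots[2L * seq_len(n) - 1L][!del] <- chars[!del]
    n_ins <- sum(ins)
    if (n_ins)
      slots[2L * which(ins)] <-
        c("A", "C", "G", "T")[sample.int(4L, n_ins, replace = TRUE)]
    paste(slots[nzchar(slots)], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate barcoded nanopore-like reads with ground truth
#'
#' Barcodes are assigned round-robin over the set so per-barcode counts are
#' exact. Each error-free template is leader + barcode + flank + insert; the
#' truth table records the barcode position on the template before errors
#' are applied. Qualities are a constant `q_const` for every base. Identical
#' parameters (including seed) give byte-identical outputs.
#'
#' @param params A [sim_params()].
#' @param out_fastq,out_truth Optional output paths (FASTQ, truth TSV with
#'   columns `read_id`, `true_barcode`, `barcode_start`, `barcode_end`).
#' @return `list(reads = , truth = , manifest = )` where `manifest` counts
#'   reads per barcode.
#' @examples
#' sim <- simulate_reads(sim_params(n_reads = 4, seed = 7))
#' sim$truth
#' @export
simulate_reads <- function(params = sim_params(), out_fastq = NULL,
                           out_truth = NULL) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  n <- p$n_reads
  bc_idx <- if (n > 0L)
    rep_len(seq_len(nrow(p$barcodes)), n) else integer(0)
  reads_truth <- with_seed(p$seed, {
    jit <- if (p$jitter > 0L)
      sample.int(2L * p$jitter + 1L, n, replace = TRUE) - p$jitter - 1L
    else rep(0L, n)
    lead_len <- pmax(p$leader_length + jit, 0L)
    leaders <- random_dna(lead_len)
    inserts <- random_dna(rep(p$insert_length, n))
    bcs <- p$barcodes$sequence[bc_idx]
    templates <- paste0(leaders, bcs, p$flank, inserts)
    seqs <- apply_errors(templates, p$p_sub, p$p_ins, p$p_del)
    list(seqs = seqs, lead_len = lead_len, bcs = bcs)
  })
  seqs <- reads_truth$seqs
  ids <- sprintf("simread-%06d", seq_len(n))
  reads <- data.frame(read_id = ids, desc = "",
                      sequence = seqs,
                      quality = strrep(intToUtf8(p$q_const + 33L), nchar(seqs)),
                      source = "simulated",
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = ids,
                      true_barcode = p$barcodes$barcode_id[bc_idx],
                      barcode_start = reads_truth$lead_len + 1L,
                      barcode_end = reads_truth$lead_len +
                        nchar(reads_truth$bcs),
                      stringsAsFactors = FALSE)
  if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
  if (!is.null(out_truth)) {
    dir.create(dirname(out_truth), showWarnings = FALSE, recursive = TRUE)
    write.table(truth, out_truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  manifest <- as.data.frame(table(true_barcode = truth$true_barcode),
                            stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, manifest = manifest)
}

#' Generate barcode-free negative-control reads
#'
#' Reads of pure random sequence (no leader, barcode or flank), emulating a
#' mock-community negative control after head-cropping: any barcode
#' assignment on these reads is a false positive.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length, nt (default 1000).
#' @param q_const Constant Phred score (default 12).
#' @param seed RNG seed.
#' @param out_fastq,out_truth Optional output paths; the truth table lists
#'   `true_barcode = "none"` for every read.
#' @return `list(reads = , truth = )`.
#' @export
simulate_negative <- function(n_reads = 10000L, read_length = 1000L,
                              q_const = 12L, seed = 1L, out_fastq = NULL,
                              out_truth = NULL) {
  stopifnot(n_reads >= 0L, read_length >= 0L)
  seqs <- with_seed(seed, random_dna(rep(as.integer(read_length), n_reads)))
  ids <- sprintf("negread-%06d", seq_len(n_reads))
  reads <- data.frame(read_id = ids, desc = "", sequence = seqs,
                      quality = strrep(intToUtf8(q_const + 33L), nchar(seqs)),
                      source = "simulated", stringsAsFactors = FALSE)
  truth <- data.frame(read_id = ids, true_barcode = "none",
                      barcode_start = NA_integer_, barcode_end = NA_integer_,
                      stringsAsFactors = FALSE)
  if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
  if (!is.null(out_truth)) {
    dir.create(dirname(out_truth), showWarnings = FALSE, recursive = TRUE)
    write.table(truth, out_truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(reads = reads, truth = truth)
}
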