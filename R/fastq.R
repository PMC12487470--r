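#' Read FASTQ records from a file or directory
#'
#' Accepts a single FASTQ file (plain or gzipped) or a directory containing
#' files with extensions `.fastq`, `.fq`, `.fastq.gz` or `.fq.gz`
#' (case-insensitive). Directory files are processed in lexicographic name
#' order so multi-file runs are deterministic; record order within a file is
#' preserved. The read ID is the header token up to the first whitespace; the
#' remainder of the header is kept in `desc` and restored on output.
#'
#' @param path A FASTQ(.gz) file or a directory of such files.
#' @return A `data.frame` with columns `read_id`, `desc`, `sequence`,
#'   `quality` (Phred+33 string, same length as `sequence`) and `source`
#'   (originating file name).
#' @seealso [write_fastq()]
#' @export
read_fastq <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fastq|fq)(\\.gz)?$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L)
      stop("no .fastq/.fq/.fastq.gz/.fq.gz files found in directory: ", path,
           call. = FALSE)
    files <- files[order(basename(files), method = "radix")]
  } else if (file.exists(path)) {
    files <- path
  } else {
    stop("input path does not exist: ", path, call. = FALSE)
  }
  out <- lapply(files, read_fastq_file)
  if (length(out) == 1L) out[[1]] else do.call(rbind, out)
}

read_fastq_file <- function(file) {
  # structural pre-check: FASTQ is strictly 4 lines per record, and a
  # truncated trailing record must be reported, not silently mis-parsed
  n_lines <- length(readLines(file, warn = FALSE))
  if (n_lines %% 4L != 0L)
    stop("malformed FASTQ in '", file, "': ", n_lines,
         " lines is not a multiple of 4 (truncated around record ",
         (n_lines %/% 4L) + 1L, ")", call. = FALSE)
  recs <- tryCatch(
    Biostrings::readDNAStringSet(file, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("malformed FASTQ in '", file, "': ", conditionMessage(e),
           call. = FALSE)
    })
  headers <- names(recs)
  if (is.null(headers)) headers <- rep("", length(recs))
  id <- sub("[ \t].*$", "", headers)
  desc <- ifelse(grepl("[ \t]", headers),
                 sub("^[^ \t]*[ \t]+", "", headers), "")
  data.frame(read_id = id, desc = desc,
             sequence = as.character(recs),
             quality = as.character(S4Vectors::mcols(recs)$qualities),
             source = basename(file),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write FASTQ records
#'
#' Writes records in 4-line-per-record FASTQ; a `.gz` suffix selects gzip
#' output. Reading the file back with [read_fastq()] reproduces
#' `(read_id, sequence, quality)` exactly.
#'
#' @param reads A `data.frame` as returned by [read_fastq()] (columns `desc`
#'   and `source` are optional).
#' @param path Output file path; parent directory is created if needed.
#' @return Invisibly, the number of records written.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality") %in% names(reads)))
  bad <- which(nchar(reads$quality) != nchar(reads$sequence))
  if (length(bad))
    stop("record '", reads$read_id[bad[1]],
         "': quality length differs from sequence length", call. = FALSE)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  desc <- if ("desc" %in% names(reads)) reads$desc else ""
  header <- ifelse(nzchar(desc),
                   paste0("@", reads$read_id, " ", desc),
                   paste0("@", reads$read_id))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    lines <- as.vector(rbind(header, reads$sequence, "+", reads$quality))
    writeLines(lines, con)
  }
  invisible(nrow(reads))
}

# Mean Phred quality of a set of reads: Phred of the mean per-base error
# probability over all bases (long-read QC convention). NA for zero bases.
mean_read_quality <- function(quality) {
  quality <- quality[nchar(quality) > 0L]
  if (length(quality) == 0L) return(NA_real_)
  tot_p <- 0; tot_n <- 0
  for (q in quality) {
    ph <- utf8ToInt(q) - 33L
    tot_p <- tot_p + sum(10^(-ph / 10))
    tot_n <- tot_n + length(ph)
  }
  -10 * log10(tot_p / tot_n)
}
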