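#' Load a barcode reference set
#'
#' Reads a FASTA file of barcode sequences, or one of the two bundled sets.
#' The bundled sets (`"builtin24"`, `"builtin96"`) contain synthetic 24-nt
#' barcodes generated with enforced pairwise separation; they stand in for
#' kit barcode sets, which can be supplied as a FASTA file instead.
#'
#' Sequences are upper-cased; every barcode must be a non-empty A/C/G/T
#' string and IDs (the first whitespace-delimited token of each FASTA header)
#' must be unique. Input order is preserved.
#'
#' @param path_or_name Path to a FASTA file, or `"builtin24"` / `"builtin96"`.
#' @return A `data.frame` with columns `barcode_id` and `sequence`.
#' @examples
#' bc <- load_barcode_set("builtin24")
#' nrow(bc)
#' @export
load_barcode_set <- function(path_or_name) {
  stopifnot(is.character(path_or_name), length(path_or_name) == 1L)
  path <- switch(path_or_name,
    builtin24 = system.file("extdata", "barcodes_24_synthetic.fasta",
                            package = "nanodemux", mustWork = TRUE),
    builtin96 = system.file("extdata", "barcodes_96_synthetic.fasta",
                            package = "nanodemux", mustWork = TRUE),
    path_or_name)
  if (!file.exists(path))
    stop("barcode FASTA not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("failed to parse barcode FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("barcode FASTA '", path, "' contains no records", call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  bad <- which(!grepl("^[ACGT]+$", seqs))
  if (length(bad))
    stop("barcode '", ids[bad[1]], "' has an empty or non-ACGT sequence",
         call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate barcode ID in set: '", dup[1], "'", call. = FALSE)
  data.frame(barcode_id = ids, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

# Accepts a barcode set in any supported form; validates and normalizes.
as_barcode_set <- function(barcodes) {
  if (is.character(barcodes) && length(barcodes) == 1L)
    return(load_barcode_set(barcodes))
  if (is.data.frame(barcodes)) {
    stopifnot(all(c("barcode_id", "sequence") %in% names(barcodes)))
    seqs <- toupper(barcodes$sequence)
    if (any(!grepl("^[ACGT]+$", seqs)))
      stop("barcode sequences must be non-empty A/C/G/T strings", call. = FALSE)
    if (anyDuplicated(barcodes$barcode_id))
      stop("duplicate barcode IDs", call. = FALSE)
    return(data.frame(barcode_id = as.character(barcodes$barcode_id),
                      sequence = seqs, stringsAsFactors = FALSE))
  }
  stop("'barcodes' must be a FASTA path, a builtin set name, ",
       "or a data.frame with columns barcode_id/sequence", call. = FALSE)
}
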