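#' Read an sgRNA library table
#'
#' Loads a tab-delimited guide library with columns `guide_id`, `gene_id` and
#' `sequence` (20-nt protospacer, A/C/G/T). The library is validated on load:
#' duplicate guide identifiers or duplicate sequences are errors, as is any
#' sequence that is not exactly 20 nt.
#'
#' @param path Path to a TSV file with header `guide_id, gene_id, sequence`.
#' @return A data.frame with columns `guide_id`, `gene_id`, `sequence`.
#' @export
read_sgrna_library <- function(path) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sgrna_library(lib)
}

#' Validate an sgRNA library data.frame
#'
#' @param lib data.frame with columns `guide_id`, `gene_id`, `sequence`.
#' @return The validated library (sequences upper-cased), invisibly usable.
#' @export
validate_sgrna_library <- function(lib) {
  req <- c("guide_id", "gene_id", "sequence")
  if (!all(req %in% names(lib))) {
    stop("library must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(lib) == 0L) stop("library is empty")
  lib$sequence <- toupper(lib$sequence)
  if (any(nchar(lib$sequence) != 20L)) {
    stop("all library sequences must be exactly 20 nt")
  }
  if (any(grepl("[^ACGT]", lib$sequence))) {
    stop("library sequences may contain only A, C, G, T")
  }
  if (anyDuplicated(lib$guide_id)) stop("duplicate guide_id in library")
  if (anyDuplicated(lib$sequence)) stop("duplicate sequences in library")
  lib
}

#' Read a sample sheet
#'
#' @param path TSV with header `sample_id, barcode, condition, replicate`.
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet data.frame
#'
#' Barcodes must be unique 6-mers over A/C/G/T and each
#' (condition, replicate) pair may occur once.
#'
#' @param sheet data.frame with columns `sample_id, barcode, condition, replicate`.
#' @return The validated sheet.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "barcode", "condition", "replicate")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  sheet$barcode <- toupper(sheet$barcode)
  if (any(nchar(sheet$barcode) != 6L) || any(grepl("[^ACGT]", sheet$barcode))) {
    stop("barcodes must be 6-nt sequences over A, C, G, T")
  }
  if (anyDuplicated(sheet$barcode)) stop("duplicate barcodes in sample sheet")
  if (anyDuplicated(paste(sheet$condition, sheet$replicate))) {
    stop("each (condition, replicate) pair must be unique")
  }
  sheet
}

#' Read a FASTQ file into id and sequence vectors
#'
#' Four-line FASTQ records, plain or gzip. Qualities are ignored (counting
#' does not use them).
#'
#' @param path FASTQ file (optionally `.gz`).
#' @return Named character vector of read sequences (names are read ids).
#' @export
read_fastq_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write reads as FASTQ
#'
#' Emits 4-line records with a constant quality character (counting ignores
#' qualities). Writes gzip output when `path` ends in `.gz`.
#'
#' @param sequences Character vector of reads; names used as read ids.
#' @param path Output path.
#' @param quality_char Single quality character repeated per base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sequences, path, quality_char = "I") {
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("read_%06d", seq_along(sequences))
  quals <- strrep(quality_char, nchar(sequences))
  rec <- as.vector(rbind(paste0("@", ids), sequences, "+", quals))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(rec, con)
  invisible(path)
}

#' Write a count matrix as TSV
#'
#' @param counts Integer matrix, guides x samples, with dimnames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(guide_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix TSV (first column `guide_id`)
#'
#' @param path TSV written by [write_count_matrix()].
#' @return Integer matrix with guide rownames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (one set per line: name, description, members).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}
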