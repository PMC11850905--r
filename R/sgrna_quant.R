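#' Demultiplex reads by sample barcode
#'
#' Assigns each read to the sample whose barcode equals the read's first six
#' bases exactly; everything else (including reads shorter than 6 nt, which
#' trigger a warning) is unassigned.
#'
#' @param reads Named character vector of read sequences.
#' @param sheet Sample sheet data.frame (see [validate_sample_sheet()]).
#' @return List with `by_sample` (named list of read vectors, one per sample,
#'   in sheet order) and `n_unassigned`.
#' @export
demultiplex <- function(reads, sheet) {
  sheet <- validate_sample_sheet(sheet)
  if (length(reads) == 0L) stop("no reads to demultiplex")
  reads <- toupper(reads)
  short <- nchar(reads) < 6L
  if (any(short)) {
    warning(sum(short), " read(s) shorter than 6 nt counted as unassigned")
  }
  bc <- substr(reads, 1L, 6L)
  idx <- match(bc, sheet$barcode)
  idx[short] <- NA_integer_
  by_sample <- lapply(seq_len(nrow(sheet)), function(i) {
    reads[!is.na(idx) & idx == i]
  })
  names(by_sample) <- sheet$sample_id
  list(by_sample = by_sample, n_unassigned = sum(is.na(idx)))
}

#' Locate the key sequence within the search window
#'
#' Returns, per read, the smallest 1-based position p inside
#' `[window[1], window[2]]` at which the full key occurs, or `NA` when the key
#' is absent from the window. The window bounds the position of the key's
#' first base, inclusive on both ends.
#'
#' @param seqs Character vector of read sequences.
#' @param key Key sequence preceding the guide (default `CGAAACACC`).
#' @param window Integer length-2: allowed 1-based key start positions.
#' @return Integer vector of key start positions (`NA` = not found).
#' @export
find_key <- function(seqs, key = "CGAAACACC", window = c(16L, 44L)) {
  stopifnot(length(window) == 2L, window[1] >= 1L, window[2] >= window[1])
  region <- substr(toupper(seqs), window[1], window[2] + nchar(key) - 1L)
  pos <- regexpr(key, region, fixed = TRUE)
  out <- ifelse(pos > 0L, as.integer(pos) + window[1] - 1L, NA_integer_)
  as.integer(out)
}

#' Extract candidate 20-mers downstream of the key
#'
#' Candidate A is the 20 bases immediately after the key; when the first base
#' after the key is a G (a stochastic artifact of the construct), candidate B
#' is the 20 bases after that G. Candidates truncated by the read end are
#' dropped; a read without a key yields no candidates.
#'
#' @param seqs Character vector of read sequences.
#' @param key,window Passed to [find_key()].
#' @return data.frame with columns `key_pos`, `cand_a`, `cand_b`
#'   (`NA` where absent).
#' @export
extract_candidates <- function(seqs, key = "CGAAACACC", window = c(16L, 44L)) {
  seqs <- toupper(seqs)
  p <- find_key(seqs, key = key, window = window)
  klen <- nchar(key)
  a_start <- p + klen
  cand_a <- substr(seqs, a_start, a_start + 19L)
  cand_a[is.na(p) | nchar(cand_a) < 20L] <- NA_character_
  has_g <- !is.na(p) & substr(seqs, a_start, a_start) == "G"
  cand_b <- substr(seqs, a_start + 1L, a_start + 20L)
  cand_b[!has_g | nchar(cand_b) < 20L] <- NA_character_
  data.frame(key_pos = p, cand_a = cand_a, cand_b = cand_b,
             stringsAsFactors = FALSE)
}

#' Count guides from demultiplexed reads
#'
#' Matches candidate 20-mers exactly against the library ('N' never matches;
#' no mismatch tolerance). A read whose two candidates match two distinct
#' guides is tallied as ambiguous and the candidate-A match is counted (a
#' deterministic priority rule, reported per sample).
#'
#' @param reads_by_sample Named list of read-sequence vectors (one per sample).
#' @param library sgRNA library data.frame (validated).
#' @param key,window Passed to [find_key()].
#' @return List with `counts` (guides x samples integer matrix, library row
#'   order) and `report` (data.frame, one row per sample: `n_reads`,
#'   `n_no_key`, `n_unmatched`, `n_ambiguous`, `n_assigned`).
#' @export
count_guides <- function(reads_by_sample, library,
                         key = "CGAAACACC", window = c(16L, 44L)) {
  library <- validate_sgrna_library(library)
  samples <- names(reads_by_sample)
  ng <- nrow(library)
  counts <- matrix(0L, nrow = ng, ncol = length(samples),
                   dimnames = list(library$guide_id, samples))
  rep_rows <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    seqs <- reads_by_sample[[i]]
    n <- length(seqs)
    if (n == 0L) {
      rep_rows[[i]] <- data.frame(sample_id = samples[i], n_reads = 0L,
                                  n_no_key = 0L, n_unmatched = 0L,
                                  n_ambiguous = 0L, n_assigned = 0L)
      next
    }
    cand <- extract_candidates(seqs, key = key, window = window)
    ma <- match(cand$cand_a, library$sequence)
    mb <- match(cand$cand_b, library$sequence)
    no_key <- is.na(cand$key_pos)
    both <- !is.na(ma) & !is.na(mb)
    guide <- ifelse(!is.na(ma), ma, mb)  # candidate A wins double matches
    assigned <- !no_key & !is.na(guide) & !both
    ambiguous <- !no_key & both
    unmatched <- !no_key & is.na(guide)
    tab <- tabulate(guide[assigned | ambiguous], nbins = ng)
    counts[, i] <- as.integer(tab)
    rep_rows[[i]] <- data.frame(sample_id = samples[i], n_reads = n,
                                n_no_key = sum(no_key),
                                n_unmatched = sum(unmatched),
                                n_ambiguous = sum(ambiguous),
                                n_assigned = sum(assigned))
  }
  list(counts = counts, report = do.call(rbind, rep_rows))
}

#' Quantify a screen FASTQ into a guide x sample count matrix
#'
#' End-to-end convenience: read FASTQ, demultiplex by the 6-nt sample barcode,
#' locate the key sequence within the window, extract guide candidates, and
#' count exact library matches.
#'
#' @param fastq Path to FASTQ (plain or gzip), or a named character vector of
#'   read sequences.
#' @param library sgRNA library data.frame.
#' @param sheet Sample sheet data.frame.
#' @param key,window Passed to [find_key()].
#' @return List with `counts`, `report` (the per-sample tallies plus an
#'   `(unassigned)` row counting reads matching no barcode) and
#'   `n_unassigned`.
#' @export
quantify_screen <- function(fastq, library, sheet,
                            key = "CGAAACACC", window = c(16L, 44L)) {
  reads <- if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq)) {
    read_fastq_sequences(fastq)
  } else {
    fastq
  }
  dm <- demultiplex(reads, sheet)
  cg <- count_guides(dm$by_sample, library, key = key, window = window)
  report <- rbind(
    cg$report,
    data.frame(sample_id = "(unassigned)", n_reads = dm$n_unassigned,
               n_no_key = NA_integer_, n_unmatched = NA_integer_,
               n_ambiguous = NA_integer_, n_assigned = NA_integer_))
  list(counts = cg$counts, report = report, n_unassigned = dm$n_unassigned)
}
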