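## Seeded generators for every input the pipeline consumes, each returning a
## ground-truth ledger that fully determines the expected output of the
## deterministic stages downstream.

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  chars <- sample(c("A", "C", "G", "T"), n * len, replace = TRUE)
  apply(matrix(chars, nrow = n), 1, paste0, collapse = "")
}

#' Generate a synthetic sgRNA library
#'
#' Unique random 20-mers with guide ids encoding gene membership
#' (`gene_0001_sg1`, ...). Deterministic given the seed.
#'
#' @param n_genes,guides_per_gene Positive integers.
#' @param seed Optional integer seed.
#' @return Library data.frame (`guide_id`, `gene_id`, `sequence`).
#' @export
make_library <- function(n_genes, guides_per_gene, seed = NULL) {
  stopifnot(n_genes > 0L, guides_per_gene > 0L)
  run <- function() {
    n <- n_genes * guides_per_gene
    seqs <- random_dna(n, 20L)
    for (tries in 1:10) {
      dup <- duplicated(seqs)
      if (!any(dup)) break
      seqs[dup] <- random_dna(sum(dup), 20L)
    }
    if (anyDuplicated(seqs)) stop("could not generate unique sequences")
    gene <- sprintf("gene_%04d", rep(seq_len(n_genes), each = guides_per_gene))
    data.frame(
      guide_id = paste0(gene, "_sg", rep(seq_len(guides_per_gene), n_genes)),
      gene_id = gene, sequence = seqs, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate paired negative-binomial screen counts
#'
#' Control counts are NB with mean `depth_per_guide` and variance
#' mu + dispersion * mu^2; treated means for guides of planted genes are
#' scaled by 2^effect before sampling. A shared per-replicate log-normal
#' depth factor couples the two samples of a replicate (the pairing the
#' paired statistic exploits) and an independent per-sample log-normal factor
#' emulates library-size variation (what median-of-ratios normalization
#' removes). `dispersion = 0` switches off all count noise: counts are the
#' rounded means, so the ledger matches exactly.
#'
#' @param library Library data.frame from [make_library()].
#' @param n_replicates Paired replicates (default 2, the screen design).
#' @param depth_per_guide Mean control coverage per guide (default 500).
#' @param nb_dispersion NB dispersion phi (default 0.1).
#' @param planted Named numeric vector gene_id -> log2 effect in treated.
#' @param replicate_sdlog,sample_sdlog Log-normal sd of the per-replicate and
#'   per-sample depth factors.
#' @param seed Optional integer seed.
#' @return List `counts` (guides x samples), `design` (data.frame), `ledger`
#'   (mu matrix, factors, planted effects).
#' @export
simulate_counts <- function(library, n_replicates = 2L, depth_per_guide = 500,
                            nb_dispersion = 0.1, planted = NULL,
                            replicate_sdlog = 0.2, sample_sdlog = 0.15,
                            seed = NULL) {
  stopifnot(n_replicates >= 1L, depth_per_guide > 0, nb_dispersion >= 0)
  run <- function() {
    ng <- nrow(library)
    effect <- rep(0, ng)
    if (!is.null(planted)) {
      stopifnot(!is.null(names(planted)))
      hit <- library$gene_id %in% names(planted)
      effect[hit] <- planted[library$gene_id[hit]]
    }
    reps <- seq_len(n_replicates)
    samples <- c(paste0("control_rep", reps), paste0("treated_rep", reps))
    design <- data.frame(
      sample_id = samples,
      condition = rep(c("control", "treated"), each = n_replicates),
      replicate = paste0("rep", c(reps, reps)),
      stringsAsFactors = FALSE)
    rep_factor <- stats::rlnorm(n_replicates, 0, replicate_sdlog)
    samp_factor <- stats::rlnorm(length(samples), 0, sample_sdlog)
    mu <- matrix(depth_per_guide, ng, length(samples),
                 dimnames = list(library$guide_id, samples))
    for (j in seq_along(samples)) {
      fc <- if (design$condition[j] == "treated") 2^effect else rep(1, ng)
      mu[, j] <- depth_per_guide * fc *
        rep_factor[match(design$replicate[j], paste0("rep", reps))] *
        samp_factor[j]
    }
    counts <- if (nb_dispersion == 0) {
      round(mu)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
             nrow = ng, dimnames = dimnames(mu))
    }
    storage.mode(counts) <- "integer"
    list(counts = counts, design = design,
         ledger = list(mu = mu, effect = stats::setNames(effect, library$guide_id),
                       planted = planted, rep_factor = rep_factor,
                       sample_factor = stats::setNames(samp_factor, samples)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# One read: barcode + stuffer (so the key starts at `offset`) + key +
# optional G + guide + random tail, validated so the first in-window key
# occurrence is the intended one.
assemble_reads <- function(guide_seq, barcode, offsets, g_flag, read_length,
                           key, window) {
  n <- length(guide_seq)
  klen <- nchar(key)
  reads <- character(n)
  for (i in seq_len(n)) {
    for (attempt in 1:20) {
      stuffer <- random_dna(1L, offsets[i] - 1L - nchar(barcode))
      core <- paste0(barcode, stuffer, key,
                     if (g_flag[i]) "G" else "", guide_seq[i])
      tail_len <- read_length - nchar(core)
      if (tail_len < 0L) stop("read layout does not fit read_length")
      read <- paste0(core, random_dna(1L, tail_len))
      if (identical(find_key(read, key = key, window = window),
                    offsets[i])) break
      if (attempt == 20L) stop("could not place key unambiguously")
    }
    reads[i] <- read
  }
  reads
}

#' Simulate reads for one sample from a count vector
#'
#' Emits exactly `counts[g]` reads per guide g with the screen's read layout:
#' a 6-nt sample barcode, a random stuffer placing the key start uniformly in
#' `offset_range`, the key sequence, a G inserted with probability
#' `g_insertion_prob`, the 20-nt guide, and a random tail up to
#' `read_length`. Stuffers are re-drawn in the rare case they would create an
#' earlier in-window key occurrence, so extraction is exact by construction.
#'
#' @param counts Named integer vector (guide_id -> read count).
#' @param library Library data.frame.
#' @param barcode 6-nt sample barcode.
#' @param read_length Read length (default 75).
#' @param key Key sequence (default `CGAAACACC`).
#' @param offset_range Inclusive range of 1-based key start positions.
#' @param g_insertion_prob Probability of the post-key G artifact.
#' @param seed Optional seed.
#' @return Named character vector of reads (names are read ids); attribute
#'   `ledger` holds the per-read guide assignment.
#' @export
simulate_sample_reads <- function(counts, library, barcode, read_length = 75L,
                                  key = "CGAAACACC",
                                  offset_range = c(16L, 44L),
                                  g_insertion_prob = 0.2, seed = NULL) {
  stopifnot(nchar(barcode) == 6L)
  if (offset_range[1] <= nchar(barcode)) {
    stop("key cannot start inside the barcode")
  }
  if (read_length < offset_range[2] + nchar(key) + 20L) {
    stop("read_length too short for the layout")
  }
  run <- function() {
    guides <- rep(names(counts), counts)
    n <- length(guides)
    if (n == 0L) return(structure(character(0), ledger = character(0)))
    guides <- sample(guides)
    offsets <- sample(seq(offset_range[1], offset_range[2]), n, replace = TRUE)
    g_flag <- stats::runif(n) < g_insertion_prob
    seqs <- library$sequence[match(guides, library$guide_id)]
    if (anyNA(seqs)) stop("counts name a guide absent from the library")
    reads <- assemble_reads(seqs, barcode, offsets, g_flag, read_length,
                            key, c(offset_range[1], offset_range[2]))
    names(reads) <- sprintf("read_%s_%06d", barcode, seq_len(n))
    structure(reads, ledger = guides)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a full screen FASTQ from a count matrix
#'
#' Generates reads for every sample column with [simulate_sample_reads()]
#' using the barcodes of the sample sheet, and concatenates them.
#'
#' @param counts Guides x samples count matrix.
#' @param library Library data.frame.
#' @param sheet Sample sheet (barcodes per sample).
#' @param path Optional FASTQ output path (written when non-NULL).
#' @param ... Passed to [simulate_sample_reads()].
#' @param seed Optional seed.
#' @return Named character vector of all reads (invisible when written);
#'   attribute `ledger` is the input count matrix.
#' @export
simulate_screen_fastq <- function(counts, library, sheet, path = NULL, ...,
                                  seed = NULL) {
  run <- function() {
    all_reads <- unlist(lapply(seq_len(nrow(sheet)), function(i) {
      sid <- sheet$sample_id[i]
      simulate_sample_reads(counts[, sid], library,
                            barcode = sheet$barcode[i], ...)
    }))
    structure(all_reads, ledger = counts)
  }
  reads <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (!is.null(path)) {
    write_fastq(reads, path)
    return(invisible(reads))
  }
  reads
}

#' Simulate a cell-line panel with a planted gene-drug-class effect
#'
#' Expression is standard normal per gene and line. The target gene's
#' standardized expression z drives two things: the aneuploidy score
#' (`aneuploidy = coupling * z + noise`, the mediation structure — any
#' aneuploidy-response association exists only through the target gene) and
#' the response of drugs in the target class
#' (`response = -effect * z + noise`; lower response = more sensitive, so
#' high target expression means sensitivity). All other gene-drug pairs are
#' null.
#'
#' @param n_lines,n_genes,n_drugs Panel dimensions (defaults 200, 2000, 100).
#' @param target_gene Identifier of the driver gene (default `gene_0001`).
#' @param target_class Class label of the planted drugs (default `MPS1i`).
#' @param n_class_drugs Number of drugs in the planted class (default 5).
#' @param effect Planted effect size in response units per expression sd.
#' @param aneuploidy_coupling Mediation strength in (0, 1]; 0 decouples the
#'   aneuploidy score from the target gene entirely.
#' @param noise_sd Response noise sd (default 1).
#' @param seed Optional seed.
#' @return List `panel` (a [panel_bundle()]) and `ledger` (planted drugs,
#'   effect, coupling, target z).
#' @export
simulate_panel <- function(n_lines = 200L, n_genes = 2000L, n_drugs = 100L,
                           target_gene = "gene_0001", target_class = "MPS1i",
                           n_class_drugs = 5L, effect = 1.0,
                           aneuploidy_coupling = 0.8, noise_sd = 1,
                           seed = NULL) {
  stopifnot(n_lines >= 40L, n_class_drugs <= n_drugs)
  run <- function() {
    lines <- sprintf("line_%04d", seq_len(n_lines))
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    if (!target_gene %in% genes) genes[1] <- target_gene
    drugs <- sprintf("drug_%03d", seq_len(n_drugs))
    expression <- matrix(stats::rnorm(n_genes * n_lines), n_genes,
                         dimnames = list(genes, lines))
    z <- as.numeric(scale(expression[target_gene, ]))
    resid_sd <- sqrt(max(1 - aneuploidy_coupling^2, 0.04))
    aneuploidy <- stats::setNames(
      aneuploidy_coupling * z + stats::rnorm(n_lines, sd = resid_sd), lines)
    response <- matrix(stats::rnorm(n_drugs * n_lines, sd = noise_sd),
                       n_drugs, dimnames = list(drugs, lines))
    class_drugs <- drugs[seq_len(n_class_drugs)]
    for (d in class_drugs) response[d, ] <- response[d, ] - effect * z
    drug_class <- stats::setNames(
      ifelse(drugs %in% class_drugs, target_class, "other"), drugs)
    list(panel = panel_bundle(expression, response, aneuploidy, drug_class),
         ledger = list(target_gene = target_gene, class_drugs = class_drugs,
                       effect = effect,
                       aneuploidy_coupling = aneuploidy_coupling,
                       target_z = stats::setNames(z, lines)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate mitotic-event tables from per-condition severity distributions
#'
#' Draws each event's severity score from the condition's distribution over
#' scores 0-5, maps the score to a canonical category (uniformly among the
#' categories sharing that score), and draws a metaphase duration from a
#' normal truncated at zero.
#'
#' @param score_probs Named list: per condition a length-6 probability vector
#'   over scores 0..5 (each summing to 1).
#' @param duration_mean,duration_sd Named numeric per condition (minutes).
#' @param n_per_condition Events per condition (single number or named).
#' @param seed Optional seed.
#' @return List `events` (data.frame `cell_id`, `condition`, `category`,
#'   `other_score`, `duration_min`) and `ledger` (drawn scores per condition).
#' @export
simulate_events <- function(score_probs, duration_mean, duration_sd,
                            n_per_condition, seed = NULL) {
  stopifnot(all(vapply(score_probs, length, integer(1)) == 6L))
  if (any(abs(vapply(score_probs, sum, numeric(1)) - 1) > 1e-8)) {
    stop("each score distribution must sum to 1")
  }
  vocab <- severity_vocabulary()
  cats_by_score <- split(names(vocab), vocab)
  run <- function() {
    conds <- names(score_probs)
    n <- rep_len(n_per_condition, length(conds))
    names(n) <- conds
    rows <- lapply(conds, function(cc) {
      scores <- sample(0:5, n[[cc]], replace = TRUE, prob = score_probs[[cc]])
      category <- vapply(scores, function(s) {
        opts <- cats_by_score[[as.character(s)]]
        opts[sample.int(length(opts), 1L)]
      }, character(1))
      dur <- stats::rnorm(n[[cc]], duration_mean[[cc]], duration_sd[[cc]])
      while (any(dur < 0)) {
        dur[dur < 0] <- stats::rnorm(sum(dur < 0), duration_mean[[cc]],
                                     duration_sd[[cc]])
      }
      data.frame(cell_id = sprintf("%s_cell_%04d", cc, seq_len(n[[cc]])),
                 condition = cc, category = category,
                 other_score = NA_integer_, duration_min = dur,
                 stringsAsFactors = FALSE)
    })
    events <- do.call(rbind, rows)
    ledger <- lapply(conds, function(cc) {
      tabulate(score_category(events$category[events$condition == cc])$score + 1L,
               nbins = 6L)
    })
    names(ledger) <- conds
    list(events = events, ledger = ledger)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
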