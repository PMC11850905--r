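#' Median-of-ratios size factors
#'
#' Per-sample normalization factor: the median, across guides whose counts
#' are positive in every sample, of the ratio of the guide's count to its
#' across-sample geometric mean.
#'
#' @param counts Non-negative guides x samples matrix.
#' @param pseudocount Optional pseudocount added to all counts before the
#'   geometric means (default 0 = the standard convention, in which guides
#'   containing any zero are excluded from the reference set).
#' @return Named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts, pseudocount = 0) {
  m <- counts + pseudocount
  loggeo <- rowMeans(log(m))
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("no guide has positive counts in all samples; ",
         "consider pseudocount > 0")
  }
  geo <- exp(loggeo[use])
  apply(m[use, , drop = FALSE], 2, function(x) stats::median(x / geo))
}

#' Drop guides with zero counts in every sample
#'
#' @param counts Guides x samples matrix.
#' @return The matrix with all-zero rows removed, order preserved.
#' @export
filter_zero_guides <- function(counts) {
  counts[rowSums(counts != 0) > 0L, , drop = FALSE]
}

#' Normalize counts by size factors
#'
#' @param counts Guides x samples matrix.
#' @param sf Size factors from [size_factors()]; computed if missing.
#' @return Matrix of counts divided column-wise by the factors.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(counts, 2, sf, "/")
}

#' Build a paired screen design
#'
#' @param sample_id,condition,replicate Equal-length vectors; `condition`
#'   must use the labels "control" and "treated", and every replicate must
#'   pair exactly one sample of each condition.
#' @return data.frame with those columns, validated.
#' @export
screen_design <- function(sample_id, condition, replicate) {
  design <- data.frame(sample_id = as.character(sample_id),
                       condition = as.character(condition),
                       replicate = as.character(replicate),
                       stringsAsFactors = FALSE)
  validate_screen_design(design)
}

validate_screen_design <- function(design) {
  if (!all(design$condition %in% c("control", "treated"))) {
    stop("condition labels must be 'control' or 'treated'")
  }
  tab <- table(design$replicate, design$condition)
  if (!all(tab == 1L)) {
    stop("every replicate must have exactly one control and one treated sample")
  }
  design
}

#' Per-guide paired differential enrichment
#'
#' For each guide, the per-replicate log2 ratio
#' d_i = log2(treated_i + c) - log2(control_i + c) is computed from
#' normalized counts; `log2fc` is mean(d). Two statistics are available:
#'
#' * `"moderated"` (default): empirical-Bayes moderated paired t on the
#'   per-replicate log ratios (limma `lmFit`/`eBayes`, intercept-only design),
#'   which stabilises the variance estimate at small replicate numbers — the
#'   screen design here has only two paired replicates, where a raw
#'   1-degree-of-freedom t is Cauchy-tailed under the null and scrambles the
#'   ranking that robust rank aggregation consumes.
#' * `"t"`: the plain paired t, stat = mean(d) / (sd(d)/sqrt(m)) with a
#'   two-sided p from the t distribution on m-1 df. Guides with sd(d) = 0 get
#'   stat = 0, p = 1 when log2fc = 0, and otherwise have sd clamped to the
#'   smallest positive sd observed.
#'
#' @param norm_counts Normalized guides x samples matrix.
#' @param design Paired design data.frame (see [screen_design()]).
#' @param pseudocount Added inside the log ratios (default 0.5).
#' @param method `"moderated"` or `"t"`.
#' @return data.frame: `guide`, `log2fc`, `stat`, `p`.
#' @export
paired_differential <- function(norm_counts, design, pseudocount = 0.5,
                                method = c("moderated", "t")) {
  method <- match.arg(method)
  design <- validate_screen_design(design)
  reps <- unique(design$replicate)
  m <- length(reps)
  if (m < 2L) stop("at least 2 paired replicates are required")
  col_of <- function(cond, rep) {
    design$sample_id[design$condition == cond & design$replicate == rep]
  }
  d <- vapply(reps, function(rr) {
    log2(norm_counts[, col_of("treated", rr)] + pseudocount) -
      log2(norm_counts[, col_of("control", rr)] + pseudocount)
  }, numeric(nrow(norm_counts)))
  log2fc <- rowMeans(d)
  if (method == "moderated") {
    fit <- limma::lmFit(d, design = matrix(1, m, 1))
    eb <- limma::eBayes(fit)
    stat <- eb$t[, 1]
    p <- eb$p.value[, 1]
  } else {
    sdd <- sqrt(rowSums((d - log2fc)^2) / (m - 1))
    zero_sd <- sdd == 0
    if (any(zero_sd)) {
      pos <- sdd[!zero_sd]
      if (length(pos)) {
        sdd[zero_sd & log2fc != 0] <- min(pos)
      } else {
        warning("all guides have zero log-ratio variance; statistics set to 0")
      }
    }
    stat <- ifelse(sdd == 0, 0, log2fc / (sdd / sqrt(m)))
    p <- ifelse(sdd == 0 & log2fc == 0, 1,
                2 * stats::pt(-abs(stat), df = m - 1))
    p[sdd == 0 & log2fc != 0 & !is.finite(stat)] <- 0
  }
  data.frame(guide = rownames(norm_counts), log2fc = log2fc,
             stat = stat, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Rank guides on the test statistic
#'
#' Normalized rank r = position / n with the most enriched (stat descending)
#' or most depleted (stat ascending) guide on top; ties broken by guide id.
#'
#' @param diff Differential table from [paired_differential()].
#' @param direction `"enriched"` or `"depleted"`.
#' @return data.frame `guide`, `r`, `direction`, in rank order.
#' @export
rank_guides <- function(diff, direction = c("enriched", "depleted")) {
  direction <- match.arg(direction)
  ord <- if (direction == "enriched") {
    order(-diff$stat, diff$guide)
  } else {
    order(diff$stat, diff$guide)
  }
  n <- nrow(diff)
  data.frame(guide = diff$guide[ord], r = seq_len(n) / n,
             direction = direction, row.names = NULL,
             stringsAsFactors = FALSE)
}

rho_alpha <- function(r_sorted, alpha) {
  k <- length(r_sorted)
  sel <- r_sorted < alpha
  if (!any(sel)) return(list(rho = 1, k_sel = 0L))
  j <- seq_len(k)
  list(rho = min(stats::pbeta(r_sorted[sel], j[sel], k - j[sel] + 1)),
       k_sel = sum(sel))
}

#' Alpha-robust rank aggregation gene scores
#'
#' Scores each gene by how improbably concentrated its guides' normalized
#' ranks are among the top `alpha` fraction: with the gene's sorted ranks
#' r(1) <= ... <= r(k), only r(j) < alpha contribute, and
#' rho = min_j P(Beta(j, k-j+1) <= r(j)) — the probability that the j-th
#' order statistic of k uniform ranks falls below r(j). rho = 1 when no rank
#' clears alpha. The permutation p-value compares the observed rho with rho
#' values of k ranks redrawn from the pooled rank list (a shared null per
#' distinct k), using the (1 + b) / (n_perm + 1) estimator; FDR is
#' Benjamini-Hochberg across genes.
#'
#' @param ranks Ranked guide list from [rank_guides()] (columns `guide`, `r`).
#' @param gene_map Named character vector guide -> gene, or a library
#'   data.frame with `guide_id` and `gene_id`.
#' @param alpha Maximum normalized rank entering the score, in (0, 1].
#' @param n_perm Number of permutations (default 100).
#' @param seed Optional integer seed for the permutation null.
#' @return data.frame `gene`, `rho`, `p_perm`, `fdr`, `k`, `k_sel`, ordered
#'   by increasing rho (ties by gene id).
#' @export
alpha_rra <- function(ranks, gene_map, alpha = 0.25, n_perm = 100L,
                      seed = NULL) {
  stopifnot(alpha > 0, alpha <= 1, n_perm >= 1L)
  if (is.data.frame(gene_map)) {
    gene_map <- stats::setNames(gene_map$gene_id, gene_map$guide_id)
  }
  gene <- unname(gene_map[ranks$guide])
  known <- !is.na(gene)
  if (any(!known)) {
    warning(sum(!known), " guide(s) missing from the gene map were dropped")
  }
  r <- ranks$r[known]
  gene <- gene[known]
  if (!length(r)) stop("no guides left after gene-map lookup")
  by_gene <- split(r, gene)
  obs <- lapply(by_gene, function(v) rho_alpha(sort(v), alpha))
  rho <- vapply(obs, `[[`, numeric(1), "rho")
  k_sel <- vapply(obs, `[[`, integer(1), "k_sel")
  k <- lengths(by_gene)

  null_for_k <- function(kk) {
    draws <- matrix(sample(r, n_perm * kk, replace = TRUE), n_perm, kk)
    sm <- t(apply(draws, 1, sort))
    if (kk == 1L) sm <- matrix(sm, ncol = 1L)
    j <- seq_len(kk)
    pb <- stats::pbeta(sm, rep(j, each = n_perm),
                       rep(kk - j + 1, each = n_perm))
    pb[sm >= alpha] <- 1
    sort(do.call(pmin, c(as.data.frame(pb), list(1))))
  }
  run <- function() {
    nulls <- lapply(sort(unique(k)), null_for_k)
    names(nulls) <- as.character(sort(unique(k)))
    vapply(seq_along(rho), function(i) {
      nl <- nulls[[as.character(k[i])]]
      (1 + findInterval(rho[i], nl)) / (n_perm + 1)
    }, numeric(1))
  }
  p_perm <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- data.frame(gene = names(by_gene), rho = unname(rho),
                    p_perm = p_perm, fdr = bh_adjust(p_perm),
                    k = as.integer(unname(k)), k_sel = unname(k_sel),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$rho, out$p_perm, out$gene), , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Step-up adjusted p-values (same order as input).
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Intersect the top fraction of two screens
#'
#' Takes each screen's top `floor(fraction * n)` genes by permutation p-value
#' (ties broken by rho, then gene id) and returns the intersection together
#' with both screens' -log10 p-values for the shared genes.
#'
#' @param screen_a,screen_b Gene score tables from [alpha_rra()].
#' @param fraction Fraction of each screen's genes to keep, in (0, 1].
#' @return List with `genes` and `table`
#'   (`gene`, `neglog10_p_a`, `neglog10_p_b`).
#' @export
top_fraction_intersection <- function(screen_a, screen_b, fraction = 0.25) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!length(intersect(screen_a$gene, screen_b$gene))) {
    stop("the two screens share no genes")
  }
  top_of <- function(tab) {
    ord <- order(tab$p_perm, tab$rho, tab$gene)
    tab$gene[ord][seq_len(floor(fraction * nrow(tab)))]
  }
  genes <- intersect(top_of(screen_a), top_of(screen_b))
  pa <- screen_a$p_perm[match(genes, screen_a$gene)]
  pb <- screen_b$p_perm[match(genes, screen_b$gene)]
  list(genes = genes,
       table = data.frame(gene = genes, neglog10_p_a = -log10(pa),
                          neglog10_p_b = -log10(pb),
                          stringsAsFactors = FALSE))
}

running_es <- function(ord_scores, inset, weight) {
  n <- length(ord_scores)
  w <- abs(ord_scores)^weight * inset
  nr <- sum(w)
  if (nr == 0) w[inset] <- 1 / sum(inset) else w <- w / nr
  dec <- (!inset) / (n - sum(inset))
  walk <- cumsum(w - dec)
  walk[which.max(abs(walk))]
}

#' Preranked gene-set enrichment score
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment of a gene set in a
#' ranking (genes sorted by score, descending): set members increment the walk
#' by |score|^weight normalized over the set, others decrement by
#' 1/(n - set size); ES is the signed maximum deviation. The permutation
#' p-value redraws the set membership labels.
#'
#' @param scores Named numeric vector (e.g. per-gene log2 fold change).
#' @param gene_set Character vector, a subset of `names(scores)`.
#' @param weight Non-negative exponent on |score| (default 1).
#' @param n_perm Number of label permutations.
#' @param seed Optional seed.
#' @return List `es` (in \[-1, 1\]), `p_perm`, `set_size`.
#' @export
gsea_enrichment <- function(scores, gene_set, weight = 1, n_perm = 1000L,
                            seed = NULL) {
  stopifnot(weight >= 0)
  if (!length(gene_set)) stop("gene_set is empty")
  if (!all(gene_set %in% names(scores))) {
    stop("gene_set must be a subset of the ranked universe")
  }
  m <- length(unique(gene_set))
  n <- length(scores)
  if (m >= n) stop("gene_set must be a strict subset of the universe")
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  inset <- names(s) %in% gene_set
  es <- running_es(s, inset, weight)
  run <- function() {
    null_es <- vapply(seq_len(n_perm), function(b) {
      running_es(s, seq_len(n) %in% sample.int(n, m), weight)
    }, numeric(1))
    if (es >= 0) {
      (1 + sum(null_es >= es)) / (n_perm + 1)
    } else {
      (1 + sum(null_es <= es)) / (n_perm + 1)
    }
  }
  p <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(es = unname(es), p_perm = p, set_size = m)
}

#' Cells required to maintain screen coverage
#'
#' ceiling(coverage x library size / surviving fraction): the cell number
#' needed so that, after losses, every guide is still represented `coverage`
#' times on average.
#'
#' @param coverage Fold representation per guide (e.g. 500).
#' @param library_size Number of guides in the library.
#' @param surviving_fraction Fraction of cells expected to survive
#'   transduction/selection, in (0, 1].
#' @return Integer-valued cell count.
#' @export
required_cells <- function(coverage, library_size, surviving_fraction) {
  stopifnot(coverage > 0, library_size > 0)
  if (surviving_fraction <= 0 || surviving_fraction > 1) {
    stop("surviving_fraction must be in (0, 1]")
  }
  ceiling(coverage * library_size / surviving_fraction)
}

#' Full screen scoring pipeline: counts to gene scores
#'
#' Filters all-zero guides, normalizes by median-of-ratios size factors, runs
#' the paired differential statistic, ranks in the requested direction and
#' aggregates ranks per gene with alpha-RRA. With `alpha = "auto"` the
#' selection threshold is the proportion of guides whose statistic is
#' positive (enriched) or negative (depleted), mirroring the usual maximum-
#' percentile convention.
#'
#' @param counts Raw guides x samples count matrix.
#' @param design Paired design (see [screen_design()]).
#' @param gene_map Guide -> gene map or library data.frame.
#' @param direction `"enriched"` or `"depleted"`.
#' @param alpha `"auto"` or a numeric threshold in (0, 1].
#' @param n_perm,seed Passed to [alpha_rra()].
#' @param method,pseudocount Passed to [paired_differential()].
#' @return List: `differential`, `ranks`, `gene_scores`, `alpha`,
#'   `size_factors`.
#' @export
screen_gene_scores <- function(counts, design, gene_map,
                               direction = c("enriched", "depleted"),
                               alpha = "auto", n_perm = 100L, seed = NULL,
                               method = "moderated", pseudocount = 0.5) {
  direction <- match.arg(direction)
  counts <- filter_zero_guides(counts)
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  diff <- paired_differential(norm, design, pseudocount = pseudocount,
                              method = method)
  if (identical(alpha, "auto")) {
    alpha <- if (direction == "enriched") {
      mean(diff$stat > 0)
    } else {
      mean(diff$stat < 0)
    }
    alpha <- max(alpha, 1 / nrow(diff))  # guard a degenerate all-one-sided table
  }
  ranks <- rank_guides(diff, direction)
  scores <- alpha_rra(ranks, gene_map, alpha = alpha, n_perm = n_perm,
                      seed = seed)
  list(differential = diff, ranks = ranks, gene_scores = scores,
       alpha = alpha, size_factors = sf)
}
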