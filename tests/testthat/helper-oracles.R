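# Independent brute-force oracles used across the suite. Each is a direct,
# loop-level transcription of the defining formula, deliberately kept apart
# from the package's vectorized implementations.

oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

oracle_size_factors <- function(counts) {
  ng <- nrow(counts)
  geo <- vapply(seq_len(ng), function(g) {
    exp(mean(log(counts[g, ])))
  }, numeric(1))
  keep <- which(apply(counts, 1, function(x) all(x > 0)))
  vapply(seq_len(ncol(counts)), function(s) {
    stats::median(counts[keep, s] / geo[keep])
  }, numeric(1))
}

oracle_ssgsea <- function(expr, gene_set, exponent) {
  nm <- names(expr)
  ord <- order(-expr, nm)
  genes <- nm[ord]
  n <- length(genes)
  rank_val <- n:1
  inset <- genes %in% gene_set
  denom_in <- sum(rank_val[inset]^exponent)
  total <- 0
  for (i in seq_len(n)) {
    p_in <- sum((rank_val^exponent * inset)[seq_len(i)]) / denom_in
    p_out <- sum(!inset[seq_len(i)]) / sum(!inset)
    total <- total + (p_in - p_out)
  }
  total
}

oracle_gsea_es <- function(scores, gene_set, weight) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  inset <- names(s) %in% gene_set
  nr <- sum(abs(s[inset])^weight)
  walk <- 0
  best <- 0
  for (i in seq_along(s)) {
    walk <- walk + if (inset[i]) abs(s[i])^weight / nr else
      -1 / (length(s) - sum(inset))
    if (abs(walk) > abs(best)) best <- walk
  }
  unname(best)
}

# Tie-corrected Kruskal-Wallis H from the textbook rank formula.
oracle_kruskal_h <- function(groups) {
  values <- unlist(groups)
  n_tot <- length(values)
  rk <- rank(values)
  grp <- rep(seq_along(groups), lengths(groups))
  h <- 0
  for (g in seq_along(groups)) {
    rbar <- mean(rk[grp == g])
    h <- h + lengths(groups)[g] * (rbar - (n_tot + 1) / 2)^2
  }
  h <- 12 / (n_tot * (n_tot + 1)) * h
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n_tot^3 - n_tot)
  h / correction
}

# Closed-form Beta order-statistic CDFs for k <= 3 (minimum over selected j).
oracle_rho_k3 <- function(r_sorted, alpha) {
  k <- length(r_sorted)
  cdf <- function(x, j) {
    if (k == 1) x
    else if (k == 2 && j == 1) 1 - (1 - x)^2
    else if (k == 2 && j == 2) x^2
    else if (k == 3 && j == 1) 1 - (1 - x)^3
    else if (k == 3 && j == 2) x^2 * (3 - 2 * x)
    else x^3
  }
  vals <- vapply(seq_len(k), function(j) cdf(r_sorted[j], j), numeric(1))
  sel <- r_sorted < alpha
  if (!any(sel)) 1 else min(vals[sel])
}

ks_uniform <- function(p) {
  n <- length(p)
  s <- sort(p)
  max(abs(s - seq_len(n) / n), abs(s - (seq_len(n) - 1) / n))
}
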