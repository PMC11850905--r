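#' Assemble a cell-line panel bundle
#'
#' Inner-joins the components on shared cell-line identifiers. Response values
#' follow the usual panel convention: lower = more sensitive (log-fold-change
#' viability / dependency score).
#'
#' @param expression Genes x lines numeric matrix (line ids as colnames).
#' @param response Drugs x lines numeric matrix, lower = more sensitive.
#' @param aneuploidy Named per-line numeric score (optional).
#' @param drug_class Named per-drug character class labels (optional).
#' @return List of class `panel_bundle` with the four components restricted
#'   to the shared line set.
#' @export
panel_bundle <- function(expression, response, aneuploidy = NULL,
                         drug_class = NULL) {
  lines <- intersect(colnames(expression), colnames(response))
  if (!is.null(aneuploidy)) lines <- intersect(lines, names(aneuploidy))
  if (length(lines) < 8L) stop("fewer than 8 shared cell lines")
  out <- list(expression = expression[, lines, drop = FALSE],
              response = response[, lines, drop = FALSE],
              aneuploidy = if (is.null(aneuploidy)) NULL else aneuploidy[lines],
              drug_class = drug_class,
              lines = lines)
  class(out) <- "panel_bundle"
  out
}

#' @export
print.panel_bundle <- function(x, ...) {
  cat("panel_bundle:", nrow(x$expression), "genes x", length(x$lines),
      "lines;", nrow(x$response), "drugs",
      if (!is.null(x$aneuploidy)) "; aneuploidy scores present" else "", "\n")
  invisible(x)
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Ranks the genes of one profile by expression (descending, ties broken by
#' gene name) and accumulates the difference between the weighted in-set
#' empirical CDF — weights are rank values raised to `exponent` — and the
#' unweighted out-of-set ECDF. The score depends on the expression values
#' only through their ranks, so it is invariant under any strictly monotone
#' transform of the profile.
#'
#' @param expr_profile Named numeric vector: one cell line's gene values.
#' @param gene_set Character vector, non-empty strict subset of the universe.
#' @param exponent Rank weight exponent (default 0.25, the usual choice).
#' @return Single numeric enrichment score.
#' @export
ssgsea <- function(expr_profile, gene_set, exponent = 0.25) {
  if (!length(gene_set)) stop("gene_set is empty")
  nm <- names(expr_profile)
  if (!all(gene_set %in% nm)) stop("gene_set must be a subset of the universe")
  n <- length(expr_profile)
  m <- length(unique(gene_set))
  if (m >= n) stop("gene_set equal to the whole universe: out-of-set ECDF undefined")
  ord <- order(-expr_profile, nm)
  inset <- nm[ord] %in% gene_set
  rank_val <- n - seq_len(n) + 1  # highest expression gets rank n
  w <- rank_val^exponent * inset
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inset) / (n - m)
  sum(p_in - p_out)
}

#' Score several signatures over all lines of a panel
#'
#' @param panel A `panel_bundle`.
#' @param signatures Named list of gene sets (e.g. from [read_gmt()]).
#' @param exponent Passed to [ssgsea()].
#' @return Signatures x lines numeric matrix.
#' @export
signature_scores <- function(panel, signatures, exponent = 0.25) {
  out <- vapply(panel$lines, function(l) {
    prof <- panel$expression[, l]
    vapply(signatures, function(gs) {
      ssgsea(prof, intersect(gs, rownames(panel$expression)),
             exponent = exponent)
    }, numeric(1))
  }, numeric(length(signatures)))
  matrix(out, nrow = length(signatures),
         dimnames = list(names(signatures), panel$lines))
}

#' Bottom- and top-quartile group membership
#'
#' Bottom = values at or below the 25th percentile, top = values at or above
#' the 75th (linear-interpolation quantiles, boundary ties included). The
#' groups are disjoint by construction unless the two quantiles coincide,
#' which is an error.
#'
#' @param values Numeric vector (NA allowed; at least 8 non-missing values).
#' @param probs Length-2 quantile probabilities (default c(0.25, 0.75)).
#' @return List with integer index vectors `bottom` and `top`.
#' @export
quartile_groups <- function(values, probs = c(0.25, 0.75)) {
  ok <- is.finite(values)
  if (sum(ok) < 8L) stop("need at least 8 non-missing values for a quartile split")
  q <- stats::quantile(values[ok], probs = probs, type = 7, names = FALSE)
  if (q[1] >= q[2]) stop("no quartile split: quantiles coincide (constant or heavily tied values)")
  list(bottom = which(ok & values <= q[1]),
       top = which(ok & values >= q[2]))
}

welch_or_pooled <- function(x, y, var_equal = FALSE) {
  delta <- mean(x) - mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (delta == 0) return(list(t = 0, p = 1, delta = delta))
    return(list(t = sign(delta) * Inf, p = 0, delta = delta))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value, delta = delta)
}

#' Top- vs bottom-quartile association t-test
#'
#' Splits the lines by the feature's quartiles (see [quartile_groups()]) and
#' compares the response of the top group against the bottom group with a
#' two-sided two-sample t-test (Welch by default, pooled with
#' `var_equal = TRUE`). `delta` is top mean minus bottom mean.
#'
#' @param feature Per-line numeric vector (e.g. a gene's expression).
#' @param response Per-line numeric vector (lower = more sensitive).
#' @param var_equal Pooled-variance t instead of Welch.
#' @param min_group Minimum lines per group after missing-data removal.
#' @return List `delta`, `t_stat`, `p`, `n_top`, `n_bottom`.
#' @export
quartile_t_test <- function(feature, response, var_equal = FALSE,
                            min_group = 2L) {
  stopifnot(length(feature) == length(response))
  ok <- is.finite(feature) & is.finite(response)
  f <- ifelse(ok, feature, NA_real_)
  grp <- quartile_groups(f)
  top <- response[intersect(grp$top, which(ok))]
  bottom <- response[intersect(grp$bottom, which(ok))]
  if (length(top) < min_group || length(bottom) < min_group) {
    stop("fewer than ", min_group, " lines in a quartile group")
  }
  res <- welch_or_pooled(top, bottom, var_equal = var_equal)
  list(delta = res$delta, t_stat = res$t, p = res$p,
       n_top = length(top), n_bottom = length(bottom))
}

#' Remove a linear covariate from a response (partialization)
#'
#' Ordinary least-squares residuals of `response ~ covariate` (with
#' intercept), computed on complete pairs; residuals have zero mean and zero
#' sample covariance with the covariate. Positions with missing data keep NA.
#'
#' @param response,covariate Equal-length numeric vectors.
#' @return Numeric vector of residuals (NA where either input was missing).
#' @export
partial_out <- function(response, covariate) {
  stopifnot(length(response) == length(covariate))
  ok <- is.finite(response) & is.finite(covariate)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(covariate[ok]) == 0) stop("covariate is constant")
  fit <- stats::lm(response[ok] ~ covariate[ok])
  out <- rep(NA_real_, length(response))
  out[ok] <- stats::resid(fit)
  out
}

#' Aneuploidy-quartile response association, raw and partialized
#'
#' Splits lines into near-diploid (bottom aneuploidy quartile) and highly
#' aneuploid (top quartile) groups and tests the response difference; when a
#' covariate (e.g. a mediator gene's expression) is supplied, the test is
#' repeated on the residuals after [partial_out()].
#'
#' @param response Per-line numeric response (lower = more sensitive).
#' @param aneuploidy Per-line aneuploidy score.
#' @param covariate Optional per-line covariate to partial out.
#' @param var_equal,min_group Passed to [quartile_t_test()].
#' @return List `raw` and `partialized` (NULL without a covariate), each an
#'   association result as from [quartile_t_test()].
#' @export
aneuploidy_association <- function(response, aneuploidy, covariate = NULL,
                                   var_equal = FALSE, min_group = 2L) {
  raw <- quartile_t_test(aneuploidy, response, var_equal = var_equal,
                         min_group = min_group)
  part <- NULL
  if (!is.null(covariate)) {
    resid <- partial_out(response, covariate)
    part <- quartile_t_test(aneuploidy, resid, var_equal = var_equal,
                            min_group = min_group)
  }
  list(raw = raw, partialized = part)
}

# Vectorized Welch/pooled quartile t-tests of one drug's response against
# every gene's expression quartile split, from precomputed group masks.
# Returns delta, t, p, n_top, n_bottom per gene (NA where a group is short).
quartile_tests_engine <- function(top_mask, bottom_mask, y, var_equal,
                                  min_group) {
  f <- as.numeric(is.finite(y))
  y0 <- ifelse(is.finite(y), y, 0)
  moments <- function(mask) {
    n <- as.vector(mask %*% f)
    s1 <- as.vector(mask %*% y0)
    s2 <- as.vector(mask %*% (y0^2))
    mu <- s1 / n
    v <- (s2 - s1^2 / n) / (n - 1)
    list(n = n, mu = mu, v = pmax(v, 0))
  }
  a <- moments(top_mask)
  b <- moments(bottom_mask)
  bad <- a$n < min_group | b$n < min_group
  delta <- a$mu - b$mu
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$v + (b$n - 1) * b$v) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$v / a$n
    vb <- b$v / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- delta / se
  p <- 2 * stats::pt(-abs(t), df)
  zero_se <- which(is.finite(delta) & !is.na(se) & se == 0)
  t[zero_se] <- ifelse(delta[zero_se] == 0, 0, sign(delta[zero_se]) * Inf)
  p[zero_se] <- ifelse(delta[zero_se] == 0, 1, 0)
  t[bad] <- NA_real_
  p[bad] <- NA_real_
  list(delta = delta, t = t, p = p, n_top = a$n, n_bottom = b$n)
}

#' Genome-wide gene-drug ranking percentile of a target gene
#'
#' For every drug, runs the top- vs bottom-expression-quartile t-test for
#' every gene, ranks the genes by ascending p-value (ties broken by gene id)
#' and records the percentile of the target gene. With the default
#' `direction = "significance"`, percentile = 100 x (1 - (rank - 1)/n), so
#' 100 means the target is the drug's most significantly associated gene;
#' `direction = "rank"` reports the plain rank percentile (low = best).
#'
#' @param panel A `panel_bundle`.
#' @param target_gene Gene identifier present in the expression matrix.
#' @param direction `"significance"` (100 = most significant) or `"rank"`.
#' @param var_equal Pooled t instead of Welch.
#' @param min_group Minimum lines per quartile group (10 at panel scale;
#'   lower it for toy fixtures).
#' @param genes Optional gene subset to rank within (target included).
#' @return data.frame `drug`, `class`, `percentile`, `p_target`, `rank`,
#'   `n_genes`; drugs with too few usable lines are dropped with a warning.
#' @export
gene_drug_percentiles <- function(panel, target_gene,
                                  direction = c("significance", "rank"),
                                  var_equal = FALSE, min_group = 10L,
                                  genes = NULL) {
  direction <- match.arg(direction)
  expr <- panel$expression
  if (!is.null(genes)) {
    expr <- expr[union(genes, target_gene), , drop = FALSE]
  }
  if (!target_gene %in% rownames(expr)) {
    stop("target gene not in the expression matrix")
  }
  qs <- t(apply(expr, 1, stats::quantile, probs = c(0.25, 0.75),
                na.rm = TRUE, type = 7))
  degenerate <- qs[, 1] >= qs[, 2]
  em <- expr
  em[!is.finite(em)] <- NA
  top_mask <- (em >= qs[, 2]) & !degenerate
  bottom_mask <- (em <= qs[, 1]) & !degenerate
  top_mask[is.na(top_mask)] <- FALSE
  bottom_mask[is.na(bottom_mask)] <- FALSE
  storage.mode(top_mask) <- "double"
  storage.mode(bottom_mask) <- "double"
  gene_ids <- rownames(expr)
  rows <- lapply(rownames(panel$response), function(d) {
    y <- panel$response[d, ]
    res <- quartile_tests_engine(top_mask, bottom_mask, y, var_equal,
                                 min_group)
    p <- res$p
    pt <- p[match(target_gene, gene_ids)]
    if (!is.finite(pt)) return(NULL)
    usable <- is.finite(p)
    n_eff <- sum(usable)
    rank <- 1L + sum(p[usable] < pt) +
      sum(p[usable] == pt & gene_ids[usable] < target_gene)
    pct <- if (direction == "significance") {
      100 * (1 - (rank - 1) / n_eff)
    } else {
      100 * rank / n_eff
    }
    data.frame(drug = d,
               class = if (is.null(panel$drug_class)) NA_character_ else
                 unname(panel$drug_class[d]),
               percentile = pct, p_target = pt, rank = rank,
               n_genes = n_eff, stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) {
    warning(dropped, " drug(s) dropped (too few usable lines for the target test)")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no drug had enough usable lines")
  rownames(out) <- NULL
  out
}

#' Compare a drug class's percentiles against all other drugs
#'
#' Two-sample t-test (Welch by default) of the target gene's ranking
#' percentiles for the class of interest versus all remaining drugs.
#'
#' @param profile Ranking profile from [gene_drug_percentiles()].
#' @param class_of_interest Drug class label.
#' @param var_equal Pooled t instead of Welch.
#' @return List `t_stat`, `p`, `mean_in`, `mean_out`, `n_in`, `n_out`.
#' @export
compare_drug_classes <- function(profile, class_of_interest,
                                 var_equal = FALSE) {
  inside <- profile$percentile[profile$class == class_of_interest]
  outside <- profile$percentile[profile$class != class_of_interest]
  if (length(inside) < 2L) stop("need at least 2 drugs in the class of interest")
  if (length(outside) < 2L) stop("need at least 2 drugs outside the class")
  res <- welch_or_pooled(inside, outside, var_equal = var_equal)
  list(t_stat = res$t, p = res$p, mean_in = mean(inside),
       mean_out = mean(outside), n_in = length(inside),
       n_out = length(outside))
}
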