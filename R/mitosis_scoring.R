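## Severity scheme for chromosome missegregation phenotypes observed by
## time-lapse imaging. Canonical category tokens are lower-case; the alias
## map absorbs the long phrasings used on annotation sheets.

severity_vocabulary <- function() {
  c("correct segregation" = 0L,
    "dna bridge" = 1L,
    "micronucleus" = 1L,
    "lagging chromosome" = 1L,
    "bridge or lagging with micronucleus" = 2L,
    "metaphase misalignment" = 2L,
    "misalignment with micronucleus" = 3L,
    "misalignment with lagging or bridge" = 3L,
    "metaphase skipping" = 4L,
    "cytokinesis failure" = 4L,
    "misalignment with lagging or bridge and micronuclei" = 4L,
    "skipping with dna bridge" = 5L,
    "skipping with micronucleus" = 5L)
}

severity_aliases <- function() {
  c("correct chromosomal segregation" = "correct segregation",
    "dna bridge formation" = "dna bridge",
    "micronucleus formation" = "micronucleus",
    "chromosomal lagging" = "lagging chromosome",
    "dna bridge/lagging with micronucleus formation" =
      "bridge or lagging with micronucleus",
    "bridge/lagging with micronucleus" = "bridge or lagging with micronucleus",
    "metaphase misalignment with micronucleus formation" =
      "misalignment with micronucleus",
    "metaphase misalignment with chromosomal lagging/bridge formation" =
      "misalignment with lagging or bridge",
    "metaphase misalignment with chromosomal lagging/bridge formation and emergence of micronuclei" =
      "misalignment with lagging or bridge and micronuclei",
    "metaphase skipping with dna bridging" = "skipping with dna bridge",
    "metaphase skipping with micronucleus formation" =
      "skipping with micronucleus")
}

normalize_category <- function(category) {
  x <- tolower(trimws(category))
  x <- gsub("\\s+", " ", x)
  al <- severity_aliases()
  hit <- match(x, names(al))
  ifelse(is.na(hit), x, unname(al[hit]))
}

#' Severity score of a mitotic-event category
#'
#' Maps each event category to its 0-5 severity score. Events of category
#' `"other"` (aberrations outside the predefined vocabulary) carry a manual
#' 1-5 score and are flagged `excluded` so downstream statistics can drop
#' them while exports retain them.
#'
#' @param category Character vector of category labels (canonical tokens or
#'   their common aliases; case/whitespace-insensitive), or `"other"`.
#' @param other_score Integer 1-5 per event, required where
#'   `category == "other"`.
#' @return data.frame with `score` (integer 0-5) and `excluded` (logical).
#' @export
score_category <- function(category, other_score = NULL) {
  x <- normalize_category(category)
  vocab <- severity_vocabulary()
  is_other <- x == "other"
  score <- rep(NA_integer_, length(x))
  hit <- match(x[!is_other], names(vocab))
  if (anyNA(hit)) {
    bad <- unique(x[!is_other][is.na(hit)])
    stop("unknown category: ", paste(bad, collapse = ", "),
         "\nknown categories: ",
         paste(c(names(vocab), "other"), collapse = "; "))
  }
  score[!is_other] <- unname(vocab[hit])
  if (any(is_other)) {
    if (is.null(other_score)) stop("'other' events require other_score")
    os <- rep_len(other_score, length(x))[is_other]
    if (anyNA(os) || any(os < 1L | os > 5L)) {
      stop("other_score must be an integer in 1..5 for every 'other' event")
    }
    score[is_other] <- as.integer(os)
  }
  data.frame(score = score, excluded = is_other)
}

#' Per-condition severity histogram
#'
#' Tallies events by score 0-5 within each condition; `"other"` events are
#' counted only in `n_other_excluded`.
#'
#' @param events data.frame with columns `condition`, `category` and (for
#'   "other" events) `other_score`.
#' @return data.frame, one row per condition: counts `score_0` .. `score_5`,
#'   `n_other_excluded`, `n_events`.
#' @export
severity_table <- function(events) {
  if (nrow(events) == 0L) stop("no events")
  sc <- score_category(events$category,
                       if ("other_score" %in% names(events))
                         events$other_score else NULL)
  conds <- unique(events$condition)
  rows <- lapply(conds, function(cc) {
    sel <- events$condition == cc
    keep <- sel & !sc$excluded
    counts <- tabulate(sc$score[keep] + 1L, nbins = 6L)
    out <- data.frame(condition = cc, stringsAsFactors = FALSE)
    out[paste0("score_", 0:5)] <- as.list(counts)
    out$n_other_excluded <- sum(sel & sc$excluded)
    out$n_events <- sum(sel)
    out
  })
  do.call(rbind, rows)
}

#' Severity scores per condition, "other" events excluded
#'
#' @param events Events data.frame (see [severity_table()]).
#' @return Named list of integer score vectors, one per condition.
#' @export
severity_groups <- function(events) {
  sc <- score_category(events$category,
                       if ("other_score" %in% names(events))
                         events$other_score else NULL)
  keep <- !sc$excluded
  split(sc$score[keep], events$condition[keep])
}

#' Kruskal-Wallis rank test across score groups
#'
#' Tie-corrected H statistic with mid-ranks and the upper-tail chi-square
#' p-value on (groups - 1) degrees of freedom — the test is inherently
#' upper-tailed. All observations identical yields H = 0, p = 1.
#'
#' @param score_groups List of >= 2 non-empty numeric vectors.
#' @return List `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(score_groups) {
  stopifnot(length(score_groups) >= 2L,
            all(lengths(score_groups) >= 1L))
  values <- unlist(score_groups, use.names = FALSE)
  if (length(values) < 3L) stop("need at least 3 observations in total")
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p = 1, df = length(score_groups) - 1L))
  }
  grp <- factor(rep(seq_along(score_groups), lengths(score_groups)))
  kt <- stats::kruskal.test(values, grp)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Compare event durations across conditions
#'
#' Two groups: two-sided t-test (Welch by default). More than two groups:
#' one-way ANOVA (F and p).
#'
#' @param duration_groups List of >= 2 numeric vectors, each with >= 2 values.
#' @param var_equal For the two-group case, pooled t instead of Welch.
#' @return List `method` ("t" or "anova"), `statistic`, `p`, `df`.
#' @export
compare_durations <- function(duration_groups, var_equal = FALSE) {
  stopifnot(length(duration_groups) >= 2L,
            all(lengths(duration_groups) >= 2L))
  if (length(duration_groups) == 2L) {
    res <- welch_or_pooled(duration_groups[[1]], duration_groups[[2]],
                           var_equal = var_equal)
    return(list(method = "t", statistic = res$t, p = res$p, df = NA_real_))
  }
  values <- unlist(duration_groups, use.names = FALSE)
  grp <- factor(rep(seq_along(duration_groups), lengths(duration_groups)))
  av <- stats::anova(stats::lm(values ~ grp))
  list(method = "anova", statistic = av[["F value"]][1],
       p = av[["Pr(>F)"]][1], df = av$Df[1])
}

#' Western-blot densitometry fold change with double normalization
#'
#' Per lane, the target band is normalized to the mitotic marker, itself
#' first normalized to the loading control:
#' norm = target / (marker / control). The fold change is the treated lane's
#' normalized value over the control lane's.
#'
#' @param target,mitotic_marker,loading_control Per-lane positive band
#'   intensities (equal-length vectors; names or positions identify lanes).
#' @param treated_lane,control_lane Lane names or indices.
#' @return Single numeric fold change.
#' @export
densitometry_fold_change <- function(target, mitotic_marker, loading_control,
                                     treated_lane, control_lane) {
  if (any(c(target, mitotic_marker, loading_control) <= 0)) {
    stop("all band intensities must be positive")
  }
  norm <- target / (mitotic_marker / loading_control)
  unname(norm[treated_lane] / norm[control_lane])
}
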