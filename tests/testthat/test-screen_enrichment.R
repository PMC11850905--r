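test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # second sample exactly doubled: factors (1/sqrt(2), sqrt(2))
  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # random matrices against the brute-force oracle and DESeq2
  set.seed(101)
  for (i in 1:20) {
    r <- matrix(rpois(400, 50) + 1L, 100, 4)
    expect_equal(unname(size_factors(r)), oracle_size_factors(r),
                 tolerance = 1e-12)
  }
  # odd guide count: the median is a data point, so the plain median of
  # ratios coincides with DESeq2's exp(median(log ratio)) convention
  r <- matrix(rnbinom(404, mu = 100, size = 10) + 1L, 101, 4)
  expect_equal(unname(size_factors(r)),
               unname(DESeq2::estimateSizeFactorsForMatrix(r)),
               tolerance = 1e-8)
})

test_that("size factors are scale-equivariant and fail without a positive reference", {
  set.seed(102)
  r <- matrix(rpois(400, 50) + 1L, 100, 4)
  sf <- size_factors(r)
  r2 <- r
  r2[, 2] <- r2[, 2] * 3L
  sf2 <- size_factors(r2)
  # factors are defined relative to the geometric-mean pseudo-reference,
  # which itself rescales; equivariance holds for factor ratios
  expect_equal(sf2[2] / sf2[1], 3 * sf[2] / sf[1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sf2[3] / sf2[1], sf[3] / sf[1], tolerance = 1e-12,
               ignore_attr = TRUE)

  z <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_error(size_factors(z), "pseudocount")
  expect_silent(size_factors(z, pseudocount = 0.5))
})

test_that("all-zero guides are removed, order preserved", {
  set.seed(103)
  m <- matrix(rpois(400, 5), 100, 4, dimnames = list(paste0("g", 1:100), NULL))
  zero_rows <- sample(100, 7)
  m[zero_rows, ] <- 0L
  f <- filter_zero_guides(m)
  expect_equal(nrow(f), 93L)
  expect_identical(rownames(f), setdiff(rownames(m), paste0("g", zero_rows)))

  one_hit <- matrix(c(0L, 0L, 1L, 0L), 1, 4)
  expect_equal(nrow(filter_zero_guides(one_hit)), 1L)
})

test_that("plain paired t matches the defining formula", {
  lib <- tiny_library()
  design <- tiny_sheet()[, c("sample_id", "condition", "replicate")]
  m <- matrix(100, 4, 4, dimnames = list(lib$guide_id, design$sample_id))

  expect_warning(d0 <- paired_differential(m, design, method = "t"),
                 "zero log-ratio variance")
  expect_equal(d0$log2fc, rep(0, 4))
  expect_equal(d0$stat, rep(0, 4))
  expect_equal(d0$p, rep(1, 4))

  # one guide at 4x in treated, both replicates
  m4 <- m
  m4["geneA_sg1", c("treated_rep1", "treated_rep2")] <- c(400, 410)
  d4 <- paired_differential(m4, design, method = "t")
  expect_equal(d4$log2fc[d4$guide == "geneA_sg1"], 2, tolerance = 0.05)

  # random fixture vs a hand computation
  set.seed(104)
  r <- matrix(rpois(4 * 4, 200), 4, 4,
              dimnames = list(lib$guide_id, design$sample_id))
  dr <- paired_differential(r, design, method = "t", pseudocount = 0.5)
  d <- log2(r[, c("treated_rep1", "treated_rep2")] + 0.5) -
    log2(r[, c("control_rep1", "control_rep2")] + 0.5)
  fc <- rowMeans(d)
  sdd <- apply(d, 1, sd)
  expect_equal(dr$log2fc, unname(fc))
  expect_equal(dr$stat, unname(fc / (sdd / sqrt(2))))
  expect_equal(dr$p, unname(2 * pt(-abs(fc / (sdd / sqrt(2))), df = 1)))

  expect_error(
    paired_differential(m[, c(1, 3)],
                        design[design$replicate == "rep1", ], method = "t"),
    "replicates")
})

test_that("moderated paired t keeps the fold change and tames single-guide variance spikes", {
  lib <- make_library(50, 4, seed = 105)
  sim <- simulate_counts(lib, depth_per_guide = 300,
                         planted = c(gene_0001 = 2), seed = 106)
  norm <- normalize_counts(sim$counts)
  mt <- paired_differential(norm, sim$design, method = "moderated")
  tt <- paired_differential(norm, sim$design, method = "t")
  expect_equal(mt$log2fc, tt$log2fc, tolerance = 1e-12)
  # planted guides dominate the moderated ranking
  top4 <- mt$guide[order(-mt$stat)][1:4]
  expect_setequal(top4, lib$guide_id[lib$gene_id == "gene_0001"])
})

test_that("moderated null p-values are approximately uniform", {
  # empirical-Bayes moderation trades exact null calibration for ranking
  # stability at two replicates; its p-values stay close to uniform while
  # gene-level inference rests on the RRA permutation p
  lib <- make_library(250, 4, seed = 115)
  sim <- simulate_counts(lib, depth_per_guide = 500, seed = 116)
  norm <- normalize_counts(filter_zero_guides(sim$counts))
  d <- paired_differential(norm, sim$design, method = "moderated")
  expect_lt(ks_uniform(d$p), 0.1)
})

test_that("guide ranking is direction-aware with deterministic ties", {
  diff <- data.frame(guide = c("a", "b", "c"), log2fc = c(1, -1, 0),
                     stat = c(3, 1, 2), p = c(0.1, 0.5, 0.2))
  up <- rank_guides(diff, "enriched")
  expect_equal(up$guide, c("a", "c", "b"))
  expect_equal(up$r, c(1, 2, 3) / 3)

  down <- rank_guides(diff, "depleted")
  expect_equal(down$guide, c("b", "c", "a"))

  tie <- data.frame(guide = c("z", "y", "x"), stat = c(1, 1, 1))
  expect_equal(rank_guides(tie, "enriched")$guide, c("x", "y", "z"))
  # invariance to input row order
  expect_equal(rank_guides(tie[3:1, ], "enriched")$guide, c("x", "y", "z"))
})

test_that("alpha-RRA rho matches closed-form Beta order statistics", {
  # k = 1: Beta(1, 1) CDF is the identity
  one <- alpha_rra(data.frame(guide = "g", r = 0.01), c(g = "G"),
                   alpha = 0.1, n_perm = 10, seed = 1)
  expect_equal(one$rho, 0.01, tolerance = 1e-12)

  # k = 2, ranks (0.05, 0.10): min(1 - 0.95^2, 0.10^2)
  two <- alpha_rra(data.frame(guide = c("g1", "g2"), r = c(0.05, 0.10)),
                   c(g1 = "G", g2 = "G"), alpha = 0.25, n_perm = 10, seed = 1)
  expect_equal(two$rho, min(1 - 0.95^2, 0.10^2), tolerance = 1e-12)
  expect_equal(two$k_sel, 2L)

  # ranks at or above alpha do not contribute; none selected gives rho = 1
  none <- alpha_rra(data.frame(guide = c("g1", "g2"), r = c(0.3, 0.9)),
                    c(g1 = "G", g2 = "G"), alpha = 0.25, n_perm = 10, seed = 1)
  expect_equal(none$rho, 1)
  expect_equal(none$k_sel, 0L)

  # random k <= 3 fixtures vs the closed-form oracle
  set.seed(107)
  for (i in 1:100) {
    k <- sample(1:3, 1)
    r <- sort(runif(k))
    alpha <- runif(1, 0.05, 1)
    res <- alpha_rra(data.frame(guide = paste0("g", 1:k), r = r),
                     setNames(rep("G", k), paste0("g", 1:k)),
                     alpha = alpha, n_perm = 5, seed = 1)
    expect_equal(res$rho, oracle_rho_k3(r, alpha), tolerance = 1e-12)
  }
})

test_that("alpha-RRA permutation p is conservative at the rho = 1 atom and recovers a planted gene", {
  lib <- make_library(100, 4, seed = 108)
  n <- nrow(lib)
  set.seed(109)
  # plant one gene's guides into the top 1%
  planted <- lib$guide_id[lib$gene_id == "gene_0042"]
  others <- sample(setdiff(lib$guide_id, planted))
  rk <- data.frame(guide = c(planted, others), r = seq_len(n) / n)
  gs <- alpha_rra(rk, lib, alpha = 0.25, n_perm = 1000, seed = 110)
  expect_equal(gs$gene[1], "gene_0042")
  expect_equal(gs$p_perm[1], min(gs$p_perm))
  # genes with no rank below alpha sit at rho = 1 with p = 1
  expect_true(all(gs$p_perm[gs$rho == 1] == 1))
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(111)
  for (i in 1:100) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("top-fraction intersection returns shared top genes with both significances", {
  tab <- data.frame(gene = paste0("g", 1:20), rho = (1:20) / 100,
                    p_perm = (1:20) / 20, fdr = (1:20) / 20,
                    k = 4L, k_sel = 2L)
  same <- top_fraction_intersection(tab, tab, fraction = 0.25)
  expect_setequal(same$genes, paste0("g", 1:5))
  expect_equal(same$table$neglog10_p_a, same$table$neglog10_p_b)

  rev_tab <- tab
  rev_tab$p_perm <- rev(tab$p_perm)
  rev_tab$rho <- rev(tab$rho)
  disjoint <- top_fraction_intersection(tab, rev_tab, fraction = 0.25)
  expect_length(disjoint$genes, 0)

  other <- tab
  other$gene <- paste0("h", 1:20)
  expect_error(top_fraction_intersection(tab, other), "no genes")
})

test_that("preranked enrichment score matches the running-sum oracle", {
  s <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  top <- gsea_enrichment(s, "g1", weight = 0, n_perm = 10, seed = 1)
  expect_equal(top$es, 1)

  # a uniformly interleaved set attains the minimal possible deviation
  # (one hit step, 1/set_size) rather than any concentration signal
  s10 <- setNames(rep(1, 10), sprintf("g%02d", 1:10))
  inter <- gsea_enrichment(s10, sprintf("g%02d", c(1, 3, 5, 7, 9)),
                           weight = 0, n_perm = 10, seed = 1)
  expect_lte(abs(inter$es), 0.2 + 1e-12)

  set.seed(112)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    scores <- setNames(rnorm(n), sprintf("g%03d", 1:n))
    gs <- sample(names(scores), sample(3:10, 1))
    w <- sample(c(0, 0.5, 1), 1)
    res <- gsea_enrichment(scores, gs, weight = w, n_perm = 1, seed = 1)
    expect_equal(res$es, oracle_gsea_es(scores, gs, w), tolerance = 1e-12)
  }

  expect_error(gsea_enrichment(s, character(0)), "empty")
  expect_error(gsea_enrichment(s, names(s)), "strict subset")
})

test_that("coverage arithmetic reproduces the screen's cell-number bookkeeping", {
  expect_equal(required_cells(500, 188509, 0.25), 377018000)
  expect_equal(required_cells(500, 188509, 1.0), 94254500)
  expect_equal(required_cells(1, 100, 1.0), 100)
  expect_error(required_cells(500, 188509, 0), "surviving_fraction")
})
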