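test_that("ssGSEA is rank-based and matches the ECDF-difference oracle", {
  prof <- setNames(c(5, 3, 2, 1), c("a", "b", "c", "d"))
  expect_gt(ssgsea(prof, "a"), 0)

  # invariance under strictly monotone transforms of the profile
  set.seed(201)
  expr <- setNames(rnorm(30), sprintf("g%02d", 1:30))
  gs <- sample(names(expr), 6)
  s0 <- ssgsea(expr, gs)
  expect_equal(ssgsea(exp(expr), gs), s0, tolerance = 1e-12)
  expect_equal(ssgsea(2 * expr + 7, gs), s0, tolerance = 1e-12)

  for (i in 1:100) {
    n <- sample(8:20, 1)
    e <- setNames(rnorm(n), sprintf("g%02d", 1:n))
    set_i <- sample(names(e), sample(2:(n - 1), 1))
    tau <- sample(c(0, 0.25, 1), 1)
    expect_equal(ssgsea(e, set_i, exponent = tau),
                 oracle_ssgsea(e, set_i, tau), tolerance = 1e-12)
  }

  expect_error(ssgsea(prof, character(0)), "empty")
  expect_error(ssgsea(prof, names(prof)), "whole universe")
  expect_error(ssgsea(prof, "zz"), "subset")
})

test_that("signature scores cover all lines of a panel", {
  sp <- simulate_panel(n_lines = 40, n_genes = 50, n_drugs = 5,
                       n_class_drugs = 2, seed = 202)
  sigs <- list(sigA = rownames(sp$panel$expression)[1:10],
               sigB = rownames(sp$panel$expression)[11:25])
  sm <- signature_scores(sp$panel, sigs)
  expect_equal(dim(sm), c(2L, 40L))
  expect_true(all(is.finite(sm)))
})

test_that("quartile groups are the boundary-inclusive outer quarters", {
  g <- quartile_groups(1:8)
  expect_equal(g$bottom, 1:2)
  expect_equal(g$top, 7:8)

  # boundary ties are included deterministically
  v <- c(1, 1, 1, 2, 3, 4, 5, 5)  # q25 = 1, q75 = 4.25
  gt <- quartile_groups(v)
  expect_equal(gt$bottom, 1:3)
  expect_equal(gt$top, 7:8)

  expect_error(quartile_groups(rep(2, 10)), "no quartile split")
  expect_error(quartile_groups(1:5), "at least 8")

  set.seed(203)
  v531 <- rnorm(531)
  g531 <- quartile_groups(v531)
  expect_true(abs(length(g531$bottom) + length(g531$top) - 266) <= 2)
  expect_length(intersect(g531$bottom, g531$top), 0)
})

test_that("quartile t-test reproduces hand arithmetic and is antisymmetric", {
  same <- quartile_t_test(1:8, rep(5, 8))
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)

  # feature 1..8, response = feature: groups {1,2} vs {7,8}
  r <- quartile_t_test(1:8, 1:8, var_equal = TRUE)
  expect_equal(r$delta, 6)
  expect_equal(r$t_stat, 6 / sqrt(0.5 * (1 / 2 + 1 / 2)), tolerance = 1e-3)
  expect_equal(r$t_stat, 8.485, tolerance = 1e-3)
  expect_equal(r$n_top, 2L)
  expect_equal(r$n_bottom, 2L)

  set.seed(204)
  f <- rnorm(40)
  y <- rnorm(40)
  a <- quartile_t_test(f, y)
  b <- quartile_t_test(f, -y)
  expect_equal(b$delta, -a$delta)
  expect_equal(b$t_stat, -a$t_stat)
  expect_equal(b$p, a$p)

  # agrees with stats::t.test on the same groups
  grp <- quartile_groups(f)
  tt <- t.test(y[grp$top], y[grp$bottom])
  expect_equal(a$t_stat, unname(tt$statistic))
  expect_equal(a$p, tt$p.value)
})

test_that("partialization residuals are exactly orthogonal to the covariate", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(partial_out(3 * x + 1, x), rep(0, 5), tolerance = 1e-12)

  set.seed(205)
  y <- rnorm(50)
  x <- rnorm(50)
  res <- partial_out(y, x)
  expect_equal(mean(res), 0, tolerance = 1e-12)
  expect_equal(sum(res * x), 0, tolerance = 1e-9)
  expect_equal(unname(cor(res, x)), 0, tolerance = 1e-9)

  # missing data stays missing, complete pairs are used
  y[3] <- NA
  res2 <- partial_out(y, x)
  expect_true(is.na(res2[3]))
  expect_equal(sum(res2 * x, na.rm = TRUE), 0, tolerance = 1e-9)

  expect_error(partial_out(y, rep(1, 50)), "constant")
  expect_error(partial_out(c(1, 2), c(1, 2)), "at least 3")
})

test_that("aneuploidy association is unchanged by an irrelevant covariate and killed by the mediator", {
  sp <- simulate_panel(n_genes = 5, n_drugs = 2, n_class_drugs = 1,
                       effect = 1, aneuploidy_coupling = 0.8, seed = 206)
  y <- sp$panel$response["drug_001", ]
  a <- sp$panel$aneuploidy
  z <- sp$panel$expression["gene_0001", ]
  irrelevant <- sp$panel$expression["gene_0002", ]

  with_noise <- aneuploidy_association(y, a, covariate = irrelevant)
  expect_lt(with_noise$raw$p, 0.001)
  expect_lt(with_noise$partialized$p, 0.001)
  expect_equal(with_noise$partialized$delta, with_noise$raw$delta,
               tolerance = 0.15)

  mediated <- aneuploidy_association(y, a, covariate = z)
  expect_lt(mediated$raw$p, 0.001)
  expect_gt(mediated$partialized$p, 0.05)
})

test_that("gene-drug percentile engine agrees with per-gene t-tests", {
  sp <- simulate_panel(n_lines = 60, n_genes = 30, n_drugs = 8,
                       n_class_drugs = 2, effect = 1.2, seed = 207)
  prof <- gene_drug_percentiles(sp$panel, "gene_0001", min_group = 5)
  expect_equal(nrow(prof), 8L)
  expect_true(all(prof$percentile >= 0 & prof$percentile <= 100))

  # engine p-values equal looped quartile_t_test p-values
  d <- "drug_003"
  y <- sp$panel$response[d, ]
  genes <- rownames(sp$panel$expression)
  p_loop <- vapply(genes, function(g) {
    quartile_t_test(sp$panel$expression[g, ], y, min_group = 5)$p
  }, numeric(1))
  rank_target <- 1 + sum(p_loop < p_loop["gene_0001"]) +
    sum(p_loop == p_loop["gene_0001"] & genes < "gene_0001")
  expect_equal(prof$rank[prof$drug == d], rank_target)
  expect_equal(prof$p_target[prof$drug == d],
               unname(p_loop["gene_0001"]), tolerance = 1e-9)

  # a strongly planted drug puts the target at the very top
  expect_true(all(prof$percentile[prof$class == "MPS1i"] >
                    prof$percentile[prof$class == "other"]))

  # rank direction flips the scale
  prof_rank <- gene_drug_percentiles(sp$panel, "gene_0001", min_group = 5,
                                     direction = "rank")
  expect_true(all(prof_rank$percentile[prof_rank$class == "MPS1i"] <
                    prof_rank$percentile[prof_rank$class == "other"]))
})

test_that("null target percentiles are close to uniform", {
  sp <- simulate_panel(n_lines = 80, n_genes = 100, n_drugs = 400,
                       n_class_drugs = 2, effect = 0, seed = 208)
  prof <- gene_drug_percentiles(sp$panel, "gene_0050", min_group = 5)
  expect_lt(ks_uniform(prof$percentile / 100), 0.1)
})

test_that("drug-class comparison tests class percentiles against the rest", {
  prof <- data.frame(drug = paste0("d", 1:10),
                     class = rep(c("MPS1i", "other"), c(3, 7)),
                     percentile = c(99, 98, 97, 50, 40, 60, 55, 45, 52, 48))
  cc <- compare_drug_classes(prof, "MPS1i")
  expect_lt(cc$p, 0.01)
  expect_gt(cc$mean_in, cc$mean_out)
  expect_equal(cc$n_in, 3L)

  flat <- prof
  flat$percentile <- 50
  expect_equal(compare_drug_classes(flat, "MPS1i")$p, 1)

  single <- prof
  single$class <- c("MPS1i", rep("other", 9))
  expect_error(compare_drug_classes(single, "MPS1i"), "at least 2")
  expect_error(compare_drug_classes(prof, "absent"), "at least 2")
})

test_that("panel bundles inner-join components on shared lines", {
  expr <- matrix(rnorm(40), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("L", 1:10)))
  resp <- matrix(rnorm(30), 3, 10,
                 dimnames = list(paste0("d", 1:3), paste0("L", 3:12)))
  as <- setNames(rnorm(10), paste0("L", 1:10))
  pb <- panel_bundle(expr, resp, as)
  expect_equal(pb$lines, paste0("L", 3:10))
  expect_equal(colnames(pb$expression), colnames(pb$response))
  expect_error(panel_bundle(expr[, 1:3], resp), "8 shared")
})
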