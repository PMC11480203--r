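# TYI selection, z-scoring, fuzzy c-means, cluster summaries.

test_that("top-induced selection applies strict fold-change and padj cuts", {
  de <- tibble::tibble(gene = c("a", "b", "c", "d"),
                       log2FC = c(2.0, 0.5, 2.0, 1.0),
                       padj = c(1e-6, 1e-6, 1e-3, 1e-9))
  sel <- select_tyi(de)
  expect_equal(sel$gene, "a")  # b fails lfc, c fails padj, d is not strict
  expect_warning(select_tyi(de[2, ]), "no genes")
})

test_that("z-scoring centres and scales per gene, drops constants, is idempotent", {
  expr <- tibble::tibble(gene = c("g1", "g2"),
                         s1 = c(1, 5), s2 = c(2, 5), s3 = c(3, 5))
  expect_warning(z <- zscore_expr(expr), "constant")
  expect_equal(z$gene, "g1")
  vals <- as.numeric(z[1, -1])
  expect_equal(mean(vals), 0)
  expect_equal(sd(vals), 1)
  expect_equal(as.data.frame(zscore_expr(z)), as.data.frame(z),
               tolerance = 1e-9)
})

test_that("fuzzy memberships are proper and symmetric for degenerate input", {
  expr <- tibble::tibble(gene = paste0("g", 1:6),
                         s1 = 1, s2 = 2, s3 = 3)
  fit <- fuzzy_cmeans(expr, c = 3, seed = 1)
  expect_true(all(abs(fit$membership - 1 / 3) < 1e-9))
  expect_equal(rowSums(fit$membership), rep(1, 6), tolerance = 1e-9)
  expect_error(fuzzy_cmeans(expr[1:2, ], c = 3), class = "cooccupy_bad_input")
  expect_error(fuzzy_cmeans(expr, c = 2, m = 1), class = "cooccupy_bad_input")
})

test_that("two well-separated archetypes are crisply recovered at c = 2", {
  withr::with_seed(3, {
    a <- matrix(rnorm(40 * 6, mean = rep(c(2, -2), each = 3 * 40),
                      sd = 0.2), 40)
    b <- matrix(rnorm(40 * 6, mean = rep(c(-2, 2), each = 3 * 40),
                      sd = 0.2), 40)
  })
  expr <- dplyr::bind_cols(tibble::tibble(gene = paste0("g", 1:80)),
                           tibble::as_tibble(rbind(a, b),
                                             .name_repair = ~ paste0("s", 1:6)))
  fit <- fuzzy_cmeans(expr, c = 2, seed = 5)
  expect_true(all(fit$labels$membership > 0.9))
  expect_equal(length(unique(fit$labels$cluster[1:40])), 1)
  expect_false(fit$labels$cluster[1] == fit$labels$cluster[41])
  # memberships sum to one; objective never increases
  expect_equal(rowSums(fit$membership), rep(1, 80), tolerance = 1e-9)
  expect_true(all(diff(fit$objective_trace) <= 1e-9))
})

test_that("planted three-cluster structure is recovered from the generator", {
  cfg <- sim_config(seed = 21)
  ex <- simulate_expression(cfg)
  tyi <- select_tyi(ex$de)
  z <- zscore_expr(dplyr::filter(ex$expr, gene %in% tyi$gene))
  fit <- fuzzy_cmeans(z, c = 3, seed = 2)
  truth <- ex$truth$cluster[match(fit$labels$gene, ex$truth$gene)]
  expect_gte(best_permutation_agreement(fit$labels$cluster, truth), 0.95)
  # seeded determinism of the full fit
  fit2 <- fuzzy_cmeans(z, c = 3, seed = 2)
  expect_identical(fit$membership, fit2$membership)
})

test_that("the in-package fit matches the reference fuzzy c-means", {
  skip_if_not_installed("e1071")
  cfg <- sim_config(seed = 31, cluster_sizes = c(60L, 60L, 60L),
                    n_genes = 200L)
  ex <- simulate_expression(cfg)
  z <- zscore_expr(dplyr::filter(ex$expr,
                                 gene %in% ex$truth$gene[ex$truth$is_tyi]))
  fit <- fuzzy_cmeans(z, c = 3, seed = 2)
  x <- as.matrix(z[-1])
  ref <- e1071::cmeans(x, centers = fit$centers, m = 1.25, iter.max = 200)
  expect_gte(best_permutation_agreement(fit$labels$cluster,
                                        as.integer(ref$cluster)), 0.99)
})

test_that("cluster summaries reproduce archetype ordering and ignore sample order", {
  cfg <- sim_config(seed = 41)
  ex <- simulate_expression(cfg)
  z <- zscore_expr(dplyr::filter(ex$expr,
                                 gene %in% ex$truth$gene[ex$truth$is_tyi]))
  fit <- fuzzy_cmeans(z, c = 3, seed = 2)
  summ <- summarize_clusters(z, fit, ex$samples)
  # map fitted clusters to planted ones by best permutation
  truth <- ex$truth$cluster[match(fit$labels$gene, ex$truth$gene)]
  tab <- table(fit$labels$cluster, truth)
  mapping <- apply(tab, 1, which.max)
  wide <- tidyr::pivot_wider(summ, id_cols = "cluster",
                             names_from = "group", values_from = "mean_z")
  c1 <- wide[mapping[as.character(wide$cluster)] == 1, ]
  # planted cluster 1: induced in ev_ON, blunted in JUNoe_ON
  expect_gt(c1$ev_ON, c1$ev_OFF + 1)
  expect_gt(c1$ev_ON, c1$JUNoe_ON + 1)
  c2 <- wide[mapping[as.character(wide$cluster)] == 2, ]
  expect_gt(c2$ev_ON, c2$ev_OFF + 1)
  expect_gt(c2$JUNoe_ON, c2$JUNoe_OFF + 1)
  # permuting sample columns leaves the summary unchanged
  perm <- c("gene", withr::with_seed(1, sample(names(z)[-1])))
  summ_p <- summarize_clusters(z[perm], fit, ex$samples)
  expect_equal(dplyr::arrange(summ_p, cluster, group),
               dplyr::arrange(summ, cluster, group))
})

test_that("single-gene clusters summarize to that gene's group means", {
  expr <- tibble::tibble(gene = c("g1", "g2"),
                         a1 = c(1, -1), a2 = c(1.2, -0.8),
                         b1 = c(-1, 1), b2 = c(-1.2, 0.8))
  samples <- tibble::tibble(sample = c("a1", "a2", "b1", "b2"),
                            group = c("A", "A", "B", "B"))
  fit <- fuzzy_cmeans(expr, c = 2, seed = 1)
  summ <- summarize_clusters(expr, fit, samples)
  g1row <- fit$labels$cluster[fit$labels$gene == "g1"]
  expect_equal(summ$mean_z[summ$cluster == g1row & summ$group == "A"], 1.1)
  expect_equal(summ$mean_z[summ$cluster == g1row & summ$group == "B"], -1.1)
})
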