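# Generators: determinism, planted structure, degenerate inputs.

test_that("configuration validation rejects out-of-range settings", {
  expect_error(sim_config(dispersion = -1), class = "cooccupy_invalid_config")
  expect_error(sim_config(hazard_ratio = 0), class = "cooccupy_invalid_config")
  expect_error(sim_config(motif_fraction = 2), class = "cooccupy_invalid_config")
  expect_error(sim_config(sgrnas_per_gene = 0), class = "cooccupy_invalid_config")
  expect_error(sim_config(expr_groups = c("a", "b")),
               class = "cooccupy_invalid_config")
})

test_that("genome construction is deterministic and guards capacity", {
  cfg <- sim_config(seed = 1)
  g <- make_genome(cfg)
  expect_equal(g$chrom, c("chr1", "chr2"))
  expect_equal(g$length, c(1e6, 1e6))
  expect_identical(g, make_genome(cfg))
  expect_error(make_genome(sim_config(n_chromosomes = 0)),
               class = "cooccupy_invalid_config")
  expect_error(make_genome(sim_config(chromosome_length = 1e4)),
               class = "cooccupy_invalid_config")
})

test_that("peak landscape plants categories, respects jitter and motif flags", {
  cfg <- sim_config(seed = 7, n_joint = 100, n_factor_a = 100,
                    n_factor_b = 0, replicate_jitter = 0)
  land <- simulate_peak_landscape(make_genome(cfg), cfg)
  # each factor-A replicate holds joint + A-exclusive sites
  per_rep <- dplyr::count(land$peaks, tf, replicate)
  expect_true(all(per_rep$n[per_rep$tf == "A"] == 200))
  expect_true(all(per_rep$n[per_rep$tf == "B"] == 100))
  # joint sites appear in both factors' sets
  joint <- land$truth$name[land$truth$category == "joint"]
  expect_true(all(joint %in% land$peaks$name[land$peaks$tf == "A"]))
  expect_true(all(joint %in% land$peaks$name[land$peaks$tf == "B"]))
  # replicate jitter bounded
  cfg2 <- sim_config(seed = 7, replicate_jitter = 10)
  land2 <- simulate_peak_landscape(make_genome(cfg2), cfg2)
  off <- dplyr::inner_join(land2$peaks, land2$truth, by = "name",
                           suffix = c("", "_truth"))
  expect_lte(max(abs(off$start - off$start_truth)), 10)
  # motif fraction 0 flags nothing
  cfg3 <- sim_config(seed = 7, motif_fraction = 0)
  land3 <- simulate_peak_landscape(make_genome(cfg3), cfg3)
  expect_false(any(land3$truth$motif))
  # determinism
  expect_identical(land, simulate_peak_landscape(make_genome(cfg), cfg))
  # a peak mass beyond what the supplied genome can hold errors
  cfg_big <- sim_config(n_joint = 5000, n_factor_a = 0, n_factor_b = 0,
                        chromosome_length = 5e6)
  expect_error(simulate_peak_landscape(make_genome(sim_config()), cfg_big),
               class = "cooccupy_invalid_config")
})

test_that("overlap categorization recovers planted categories at zero jitter", {
  cfg <- sim_config(seed = 3, replicate_jitter = 0)
  land <- simulate_peak_landscape(make_genome(cfg), cfg)
  a1 <- dplyr::filter(land$peaks, tf == "A", replicate == 1)
  b1 <- dplyr::filter(land$peaks, tf == "B", replicate == 1)
  lab <- categorize_overlap(list(A = a1, B = b1))$labels
  truth <- land$truth$category[match(lab$name, land$truth$name)]
  mapped <- ifelse(lab$category == "A&B", "joint", "factorA_only")
  expect_gte(mean(mapped == truth), 0.99)
})

test_that("binding counts carry the planted effect and only that effect", {
  regions <- tibble::tibble(name = sprintf("r%04d", 1:1000))
  # no planted effect: per-region log-ratios centred at zero
  cfg0 <- sim_config(seed = 5, n_diff_regions = 0)
  bc0 <- simulate_binding_counts(regions, cfg0)
  m <- as.matrix(bc0$counts[-1])
  lr <- log2(rowMeans(m[, bc0$design$condition == "ON"]) + 0.5) -
    log2(rowMeans(m[, bc0$design$condition == "OFF"]) + 0.5)
  expect_gt(t.test(lr)$p.value, 0.01)
  # planted 2 log2 units at 100 regions, recovered within +-0.3
  cfg1 <- sim_config(seed = 5, n_diff_regions = 100, diff_log2fc = 2)
  bc1 <- simulate_binding_counts(regions, cfg1)
  norm <- normalize_counts(bc1$counts, bc1$tallies)
  m <- as.matrix(norm[-1])
  lr <- log2(rowMeans(m[, bc1$design$condition == "ON"]) + 0.5) -
    log2(rowMeans(m[, bc1$design$condition == "OFF"]) + 0.5)
  planted <- bc1$truth$is_diff[match(norm$region, bc1$truth$region)]
  expect_lt(abs(mean(lr[planted]) - 2), 0.3)
  # reproducibility
  expect_identical(bc1$counts, simulate_binding_counts(regions, cfg1)$counts)
})

test_that("expression generator plants three clusters recoverable by selection", {
  cfg <- sim_config(seed = 2)
  ex <- simulate_expression(cfg)
  sel <- select_tyi(ex$de)
  expect_equal(nrow(sel), 434)
  expect_setequal(sel$gene, ex$truth$gene[ex$truth$is_tyi])
  # zero noise reproduces the archetypes exactly
  cfg0 <- sim_config(seed = 2, expr_noise_sd = 0)
  ex0 <- simulate_expression(cfg0)
  g1 <- ex0$truth$gene[which(ex0$truth$cluster == 1)[1]]
  prof <- as.numeric(ex0$expr[ex0$expr$gene == g1, -1])
  grp <- ex0$samples$group[match(names(ex0$expr)[-1], ex0$samples$sample)]
  expect_equal(as.numeric(tapply(prof, grp, mean)[colnames(ex0$archetypes)]),
               as.numeric(ex0$archetypes[1, ]))
  expect_identical(ex$expr, simulate_expression(cfg)$expr)
})

test_that("cohort generator ties hazard to signature 1 only and censors cleanly", {
  cfg <- sim_config(seed = 6, n_cohorts = 1, cohort_size = 500)
  ch <- simulate_cohort(cfg)
  expect_true(all(ch$cohorts$time > 0))
  expect_true(all(ch$cohorts$event %in% 0:1))
  # full censoring yields zero events and a not-computable log-rank
  cfg_c <- sim_config(seed = 6, n_cohorts = 1, cohort_size = 100,
                      censor_frac = 1)
  ch_c <- simulate_cohort(cfg_c)
  expect_equal(sum(ch_c$cohorts$event), 0)
  scores <- signature_score(ch_c$cohorts, ch_c$signatures$sig1)
  strat <- stratify_median(scores)
  expect_false(logrank_hr(strat)$computable)
})

test_that("hazard-ratio recovery through scoring is within the expected band", {
  inside <- vapply(1:60, function(k) {
    cfg <- sim_config(seed = 100 + k, n_cohorts = 1, cohort_size = 500)
    ch <- simulate_cohort(cfg)
    hr <- dual_signature_screen(ch$cohorts, ch$signatures$sig1,
                                ch$signatures$sig2)$hr_sig1
    hr >= 1.5 && hr <= 2.7
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("screen generator is reproducible and plants enrichment", {
  cfg <- sim_config(seed = 8)
  sc <- simulate_screen(cfg)
  expect_equal(nrow(sc$counts), 3000)
  expect_equal(sum(sc$truth$is_hit), 20)
  expect_identical(sc$counts, simulate_screen(cfg)$counts)
  # planted enrichment visible in raw fold changes
  lfc <- sgrna_log2fc(normalize_depth(sc$counts, sc$lib_sizes))
  hit_sg <- lfc$gene %in% sc$truth$gene[sc$truth$is_hit]
  expect_gt(mean(lfc$log2fc[hit_sg]) - mean(lfc$log2fc[!hit_sg]), 2)
})
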