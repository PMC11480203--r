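#' Simulate an induced-gene expression matrix with three planted clusters
#'
#' Generates per-gene expression profiles (z-score scale) over four condition
#' groups — empty-vector or JUN-overexpression crossed with induction OFF/ON
#' — with `n_replicates` samples per group.  The planted top-induced genes
#' follow one of three archetypes:
#' * cluster 1: induced on activation, and that induction is blunted under
#'   JUN overexpression;
#' * cluster 2: induced on activation regardless of JUN;
#' * cluster 3: elevated whenever JUN is high (AP-1-like).
#'
#' Background genes carry group-independent noise.  A matching
#' differential-expression table (induction contrast, log2FC and BH-adjusted
#' p) is emitted so that threshold selection with `log2FC > 1` and
#' `padj < 1e-4` recovers exactly the planted induced set.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `expr`: wide tibble, `gene` plus one column per sample;
#'   * `samples`: tibble (`sample`, `group`);
#'   * `de`: tibble (`gene`, `log2FC`, `padj`);
#'   * `truth`: tibble (`gene`, `cluster` (NA for background), `is_tyi`);
#'   * `archetypes`: cluster-by-group matrix of planted means.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  groups <- config$expr_groups
  if (length(groups) < 4) {
    abort("at least 4 condition groups are required.",
          class = "cooccupy_invalid_config")
  }
  sizes <- as.integer(config$cluster_sizes)
  n_tyi <- sum(sizes)
  n_bg <- config$n_genes - n_tyi

  # Planted group means (z-score scale) for the first four groups; any extra
  # groups repeat the baseline level.
  arch <- rbind(
    cluster1 = c(-0.75, 1.30, -0.75, -0.55),
    cluster2 = c(-1.00, 1.00, -1.00, 1.00),
    cluster3 = c(-1.00, -0.30, 0.65, 1.00)
  )[seq_along(sizes), , drop = FALSE]
  colnames(arch) <- groups[1:4]

  with_seed(sub_seed(config$seed, 3), {
    samples <- tidyr::expand_grid(group = groups,
                                  replicate = seq_len(config$n_replicates)) |>
      mutate(sample = paste0(.data$group, "_rep", .data$replicate))

    genes <- sprintf("gene_%05d", seq_len(config$n_genes))
    cluster <- rep(NA_integer_, config$n_genes)
    cluster[seq_len(n_tyi)] <- rep(seq_along(sizes), sizes)

    expr_mat <- matrix(rnorm(config$n_genes * nrow(samples),
                             sd = config$expr_noise_sd),
                       nrow = config$n_genes)
    grp_idx <- match(samples$group, colnames(arch))
    for (g in seq_len(config$n_genes)) {
      if (!is.na(cluster[g])) {
        mu <- ifelse(is.na(grp_idx), arch[cluster[g], 1], arch[cluster[g], grp_idx])
        expr_mat[g, ] <- expr_mat[g, ] + mu
      }
    }
    colnames(expr_mat) <- samples$sample

    is_tyi <- !is.na(cluster)
    de <- tibble(
      gene = genes,
      log2FC = ifelse(is_tyi, runif(config$n_genes, 1.5, 4),
                      rnorm(config$n_genes, 0, 0.3)),
      padj = ifelse(is_tyi, 10^-runif(config$n_genes, 5, 30),
                    runif(config$n_genes, 0.01, 1))
    )

    list(
      expr = bind_cols(tibble(gene = genes), as_tibble(expr_mat)),
      samples = select(samples, "sample", "group"),
      de = de,
      truth = tibble(gene = genes, cluster = cluster, is_tyi = is_tyi),
      archetypes = arch
    )
  })
}
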