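#' Select top-induced genes from a differential-expression table
#'
#' Keeps genes with `log2FC > lfc_min` and `padj < padj_max` (induction
#' contrast), preserving input order.  With the default thresholds
#' (`log2FC > 1`, `padj < 1e-4`) this is the "top induced" selection used to
#' define the gene set that is subsequently clustered.
#'
#' @param de Tibble with columns `gene`, `log2FC`, `padj`.
#' @param lfc_min Minimum log2 fold change (exclusive), default 1.
#' @param padj_max Maximum BH-adjusted p (exclusive), default 1e-4.
#' @return The filtered rows of `de`; a warning is raised if nothing passes.
#' @export
select_tyi <- function(de, lfc_min = 1, padj_max = 1e-4) {
  assert_columns(de, c("gene", "log2FC", "padj"), "de")
  out <- filter(de, .data$log2FC > lfc_min, .data$padj < padj_max)
  if (!nrow(out)) warn("no genes pass the selection thresholds.")
  out
}

#' Z-score a gene-by-sample expression table
#'
#' Centers and scales each gene to mean 0 and SD 1 across samples.  Genes
#' with zero variance cannot be scaled and are removed with a warning.
#' Idempotent.
#'
#' @param expr Wide tibble: `gene` plus numeric sample columns.
#' @return The z-scored table (possibly fewer rows).
#' @export
zscore_expr <- function(expr) {
  assert_columns(expr, "gene", "expr")
  samples <- sample_columns(expr, "gene")
  m <- as.matrix(expr[samples])
  sds <- apply(m, 1, sd)
  constant <- sds == 0 | is.na(sds)
  if (any(constant)) {
    warn(sprintf("removed %d constant gene(s) before z-scoring.",
                 sum(constant)))
    m <- m[!constant, , drop = FALSE]
    expr <- expr[!constant, ]
    sds <- sds[!constant]
  }
  z <- (m - rowMeans(m)) / sds
  bind_cols(expr["gene"], as_tibble(z))
}

#' Fuzzy c-means clustering of expression profiles
#'
#' Standard fuzzy c-means (Euclidean distance) on z-scored gene profiles:
#' memberships and centroids are alternately updated until the largest
#' centroid shift falls below `tol`, so the objective
#' `sum_{i,j} u_ij^m d(x_i, c_j)^2` is nonincreasing across iterations.
#' Initialization uses farthest-point seeding from a seeded stream (a random
#' first centre, then iteratively the gene farthest from all chosen
#' centres); `n_starts` restarts are run and the solution with the lowest
#' objective kept.  Hard labels take the maximal membership, ties going to
#' the lowest cluster index.
#'
#' @param expr Wide tibble: `gene` plus numeric sample columns (typically
#'   z-scored, see [zscore_expr()]).
#' @param c Number of clusters (default 3).
#' @param m Fuzzifier, > 1; default 1.25, a typical choice for standardized
#'   expression profiles.
#' @param seed Integer seed (initialization only; updates are
#'   deterministic).
#' @param tol Convergence threshold on the maximum absolute centroid shift.
#' @param max_iter Iteration cap; non-convergence is flagged, not an error.
#' @param n_starts Number of random restarts (default 5).
#' @return An `fcm_fit`: list with `membership` (gene x c matrix, rows sum
#'   to 1), `labels` (tibble `gene`, `cluster`, `membership`), `centers`
#'   (c x sample matrix), `m`, `c`, `objective`, `objective_trace`,
#'   `iterations`, `converged`, `seed`.
#' @export
fuzzy_cmeans <- function(expr, c = 3, m = 1.25, seed = 1L, tol = 1e-6,
                         max_iter = 200, n_starts = 5) {
  assert_columns(expr, "gene", "expr")
  samples <- sample_columns(expr, "gene")
  x <- as.matrix(expr[samples])
  rownames(x) <- expr$gene
  if (nrow(x) < c) {
    abort("need at least as many genes as clusters.",
          class = "cooccupy_bad_input")
  }
  if (m <= 1) abort("fuzzifier `m` must be > 1.", class = "cooccupy_bad_input")

  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      centers <- fcm_farthest_point_init(x, c)
      fit <- fcm_iterate(x, centers, m, tol, max_iter)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  })

  u <- best$membership
  labels <- tibble(
    gene = expr$gene,
    cluster = apply(u, 1, which.max),  # ties: first (lowest) index
    membership = apply(u, 1, max)
  )
  structure(
    list(membership = u, labels = labels, centers = best$centers,
         m = m, c = c, objective = best$objective,
         objective_trace = best$trace, iterations = best$iterations,
         converged = best$converged, seed = as.integer(seed)),
    class = "fcm_fit"
  )
}

fcm_farthest_point_init <- function(x, c) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  for (j in seq_len(c - 1)) {
    d2 <- vapply(idx, function(i) rowSums((x - rep(x[i, ], each = n))^2),
                 numeric(n))
    mind <- if (length(idx) == 1) d2[, 1] else apply(d2, 1, min)
    idx <- c(idx, which.max(mind))
  }
  x[idx, , drop = FALSE]
}

fcm_iterate <- function(x, centers, m, tol, max_iter) {
  n <- nrow(x); c <- nrow(centers)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  u <- NULL
  repeat {
    iter <- iter + 1
    d2 <- vapply(seq_len(c), function(j) {
      rowSums((x - rep(centers[j, ], each = n))^2)
    }, numeric(n))
    d2 <- matrix(d2, nrow = n)
    u <- fcm_memberships(d2, m)
    trace <- c(trace, sum(u^m * d2))
    um <- u^m
    new_centers <- t(um) %*% x / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(membership = u, centers = centers, objective = trace[length(trace)],
       trace = trace, iterations = iter, converged = converged)
}

fcm_memberships <- function(d2, m) {
  n <- nrow(d2); c <- ncol(d2)
  u <- matrix(0, n, c)
  zero <- d2 <= .Machine$double.eps
  has_zero <- rowSums(zero) > 0
  if (any(has_zero)) {
    u[has_zero, ] <- zero[has_zero, , drop = FALSE] /
      rowSums(zero[has_zero, , drop = FALSE])
  }
  if (any(!has_zero)) {
    p <- 1 / (m - 1)
    inv <- d2[!has_zero, , drop = FALSE]^(-p)
    u[!has_zero, ] <- inv / rowSums(inv)
  }
  u
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("Fuzzy c-means fit: %d genes, c = %d, m = %g\n",
              nrow(x$membership), x$c, x$m))
  cat(sprintf("  objective %.4f after %d iteration(s)%s\n", x$objective,
              x$iterations, if (x$converged) "" else " (not converged)"))
  print(count(x$labels, .data$cluster))
  invisible(x)
}

#' @method tidy fcm_fit
#' @export
tidy.fcm_fit <- function(x, ...) {
  u <- x$membership
  colnames(u) <- paste0("membership_", seq_len(ncol(u)))
  bind_cols(x$labels, as_tibble(u))
}

#' @method glance fcm_fit
#' @export
glance.fcm_fit <- function(x, ...) {
  tibble(c = x$c, m = x$m, objective = x$objective,
         iterations = x$iterations, converged = x$converged)
}

#' Per-cluster, per-condition-group expression summary
#'
#' Mean (z-scored) expression of each cluster in each condition group — the
#' summary used to read out cluster behaviour (e.g. "induced on activation
#' but blunted under JUN overexpression").
#'
#' @param expr Wide z-scored expression tibble (`gene` + sample columns).
#' @param fit An [fuzzy_cmeans()] fit over the same genes.
#' @param samples Tibble (`sample`, `group`) mapping sample columns to
#'   condition groups.
#' @return Tibble (`cluster`, `group`, `mean_z`, `n_genes`).
#' @export
summarize_clusters <- function(expr, fit, samples) {
  assert_columns(expr, "gene", "expr")
  assert_columns(samples, c("sample", "group"), "samples")
  long <- tidyr::pivot_longer(expr, -"gene", names_to = "sample",
                              values_to = "z") |>
    inner_join(samples, by = "sample") |>
    inner_join(fit$labels[c("gene", "cluster")], by = "gene")
  long |>
    group_by(.data$cluster, .data$group) |>
    summarise(mean_z = mean(.data$z),
              n_genes = dplyr::n_distinct(.data$gene), .groups = "drop")
}

#' @describeIn fuzzy_cmeans Centroid profiles per cluster across samples.
#' @param object An `fcm_fit`.
#' @param ... Unused.
#' @method autoplot fcm_fit
#' @export
autoplot.fcm_fit <- function(object, ...) {
  df <- as_tibble(object$centers) |>
    mutate(cluster = factor(seq_len(nrow(object$centers)))) |>
    tidyr::pivot_longer(-"cluster", names_to = "sample",
                        values_to = "center")
  df$sample <- factor(df$sample, levels = colnames(object$centers))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$center,
                                   colour = .data$cluster,
                                   group = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "centroid (z-score)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
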