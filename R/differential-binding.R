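#' Test regions for differential binding between two conditions
#'
#' A transparent moderated test on spike-normalized counts: per region, a
#' two-sample t-test on `log2(count + pseudocount)` across replicates, with
#' the pooled per-region variance floored at a global quantile of all
#' per-region variances.  The floor stabilizes the tiny-replicate variance
#' estimate and suppresses spuriously significant low-variance regions, in
#' the spirit of moderated differential tests, while staying hand-checkable.
#' P-values are BH-adjusted over all tested regions; `M` (log2 fold change)
#' and `A` (mean log2 signal) are reported for MA plots.
#'
#' @param counts Wide tibble: `region` plus one column per sample, already
#'   spike-in normalized (see [normalize_counts()]).
#' @param design Tibble (`sample`, `condition`, ...) mapping each sample
#'   column to its condition.
#' @param contrast Length-2 character vector `c(numerator, denominator)`;
#'   `M > 0` means more binding in the numerator condition.
#' @param padj_threshold Regions with `padj` below this (default 0.1) are
#'   called `up`/`down`, others `ns`.
#' @param pseudocount Added before log2 (default 0.5) to absorb zeros.
#' @param var_floor_quantile Quantile of the pooled per-region variances used
#'   as the variance floor (default 0.05).
#' @return A `dbr_result` tibble: `region`, `A`, `M`, `p`, `padj`,
#'   `direction` (`up`/`down`/`ns`).
#' @export
test_differential <- function(counts, design, contrast = c("ON", "OFF"),
                              padj_threshold = 0.1, pseudocount = 0.5,
                              var_floor_quantile = 0.05) {
  assert_columns(counts, "region", "counts")
  assert_columns(design, c("sample", "condition"), "design")
  if (length(contrast) != 2) {
    abort("`contrast` must name two conditions.", class = "cooccupy_bad_input")
  }
  s1 <- design$sample[design$condition == contrast[1]]
  s0 <- design$sample[design$condition == contrast[2]]
  s1 <- intersect(s1, names(counts))
  s0 <- intersect(s0, names(counts))
  if (length(s1) < 2 || length(s0) < 2) {
    abort("each contrasted condition needs at least 2 replicate columns.",
          class = "cooccupy_bad_input")
  }
  x1 <- log2(as.matrix(counts[s1]) + pseudocount)
  x0 <- log2(as.matrix(counts[s0]) + pseudocount)
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- apply(x1, 1, var); v0 <- apply(x0, 1, var)
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  floor_var <- quantile(s2, var_floor_quantile, names = FALSE)
  se <- sqrt(pmax(s2, floor_var) * (1 / n1 + 1 / n0))
  M <- m1 - m0
  A <- rowMeans(cbind(x1, x0))
  tstat <- ifelse(se == 0, ifelse(M == 0, 0, sign(M) * Inf), M / se)
  p <- 2 * pt(-abs(tstat), df = n1 + n0 - 2)
  padj <- p.adjust(p, method = "BH")
  out <- tibble(region = counts$region, A = A, M = M, p = p, padj = padj,
                direction = ifelse(padj < padj_threshold,
                                   ifelse(M > 0, "up", "down"), "ns"))
  class(out) <- c("dbr_result", class(out))
  attr(out, "contrast") <- contrast
  attr(out, "padj_threshold") <- padj_threshold
  out
}

#' Stratify peaks by joint differential-binding behaviour of two factors
#'
#' Combines the differential-binding calls of two factors over the same
#' region universe into mutually exclusive co-occupancy-change categories:
#' `"Joint"` (significant for both), `"A only"` / `"B only"` (significant
#' for exactly one; names taken from `labels`), `"none"` otherwise.
#'
#' @param dbr_a,dbr_b [test_differential()] results over identical regions.
#' @param labels Length-2 character vector naming the two factors (default
#'   `c("A", "B")`), used to build the category strings.
#' @param padj_threshold Significance cutoff applied to both results
#'   (default 0.1).
#' @return Tibble (`region`, `category`) with an attached `counts` attribute
#'   (`dplyr::count` of the categories).
#' @export
stratify_peaks <- function(dbr_a, dbr_b, labels = c("A", "B"),
                           padj_threshold = 0.1) {
  assert_columns(dbr_a, c("region", "padj"), "dbr_a")
  assert_columns(dbr_b, c("region", "padj"), "dbr_b")
  if (!setequal(dbr_a$region, dbr_b$region) ||
      nrow(dbr_a) != nrow(dbr_b)) {
    abort("the two DBR results cover different region universes.",
          class = "cooccupy_bad_input")
  }
  b <- dbr_b[match(dbr_a$region, dbr_b$region), ]
  sig_a <- dbr_a$padj < padj_threshold
  sig_b <- b$padj < padj_threshold
  category <- dplyr::case_when(
    sig_a & sig_b ~ "Joint",
    sig_a ~ paste(labels[1], "only"),
    sig_b ~ paste(labels[2], "only"),
    .default = "none"
  )
  out <- tibble(region = dbr_a$region, category = category)
  attr(out, "counts") <- count(out, .data$category)
  out
}

#' MA plot of a differential-binding result
#'
#' @param object A `dbr_result` from [test_differential()].
#' @param ... Unused.
#' @method autoplot dbr_result
#' @export
autoplot.dbr_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$A, y = .data$M,
                                       colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean log2 normalized count (A)",
                  y = "log2 fold change (M)") +
    ggplot2::theme_minimal()
}
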