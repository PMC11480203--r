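#' Depth-normalize sgRNA counts
#'
#' `(count + pseudocount) / library_size * 1e6` — reads per million with a
#' +1 pseudocount so downstream ratios never divide by zero.
#'
#' @param counts Tibble: `sgrna`, `gene`, plus one numeric count column per
#'   sample.
#' @param lib_sizes Named numeric vector of library sizes (mapped reads) per
#'   sample column; defaults to the column sums.
#' @param pseudocount Added to every count before scaling (default 1).
#' @return `counts` with sample columns replaced by normalized values.
#' @export
normalize_depth <- function(counts, lib_sizes = NULL, pseudocount = 1) {
  assert_columns(counts, c("sgrna", "gene"), "counts")
  samples <- sample_columns(counts, c("sgrna", "gene"))
  if (is.null(lib_sizes)) {
    lib_sizes <- vapply(counts[samples], sum, numeric(1))
  }
  missing <- setdiff(samples, names(lib_sizes))
  if (length(missing)) {
    abort(sprintf("no library size for sample(s): %s",
                  paste(missing, collapse = ", ")),
          class = "cooccupy_bad_input")
  }
  if (any(lib_sizes[samples] <= 0)) {
    abort("library sizes must be positive.", class = "cooccupy_bad_input")
  }
  out <- counts
  for (s in samples) {
    out[[s]] <- (out[[s]] + pseudocount) / lib_sizes[[s]] * 1e6
  }
  out
}

#' Per-sgRNA log2 fold change
#'
#' `log2(selected / baseline)` on depth-normalized values.  Rows with a
#' missing value in either condition are excluded with a warning.
#'
#' @param normalized Output of [normalize_depth()].
#' @param selected,baseline Names of the two sample columns.
#' @return Tibble (`sgrna`, `gene`, `log2fc`).
#' @export
sgrna_log2fc <- function(normalized, selected = "selected",
                         baseline = "baseline") {
  assert_columns(normalized, c("sgrna", "gene", selected, baseline),
                 "normalized")
  ok <- complete.cases(normalized[c(selected, baseline)])
  if (any(!ok)) {
    warn(sprintf("excluded %d sgRNA(s) missing in one condition.", sum(!ok)))
  }
  d <- normalized[ok, ]
  tibble(sgrna = d$sgrna, gene = d$gene,
         log2fc = log2(d[[selected]] / d[[baseline]]))
}

#' RSA activity bounds from the score distribution
#'
#' The screen's hit-calling bounds derived from the per-sgRNA scores:
#' lower bound `l = median + 1 * SD`, upper bound `u = median + 3 * SD`.
#' With zero variance both collapse to the median and the result is flagged
#' degenerate.
#'
#' @param scores Numeric vector of per-sgRNA scores, or a tibble with a
#'   `log2fc` column.
#' @return An `rsa_bounds` list: `l`, `u`, `median`, `sd`, `degenerate`.
#' @examples
#' derive_bounds(c(-1, 0, 1))  # median 0: l = SD, u = 3 SD
#' @export
derive_bounds <- function(scores) {
  if (is.data.frame(scores)) {
    assert_columns(scores, "log2fc", "scores")
    scores <- scores$log2fc
  }
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2) {
    abort("need at least 2 scores to derive bounds.",
          class = "cooccupy_bad_input")
  }
  med <- median(scores)
  s <- sd(scores)
  structure(list(l = med + 1 * s, u = med + 3 * s, median = med, sd = s,
                 degenerate = s == 0),
            class = "rsa_bounds")
}

#' Redundant-siRNA-activity (RSA) gene scores
#'
#' Integrates all sgRNAs of a gene into one enrichment p-value.  All sgRNAs
#' are ranked by score, descending; tied scores share the worst (largest)
#' rank of their block, which is the conservative deterministic variant of
#' the original tie handling.  For a gene with `K` sgRNAs whose candidate
#' sgRNAs (score >= `l`) sit at overall ranks `r_1 <= r_2 <= ...`, the gene
#' p-value is the minimum over `i` of the hypergeometric tail
#' `P(X >= i)` with `X ~ Hypergeom(N, r_i, K)` — the chance that at least
#' `i` of the gene's `K` sgRNAs land in the top `r_i` of all `N` by luck.
#' A gene is eligible only if its best sgRNA reaches `u`; ineligible genes
#' (and genes with no sgRNA above `l`) report `p = 1`.  The RSA p is a
#' ranked readout, not a calibrated p-value; no multiple-testing correction
#' is applied.
#'
#' @param scores Tibble (`sgrna`, `gene`, `log2fc`) as from
#'   [sgrna_log2fc()].
#' @param bounds An [derive_bounds()] result; derived from `scores` when
#'   `NULL`.
#' @return Tibble, one row per gene, sorted by `p`: `gene`, `p`, `log_p`
#'   (log10), `best_rank` (cutoff achieving the minimum), `n_sgrna`,
#'   `n_candidate` (sgRNAs >= `l`), `mean_log2fc`.
#' @export
rsa_score <- function(scores, bounds = NULL) {
  assert_columns(scores, c("sgrna", "gene", "log2fc"), "scores")
  if (any(!is.finite(scores$log2fc))) {
    abort("scores must be finite.", class = "cooccupy_bad_input")
  }
  if (is.null(bounds)) bounds <- derive_bounds(scores)
  stopifnot(inherits(bounds, "rsa_bounds"))

  # deterministic order: score descending, sgrna id as tie-break
  scores <- arrange(scores, dplyr::desc(.data$log2fc), .data$sgrna)
  n_total <- nrow(scores)
  worst_rank <- rank(-scores$log2fc, ties.method = "max")

  per_gene <- function(ix) {
    s <- scores$log2fc[ix]
    r <- worst_rank[ix]
    k <- length(ix)
    cand <- which(s >= bounds$l)
    if (!length(cand) || s[1] < bounds$u) {
      return(c(p = 1, best_rank = NA_real_, n_candidate = length(cand)))
    }
    tails <- phyper(seq_along(cand) - 1, r[cand], n_total - r[cand], k,
                    lower.tail = FALSE)
    j <- which.min(tails)
    c(p = tails[j], best_rank = r[cand[j]], n_candidate = length(cand))
  }
  idx <- split(seq_len(n_total), scores$gene)
  stats <- vapply(idx, per_gene, numeric(3))
  means <- vapply(idx, function(ix) mean(scores$log2fc[ix]), numeric(1))
  tibble(gene = names(idx),
         p = unname(stats["p", ]),
         log_p = unname(log10(stats["p", ])),
         best_rank = unname(stats["best_rank", ]),
         n_sgrna = unname(lengths(idx)),
         n_candidate = as.integer(stats["n_candidate", ]),
         mean_log2fc = unname(means)) |>
    arrange(.data$p, .data$gene)
}
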