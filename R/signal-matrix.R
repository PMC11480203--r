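#' Positional tag-density matrix around reference points
#'
#' Bins signal tags into fixed-width windows centred on reference intervals
#' (a reference-point matrix, as used for binding heatmaps): row *i*, column
#' *j* holds the summed signal in
#' `[center_i - window + (j-1) * bin, center_i - window + j * bin)`.
#'
#' @param signal Tibble of tags: `chrom`, `pos`, `value` (one row per tag or
#'   per covered base).
#' @param ref Reference intervals (`chrom`, `start`, `end`, optional `name`);
#'   centers are `floor((start + end) / 2)`.
#' @param window Half-width of the window around each center, bp.
#' @param bin Bin width, bp; `2 * window` must be a multiple of `bin`.
#' @param sort_rows Row order: `"total"` (descending row sum, the
#'   sorted-heatmap convention), `"none"`, or a numeric key of length
#'   `nrow(ref)` sorted descending.
#' @param genome Optional genome tibble (`chrom`, `length`); reference
#'   points whose window leaves the chromosome get a zero row and a warning.
#' @return A `signal_matrix`: numeric matrix (regions x bins) with
#'   attributes `bin`, `window`, and column names giving each bin's offset
#'   from the center.
#' @export
tag_density_matrix <- function(signal, ref, window, bin,
                               sort_rows = "total", genome = NULL) {
  assert_columns(signal, c("chrom", "pos", "value"), "signal")
  assert_columns(ref, c("chrom", "start", "end"), "ref")
  if (window <= 0 || bin <= 0 || (2 * window) %% bin != 0) {
    abort("`window` must be a positive multiple of `bin`.",
          class = "cooccupy_bad_input")
  }
  k <- as.integer(2 * window / bin)
  centers <- floor((ref$start + ref$end) / 2)
  rn <- if ("name" %in% names(ref)) ref$name else as.character(seq_len(nrow(ref)))
  mat <- matrix(0, nrow = nrow(ref), ncol = k,
                dimnames = list(rn, seq_len(k) * bin - window - bin))
  oob <- logical(nrow(ref))
  for (ch in unique(ref$chrom)) {
    si <- which(signal$chrom == ch)
    ri <- which(ref$chrom == ch)
    if (!is.null(genome)) {
      len <- genome$length[match(ch, genome$chrom)]
      bad <- centers[ri] - window < 0 | centers[ri] + window > len
      oob[ri[bad]] <- TRUE
      ri <- ri[!bad]
    }
    if (!length(si) || !length(ri)) next
    pos <- signal$pos[si]
    val <- signal$value[si]
    ord <- order(pos)
    pos <- pos[ord]; val <- val[ord]
    cv <- c(0, cumsum(val))
    for (i in ri) {
      edges <- centers[i] - window + bin * (0:k)
      at <- findInterval(edges - 0.5, pos)  # tags with pos < edge
      mat[i, ] <- diff(cv[at + 1])
    }
  }
  if (any(oob)) {
    warn(sprintf("%d reference point(s) fall outside their chromosome; rows set to zero.",
                 sum(oob)))
  }
  key <- if (identical(sort_rows, "total")) rowSums(mat)
         else if (identical(sort_rows, "none")) NULL
         else if (is.numeric(sort_rows) && length(sort_rows) == nrow(mat)) sort_rows
         else abort("invalid `sort_rows`.", class = "cooccupy_bad_input")
  if (!is.null(key)) mat <- mat[order(key, decreasing = TRUE), , drop = FALSE]
  structure(mat, bin = bin, window = window, class = c("signal_matrix", "matrix"))
}

#' Log2 ratio of two signal matrices
#'
#' Elementwise `log2((a + pseudocount) / (b + pseudocount))` for two
#' matched-dimension signal matrices — the comparison track between two
#' conditions.  Antisymmetric under swapping `a` and `b`.
#'
#' @param a,b `signal_matrix` objects (or plain matrices) of equal dimension.
#' @param pseudocount Added to both matrices before the ratio; defaults to 1
#'   normalized unit.
#' @return A `signal_matrix` of log2 ratios.
#' @export
log2_ratio_matrix <- function(a, b, pseudocount = 1) {
  if (!all(dim(a) == dim(b))) {
    abort("`a` and `b` must have identical dimensions.",
          class = "cooccupy_bad_input")
  }
  out <- log2((unclass(a) + pseudocount) / (unclass(b) + pseudocount))
  structure(out, bin = attr(a, "bin"), window = attr(a, "window"),
            class = c("signal_matrix", "matrix"))
}

#' @method tidy signal_matrix
#' @export
tidy.signal_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(region = rep(rownames(m), ncol(m)),
         offset = rep(as.numeric(colnames(m)), each = nrow(m)),
         value = as.vector(m))
}

#' @describeIn tag_density_matrix Heatmap of a signal matrix (rows in their
#'   stored order).
#' @param object A `signal_matrix`.
#' @param ... Unused.
#' @method autoplot signal_matrix
#' @export
autoplot.signal_matrix <- function(object, ...) {
  df <- tidy.signal_matrix(object)
  df$region <- factor(df$region, levels = rev(rownames(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$region,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "offset from reference point (bp)", y = NULL,
                  fill = "signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
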