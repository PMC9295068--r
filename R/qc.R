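#' Pairwise Pearson correlation of normalized counts
#'
#' Correlation of `log2(normalized count + 1)` between all sample pairs —
#' the standard screen-QC check that replicate and related samples cluster
#' together. Zero-variance samples yield `NA` entries with a warning.
#'
#' @param counts matrix or [screen_counts()].
#' @param size_factors per-sample size factors (default: estimated with a
#'   pseudo-reference so bottlenecked samples are handled).
#' @param log log2(x+1)-transform normalized counts before correlating
#'   (default `TRUE`).
#' @return symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
pearson_matrix <- function(counts, size_factors = NULL, log = TRUE) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else as.matrix(counts)
  stopifnot(ncol(m) >= 2L)
  if (is.null(size_factors)) {
    size_factors <- estimate_size_factors(m, pseudo_reference = TRUE)
  }
  q <- sweep(m, 2L, size_factors, "/")
  if (log) q <- log2(q + 1)
  zero_var <- apply(q, 2L, stats::sd) == 0
  if (any(zero_var)) {
    warning("zero-variance sample(s): ",
            paste(colnames(q)[zero_var], collapse = ", "),
            "; correlations reported as NA")
  }
  r <- suppressWarnings(stats::cor(q, method = "pearson"))
  diag(r) <- 1
  r
}

#' Number of detected guides per sample
#'
#' @param counts matrix or [screen_counts()].
#' @return integer vector: per-sample number of guides with raw count > 0.
#' @export
unique_sgrnas <- function(counts) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else as.matrix(counts)
  colSums(m > 0L)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum gap between the two empirical CDFs; the p-value uses
#' the asymptotic Kolmogorov distribution (adequate at library scale).
#'
#' @param x,y non-empty numeric vectors (e.g. two samples' counts).
#' @return list with `D` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Empirical cumulative distribution of a sample's counts
#'
#' @param counts matrix or [screen_counts()].
#' @param sample sample id (column name) or index.
#' @return data.frame with sorted unique `count` values and the
#'   `cumulative_probability` of guides at or below each; the last
#'   probability is 1.
#' @export
cumulative_distribution <- function(counts, sample) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else as.matrix(counts)
  x <- m[, sample]
  if (length(x) == 0L) stop("empty sample")
  v <- sort(unique(x))
  data.frame(count = v,
             cumulative_probability = stats::ecdf(x)(v))
}

#' Screen-level quality-control report
#'
#' Bundles the representation and concordance diagnostics usually shown
#' for a pooled screen: the pairwise Pearson matrix of log-normalized
#' counts, per-sample detected-guide numbers, normalized-count quartiles,
#' and all pairwise two-sample KS comparisons of the count distributions.
#'
#' @param counts a [screen_counts()].
#' @param log log-transform before correlation (default `TRUE`).
#' @return An object of class `screen_qc`: list with `pearson`,
#'   `unique_sgrnas`, `count_summaries` (5-number quartile matrix of
#'   normalized counts), `ks` (data.frame sample_a, sample_b, D, p_value),
#'   `size_factors`.
#' @export
screen_qc <- function(counts, log = TRUE) {
  stopifnot(inherits(counts, "screen_counts"))
  m <- counts$counts
  sf <- estimate_size_factors(m, pseudo_reference = TRUE)
  q <- sweep(m, 2L, sf, "/")
  pairs <- utils::combn(colnames(m), 2L)
  ks <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    res <- ks_two_sample(q[, pairs[1L, i]], q[, pairs[2L, i]])
    data.frame(sample_a = pairs[1L, i], sample_b = pairs[2L, i],
               D = res$D, p_value = res$p_value,
               stringsAsFactors = FALSE)
  }))
  structure(list(
    pearson = pearson_matrix(m, sf, log = log),
    unique_sgrnas = unique_sgrnas(m),
    count_summaries = apply(q, 2L, stats::quantile,
                            probs = c(0, 0.25, 0.5, 0.75, 1)),
    ks = ks,
    size_factors = sf,
    sample_meta = counts$sample_meta),
    class = "screen_qc")
}

#' @export
print.screen_qc <- function(x, ...) {
  cat("screen QC —", length(x$unique_sgrnas), "samples\n")
  cat("detected guides per sample:\n")
  print(x$unique_sgrnas)
  cat("min / median off-diagonal Pearson r: ",
      round(min(x$pearson[lower.tri(x$pearson)]), 3), " / ",
      round(stats::median(x$pearson[lower.tri(x$pearson)]), 3), "\n", sep = "")
  cat("max pairwise KS D: ", round(max(x$ks$D), 3), "\n", sep = "")
  invisible(x)
}

#' Plot a QC report
#'
#' Three base-graphics panels echoing the standard screen-QC figure:
#' correlation heatmap, per-sample boxplots of log normalized counts, and
#' overlaid per-sample ECDFs.
#'
#' @param x a [screen_qc()] report.
#' @param counts the [screen_counts()] the report was built from (needed
#'   for the boxplot/ECDF panels; omit to draw only the heatmap).
#' @param ... ignored.
#' @method plot screen_qc
#' @export
plot.screen_qc <- function(x, counts = NULL, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(counts)) 1 else 3),
                      mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  r <- x$pearson
  n <- ncol(r)
  graphics::image(seq_len(n), seq_len(n), t(r[n:1, ]),
                  zlim = c(min(r, na.rm = TRUE), 1),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Pearson r (log normalized counts)")
  graphics::axis(1, seq_len(n), colnames(r), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(r)), las = 2, cex.axis = 0.7)
  if (!is.null(counts)) {
    q <- sweep(counts$counts, 2L, x$size_factors, "/")
    graphics::boxplot(log2(q + 1), las = 2, cex.axis = 0.7,
                      ylab = "log2 normalized count + 1",
                      main = "Library representation")
    graphics::plot(NA, xlim = range(log2(q + 1)), ylim = c(0, 1),
                   xlab = "log2 normalized count + 1",
                   ylab = "cumulative probability",
                   main = "Guide abundance ECDF")
    cols <- grDevices::rainbow(ncol(q))
    for (j in seq_len(ncol(q))) {
      graphics::lines(stats::ecdf(log2(q[, j] + 1)), col = cols[j],
                      do.points = FALSE)
    }
    graphics::legend("bottomright", colnames(q), col = cols, lty = 1,
                     cex = 0.6, bty = "n")
  }
  invisible(x)
}
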