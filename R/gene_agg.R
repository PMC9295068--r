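#' Combine p-values by Fisher's method
#'
#' \eqn{X^2 = -2\sum_i \ln p_i} follows a chi-squared distribution with
#' \eqn{2k} degrees of freedom under the joint null; the combined p-value
#' is its upper tail. Inputs are clipped to `[1e-300, 1]` so the statistic
#' stays finite. With a single p-value the combination is the identity.
#'
#' @param p_values non-empty numeric vector of p-values in (0, 1].
#' @return list with `fisher_x2`, `df` (= 2k) and `combined_p`.
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0L) stop("fisher_combine needs at least one p-value")
  p <- pmin(1, pmax(as.numeric(p_values), 1e-300))
  x2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(fisher_x2 = x2, df = df,
       combined_p = max(stats::pchisq(x2, df = df, lower.tail = FALSE),
                        1e-300))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j},
#' capped at 1 and mapped back to input order. Thin wrapper over
#' [stats::p.adjust()] kept as the package's single adjustment surface.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Aggregate per-guide statistics to the gene level
#'
#' Collapses per-guide differential-abundance results to one row per
#' target: the arithmetic mean of member-guide log2 fold changes (a flag
#' switches to the log2 of the mean linear fold change), Fisher's-method
#' combination of the guide p-values, and Benjamini-Hochberg correction
#' across all aggregated targets. Non-targeting controls are excluded.
#' miRNA targets aggregate exactly like genes, keeping their class in the
#' output. Guides that were all-zero in every sample carry no information,
#' so targets whose guides are all all-zero are omitted from the BH family.
#'
#' @param guide_stats data.frame from [nb_wald_test()] or the `table` of a
#'   [screen_da()] fit (a `screen_da` object is also accepted).
#' @param library the [sgrna_library()] the guides came from; every guide
#'   must map to a library record.
#' @param alternative `"two.sided"` (default) combines the two-sided guide
#'   p-values; `"greater"` converts them to one-sided enrichment p-values
#'   (recommended for positive-selection resistance screens).
#' @param fc_mean `"log"` (default) averages log2 fold changes;
#'   `"linear"` averages linear fold changes and reports its log2.
#' @return data.frame of class `gene_stats`: `target_id`, `target_class`,
#'   `n_guides`, `mean_log2fc`, `direction` (sign of `mean_log2fc`),
#'   `fisher_x2`, `df`, `combined_p`, `q_value`, ordered by `combined_p`.
#' @export
aggregate_genes <- function(guide_stats, library,
                            alternative = c("two.sided", "greater"),
                            fc_mean = c("log", "linear")) {
  if (inherits(guide_stats, "screen_da")) guide_stats <- guide_stats$table
  alternative <- match.arg(alternative)
  fc_mean <- match.arg(fc_mean)
  stopifnot(inherits(library, "sgrna_library"),
            all(c("sgrna_id", "log2fc", "p_value") %in% names(guide_stats)))
  pos <- match(guide_stats$sgrna_id, library$sgrna_id)
  if (anyNA(pos)) {
    stop("guide(s) absent from library: ",
         paste(utils::head(guide_stats$sgrna_id[is.na(pos)], 5L),
               collapse = ", "))
  }
  gs <- guide_stats
  gs$target_id <- library$target_id[pos]
  gs$target_class <- library$target_class[pos]
  gs <- gs[gs$target_class != "non_targeting", , drop = FALSE]
  if (nrow(gs) == 0L) stop("no targeting guides to aggregate")

  p_in <- gs$p_value
  if (alternative == "greater") {
    p_in <- ifelse(gs$log2fc > 0, p_in / 2, 1 - p_in / 2)
  }
  gs$p_comb <- pmin(1, pmax(p_in, 1e-300))

  if ("all_zero" %in% names(gs)) {
    informative <- !tapply(gs$all_zero, gs$target_id, all)
  } else {
    informative <- tapply(rep(TRUE, nrow(gs)), gs$target_id, any)
  }
  split_idx <- split(seq_len(nrow(gs)), gs$target_id)
  targets <- names(split_idx)
  res <- do.call(rbind, lapply(targets, function(tg) {
    i <- split_idx[[tg]]
    fc <- if (fc_mean == "log") mean(gs$log2fc[i]) else
      log2(mean(2^gs$log2fc[i]))
    f <- fisher_combine(gs$p_comb[i])
    data.frame(target_id = tg,
               target_class = gs$target_class[i[1L]],
               n_guides = length(i),
               mean_log2fc = fc,
               direction = sign(fc),
               fisher_x2 = f$fisher_x2,
               df = f$df,
               combined_p = f$combined_p,
               stringsAsFactors = FALSE)
  }))
  res <- res[informative[res$target_id], , drop = FALSE]
  res$q_value <- bh_adjust(res$combined_p)
  res <- res[order(res$combined_p, res$target_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("gene_stats", "data.frame")
  res
}

#' @export
print.gene_stats <- function(x, n = 10L, ...) {
  cat("gene-level aggregation: ", nrow(x), " targets (",
      sum(x$q_value < 0.05), " with q < 0.05)\n", sep = "")
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more rows\n", sep = "")
  invisible(x)
}
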