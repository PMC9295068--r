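#' Hit-calling configuration
#'
#' Thresholds and ranking rules for identifying enriched guides: a guide is
#' a candidate when its treated-arm count exceeds `min_count` AND its log2
#' fold change exceeds `min_log2fc` (both strictly). Per-comparison top-N
#' cut-offs select the most enriched guides in each arm; their intersection
#' across arms gives the core guide/gene set.
#'
#' @param min_count raw/normalized count threshold, strict `>` (default 100).
#' @param min_log2fc log2 fold-change threshold, strict `>` (default 3).
#' @param top_n named integer vector of per-comparison top-N sizes
#'   (defaults: `lenvatinib_cell` 600, `primary_tumor` 400,
#'   `lung_metastasis` 200).
#' @param rank_key ranking variable for the top-N, `"log2fc"` (default) or
#'   `"count"`.
#' @param use_normalized use replicate-averaged normalized counts for the
#'   count threshold and trend ordering (default); `FALSE` restores raw
#'   treated-arm maxima.
#' @return list of class `hitcall_config`.
#' @export
hitcall_config <- function(min_count = 100, min_log2fc = 3,
                           top_n = c(lenvatinib_cell = 600L,
                                     primary_tumor = 400L,
                                     lung_metastasis = 200L),
                           rank_key = c("log2fc", "count"),
                           use_normalized = TRUE) {
  rank_key <- match.arg(rank_key)
  stopifnot(min_count >= 0, min_log2fc >= 0, all(top_n > 0))
  structure(list(min_count = min_count, min_log2fc = min_log2fc,
                 top_n = top_n, rank_key = rank_key,
                 use_normalized = isTRUE(use_normalized)),
            class = "hitcall_config")
}

# Pick the count column used by thresholds: normalized treated-arm mean
# when available, otherwise the raw treated-arm maximum.
hit_count_column <- function(stats, cfg) {
  if (cfg$use_normalized && "treated_norm_count" %in% names(stats)) {
    stats$treated_norm_count
  } else {
    stats$treated_raw_count
  }
}

#' Threshold-based enriched-guide calling
#'
#' A guide survives iff its treated-arm count is strictly greater than
#' `min_count` and its log2 fold change strictly greater than `min_log2fc`.
#'
#' @param stats per-guide data.frame with `sgrna_id`, `log2fc` and a count
#'   column (`treated_norm_count` if present and configured, else
#'   `treated_raw_count`).
#' @param cfg a [hitcall_config()].
#' @return character vector of surviving sgrna_ids.
#' @export
threshold_hits <- function(stats, cfg = hitcall_config()) {
  cnt <- hit_count_column(stats, cfg)
  stats$sgrna_id[cnt > cfg$min_count & stats$log2fc > cfg$min_log2fc]
}

#' Top-N most enriched guides
#'
#' Guides are sorted by the ranking key in decreasing order; ties are
#' broken by smaller p-value, then lexicographic sgrna_id, so the selection
#' is deterministic. Requesting more guides than available returns all of
#' them with a warning.
#'
#' @param stats per-guide data.frame with `sgrna_id`, `log2fc`, `p_value`
#'   and count columns.
#' @param n number of guides to return.
#' @param cfg a [hitcall_config()]; `cfg$rank_key` selects the ranking
#'   variable.
#' @return character vector of sgrna_ids, most enriched first.
#' @export
top_n_guides <- function(stats, n, cfg = hitcall_config()) {
  key <- if (cfg$rank_key == "log2fc") stats$log2fc else
    hit_count_column(stats, cfg)
  if (n > nrow(stats)) {
    warning("requested top ", n, " of ", nrow(stats), " guides; returning all")
    n <- nrow(stats)
  }
  ord <- order(-key, stats$p_value, stats$sgrna_id)
  stats$sgrna_id[ord][seq_len(n)]
}

#' Core guides and genes across screen arms
#'
#' Intersects the per-comparison top-enriched guide sets; the targets of
#' the surviving guides are the core ("coexpressed") resistance genes —
#' genes whose knockout enriches in every screened condition.
#'
#' @param top_sets named list (>= 2 elements) of sgrna_id character
#'   vectors, one per comparison.
#' @param library the [sgrna_library()].
#' @return list with `core_guides` (sorted sgrna_ids present in every set)
#'   and `core_genes` (their distinct targets).
#' @export
core_intersection <- function(top_sets, library) {
  stopifnot(length(top_sets) >= 2L, inherits(library, "sgrna_library"))
  core <- sort(Reduce(intersect, top_sets))
  genes <- sort(unique(library$target_id[match(core, library$sgrna_id)]))
  list(core_guides = core, core_genes = genes[!is.na(genes)])
}

#' Trend-group guides
#'
#' Guides whose counts increase strictly along the in vivo progression
#' axis: lung metastasis > primary tumor > drug-treated cells. Replicates
#' are collapsed by the mean of normalized counts (size factors estimated
#' across the three arms), or of raw counts when `cfg$use_normalized` is
#' `FALSE`.
#'
#' @param counts a [screen_counts()] containing the `lenvatinib_cell`,
#'   `primary_tumor` and `lung_metastasis` conditions.
#' @param cfg a [hitcall_config()].
#' @return character vector of sgrna_ids in the trend group.
#' @export
trend_group <- function(counts, cfg = hitcall_config()) {
  stopifnot(inherits(counts, "screen_counts"))
  need <- c("lenvatinib_cell", "primary_tumor", "lung_metastasis")
  cond <- counts$sample_meta$condition
  if (!all(need %in% cond)) {
    stop("counts must contain conditions: ", paste(need, collapse = ", "))
  }
  keep <- cond %in% need
  m <- counts$counts[, keep, drop = FALSE]
  cond <- cond[keep]
  if (cfg$use_normalized) {
    sf <- estimate_size_factors(m, pseudo_reference = TRUE)
    m <- sweep(m, 2L, sf, "/")
  }
  avg <- sapply(need, function(cc)
    rowMeans(m[, cond == cc, drop = FALSE]))
  sel <- avg[, "lung_metastasis"] > avg[, "primary_tumor"] &
    avg[, "primary_tumor"] > avg[, "lenvatinib_cell"]
  rownames(counts$counts)[sel]
}

#' Call hits across all screen comparisons
#'
#' Runs the full hit-identification logic over a set of fitted
#' comparisons: per-comparison threshold survivors, top-N enriched guides
#' (selected among guides passing the count filter), the cross-condition
#' core intersection, and the in vivo trend group.
#'
#' @param fits named list of [screen_da()] fits; names are the treated
#'   condition labels and must have entries in `cfg$top_n`.
#' @param library the [sgrna_library()].
#' @param counts the full [screen_counts()] (used for normalized treated
#'   counts and the trend group); optional — without it raw treated maxima
#'   are used and the trend group is skipped.
#' @param cfg a [hitcall_config()].
#' @return An object of class `hit_report`: list with `threshold_hits`,
#'   `n_enriched`, `top_sets`, `core_guides`, `core_genes`, `trend_guides`,
#'   `config`.
#' @export
call_hits <- function(fits, library, counts = NULL,
                      cfg = hitcall_config()) {
  stopifnot(length(fits) >= 1L, !is.null(names(fits)))
  tabs <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    stopifnot(inherits(fit, "screen_da"))
    tab <- fit$table
    if (!is.null(counts)) {
      cond <- counts$sample_meta$condition
      sf <- estimate_size_factors(counts$counts, pseudo_reference = TRUE)
      q <- sweep(counts$counts, 2L, sf, "/")
      tab$treated_norm_count <-
        rowMeans(q[, cond == fit$treated, drop = FALSE])[tab$sgrna_id]
    }
    tab
  })
  names(tabs) <- names(fits)

  thr <- lapply(tabs, threshold_hits, cfg = cfg)
  top_sets <- lapply(names(tabs), function(nm) {
    tab <- tabs[[nm]]
    pool <- tab[hit_count_column(tab, cfg) > cfg$min_count, , drop = FALSE]
    n <- if (nm %in% names(cfg$top_n)) cfg$top_n[[nm]] else
      stop("no top_n entry for comparison '", nm, "'")
    top_n_guides(pool, min(n, nrow(pool)), cfg)
  })
  names(top_sets) <- names(tabs)

  core <- if (length(top_sets) >= 2L) {
    core_intersection(top_sets, library)
  } else {
    list(core_guides = top_sets[[1L]],
         core_genes = sort(unique(
           library$target_id[match(top_sets[[1L]], library$sgrna_id)])))
  }
  trend <- if (!is.null(counts) &&
               all(c("lenvatinib_cell", "primary_tumor", "lung_metastasis")
                   %in% counts$sample_meta$condition)) {
    trend_group(counts, cfg)
  } else {
    character(0)
  }
  structure(list(threshold_hits = thr,
                 n_enriched = vapply(thr, length, integer(1)),
                 top_sets = top_sets,
                 core_guides = core$core_guides,
                 core_genes = core$core_genes,
                 trend_guides = trend,
                 config = cfg),
            class = "hit_report")
}

#' @export
print.hit_report <- function(x, ...) {
  cat("hit report\n")
  for (nm in names(x$top_sets)) {
    cat("  ", nm, ": ", x$n_enriched[[nm]], " guides past thresholds (count > ",
        x$config$min_count, ", log2FC > ", x$config$min_log2fc,
        "); top set of ", length(x$top_sets[[nm]]), "\n", sep = "")
  }
  cat("  core guides: ", length(x$core_guides),
      " -> core genes: ", paste(x$core_genes, collapse = ", "), "\n", sep = "")
  cat("  trend-group guides (metastasis > primary > drug cells): ",
      length(x$trend_guides), "\n", sep = "")
  invisible(x)
}

#' Write a hit report to disk
#'
#' @param x a `hit_report`.
#' @param dir output directory (created if needed): `hit_report.json` plus
#'   TSVs of core guides/genes and trend guides.
#' @return `dir`, invisibly.
#' @export
write_hit_report <- function(x, dir) {
  stopifnot(inherits(x, "hit_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(n_enriched = as.list(x$n_enriched),
         top_set_sizes = lapply(x$top_sets, length),
         core_guides = x$core_guides,
         core_genes = x$core_genes,
         n_trend_guides = length(x$trend_guides),
         config = unclass(x$config)),
    file.path(dir, "hit_report.json"), auto_unbox = TRUE, pretty = TRUE)
  utils::write.table(data.frame(sgrna_id = x$core_guides),
                     file.path(dir, "core_guides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(target_id = x$core_genes),
                     file.path(dir, "core_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sgrna_id = x$trend_guides),
                     file.path(dir, "trend_guides.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
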