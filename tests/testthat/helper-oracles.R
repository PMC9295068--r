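# Independent brute-force oracles, written from the definitions and kept
# deliberately naive; the package implementations are tested against them.

# median-of-ratios size factors, literal definition
oracle_size_factors <- function(m) {
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  keep <- is.finite(geo) & geo > 0
  sf <- sapply(seq_len(ncol(m)), function(s) {
    median(m[keep, s] / geo[keep])
  })
  sf / exp(mean(log(sf)))
}

# BH step-up, literal: q_(i) = min_{j>=i} p_(j) * n / j, input order restored
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- q
  out
}

# two-sample KS D: sup |ECDF_x - ECDF_y| evaluated at every data point
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(sapply(pts, function(t) mean(x <= t) - mean(y <= t))))
}

# Pearson correlation from the textbook covariance formula
oracle_pearson <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# literal threshold rule
oracle_threshold <- function(ids, counts, lfc, min_count, min_lfc) {
  out <- character(0)
  for (i in seq_along(ids)) {
    if (counts[i] > min_count && lfc[i] > min_lfc) out <- c(out, ids[i])
  }
  out
}

# literal all-way set intersection
oracle_intersection <- function(sets) {
  out <- sets[[1]]
  for (s in sets[-1]) out <- out[out %in% s]
  sort(unique(out))
}

# literal trend rule on a 3-column matrix (lenv, primary, metastasis)
oracle_trend <- function(ids, lenv, prim, met) {
  ids[met > prim & prim > lenv]
}

# brute-force read matching: compare the spacer window of each read with
# every library spacer at Hamming distance <= max_mm
oracle_match <- function(read, spacers, ids, offset, k, max_mm) {
  w <- substr(read, offset + 1, offset + k)
  if (nchar(w) < k) return(list(status = "unassigned", id = NA))
  hits <- character(0)
  for (i in seq_along(spacers)) {
    d <- sum(strsplit(w, "")[[1]] != strsplit(spacers[i], "")[[1]])
    if (d == 0) hits <- c(hits, ids[i])
  }
  if (length(hits) == 0 && max_mm >= 1) {
    for (i in seq_along(spacers)) {
      d <- sum(strsplit(w, "")[[1]] != strsplit(spacers[i], "")[[1]])
      if (d <= 1) hits <- c(hits, ids[i])
    }
  }
  hits <- unique(hits)
  if (length(hits) == 1) list(status = "assigned", id = hits)
  else if (length(hits) > 1) list(status = "ambiguous", id = NA)
  else list(status = "unassigned", id = NA)
}

# ---- fixture builders -------------------------------------------------

toy_library <- function(n_genes = 3, guides_per_gene = 2, n_ctrl = 2,
                        k = 20, seed = 11) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  ids <- c(paste0(rep(genes, each = guides_per_gene), "_sg",
                  rep(seq_len(guides_per_gene), n_genes)),
           if (n_ctrl > 0) paste0("ctrl_", seq_len(n_ctrl)))
  n <- length(ids)
  spacers <- character(0)
  while (length(spacers) < n) {
    spacers <- unique(c(spacers, paste(
      sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")))
  }
  sgrna_library(data.frame(
    sgrna_id = ids, spacer = spacers[seq_len(n)],
    target_id = c(rep(genes, each = guides_per_gene),
                  if (n_ctrl > 0) paste0("nt", seq_len(n_ctrl))),
    target_class = c(rep("gene", n_genes * guides_per_gene),
                     rep("non_targeting", n_ctrl)),
    stringsAsFactors = FALSE), spacer_length = k)
}

random_spacers_test <- function(n, k = 20) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, do.call(paste0, as.data.frame(
      matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), n, k)))))
  }
  out[seq_len(n)]
}

random_counts <- function(n_guides, samples, seed = 1, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_guides * length(samples), lambda), n_guides,
              dimnames = list(sprintf("sg%04d", seq_len(n_guides)), samples))
  m
}
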