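toy_stats <- function(ids, counts, lfc, p = NULL) {
  data.frame(sgrna_id = ids, treated_raw_count = counts, log2fc = lfc,
             p_value = if (is.null(p)) rep(0.5, length(ids)) else p,
             stringsAsFactors = FALSE)
}

test_that("threshold rule is strict on both count and fold change", {
  cfg <- hitcall_config()
  expect_equal(threshold_hits(toy_stats("a", 101, 3.01), cfg), "a")
  # count exactly 100 fails the strict '>' even at huge fold change
  expect_length(threshold_hits(toy_stats("a", 100, 5), cfg), 0L)
  # lfc exactly 3 fails
  expect_length(threshold_hits(toy_stats("a", 500, 3), cfg), 0L)

  # six-guide worked example, evaluated by hand: only guides 2 and 5 pass
  st <- toy_stats(paste0("sg", 1:6),
                  counts = c(50, 101, 250, 99, 500, 101),
                  lfc = c(4, 3.5, 2, 6, 3.01, 3.0))
  expect_equal(threshold_hits(st, cfg), c("sg2", "sg5"))
  expect_equal(threshold_hits(st, cfg),
               oracle_threshold(st$sgrna_id, st$treated_raw_count,
                                st$log2fc, 100, 3))
})

test_that("top-N ranking orders by fold change with p then id tie-breaks", {
  cfg <- hitcall_config()
  st <- toy_stats(paste0("sg", 1:5), counts = rep(200, 5),
                  lfc = c(5, 1, 4, 2, 3))
  expect_equal(top_n_guides(st, 2, cfg), c("sg1", "sg3"))
  expect_equal(top_n_guides(st, 5, cfg), paste0("sg", c(1, 3, 5, 4, 2)))

  tie <- toy_stats(c("b", "a"), counts = c(200, 200), lfc = c(4, 4),
                   p = c(0.01, 0.10))
  expect_equal(top_n_guides(tie, 1, cfg), "b")      # smaller p first
  tie2 <- toy_stats(c("b", "a"), counts = c(200, 200), lfc = c(4, 4),
                    p = c(0.05, 0.05))
  expect_equal(top_n_guides(tie2, 1, cfg), "a")     # then lexicographic id
  expect_warning(got <- top_n_guides(st, 10, cfg), "returning all")
  expect_length(got, 5L)
})

test_that("core intersection equals literal set evaluation", {
  lib <- toy_library(n_genes = 3, guides_per_gene = 1, n_ctrl = 0)
  ids <- lib$sgrna_id  # g1_sg1, g2_sg1, g3_sg1
  sets <- list(a = ids[1:3], b = ids[2:3], c = ids[3])
  core <- core_intersection(sets, lib)
  expect_equal(core$core_guides, ids[3])
  expect_equal(core$core_genes, "g3")
  expect_equal(core$core_guides, oracle_intersection(sets))

  disjoint <- core_intersection(list(a = ids[1], b = ids[2]), lib)
  expect_length(disjoint$core_guides, 0L)
  expect_length(disjoint$core_genes, 0L)

  set.seed(15)
  for (i in 1:10) {
    s <- lapply(1:3, function(j) sample(ids, sample(0:3, 1)))
    names(s) <- letters[1:3]
    expect_equal(core_intersection(s, lib)$core_guides,
                 oracle_intersection(s))
  }
})

test_that("shrinking any top-N can only shrink or preserve the core", {
  set.seed(16)
  lib <- toy_library(n_genes = 10, guides_per_gene = 2, n_ctrl = 0)
  ids <- lib$sgrna_id
  for (i in 1:10) {
    full <- lapply(1:3, function(j) sample(ids, 15))
    names(full) <- letters[1:3]
    shrunk <- full
    j <- sample(3, 1)
    shrunk[[j]] <- shrunk[[j]][1:10]  # ordered sets: shrinking = truncating
    big <- core_intersection(full, lib)$core_guides
    small <- core_intersection(shrunk, lib)$core_guides
    expect_true(all(small %in% big))
  }
})

test_that("trend group requires strict metastasis > primary > drug ordering", {
  m <- rbind(up = c(10L, 10L, 20L, 20L, 30L, 30L),
             down = c(30L, 30L, 20L, 20L, 10L, 10L),
             tie = c(10L, 10L, 10L, 10L, 30L, 30L))
  colnames(m) <- paste0("s", 1:6)
  meta <- data.frame(
    sample_id = paste0("s", 1:6),
    condition = rep(c("lenvatinib_cell", "primary_tumor", "lung_metastasis"),
                    each = 2),
    replicate = rep(c("R1", "R2"), 3))
  sc <- screen_counts(m, meta)
  # raw-count mode isolates the ordering rule itself
  cfg <- hitcall_config(use_normalized = FALSE)
  expect_equal(trend_group(sc, cfg), "up")
  expect_equal(trend_group(sc, cfg),
               oracle_trend(rownames(m), rowMeans(m[, 1:2]),
                            rowMeans(m[, 3:4]), rowMeans(m[, 5:6])))
  sub <- screen_counts(m[, 1:4], meta[1:4, ])
  expect_error(trend_group(sub, cfg), "lung_metastasis")
})

test_that("call_hits finds the genes enriched in every arm, not the partial ones", {
  # engineered screen: gene A enriches in all three drug arms, gene B in two
  res_all <- setNames(6, "gene0001")
  cfg <- sim_config(n_genes = 50, n_controls = 100,
                    resistance_genes = res_all, seq_depth = 500, seed = 23)
  sim <- simulate_screen(cfg)
  m <- sim$counts$counts
  # deplete gene0002 in the metastases so it only enriches in the first
  # two arms
  g2 <- sim$library$target_id == "gene0002"
  m[g2, grep("lung_metastasis", colnames(m))] <-
    m[g2, grep("control_cell", colnames(m))] %/% 50L
  m[g2, grep("lenvatinib_cell|primary_tumor", colnames(m))] <-
    m[g2, grep("lenvatinib_cell|primary_tumor", colnames(m))] * 40L
  sc <- screen_counts(m, sim$counts$sample_meta)
  fits <- list()
  for (tr in c("lenvatinib_cell", "primary_tumor", "lung_metastasis")) {
    fits[[tr]] <- screen_da(sc, tr, "control_cell")
  }
  hits <- call_hits(fits, sim$library, counts = sc,
                    cfg = hitcall_config(top_n = c(lenvatinib_cell = 30,
                                                   primary_tumor = 20,
                                                   lung_metastasis = 10)))
  expect_true("gene0001" %in% hits$core_genes)
  expect_false("gene0002" %in% hits$core_genes)
})
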