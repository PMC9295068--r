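two_group <- c("c", "c", "t", "t")

null_matrix <- function(n = 2000, seed = 1, alpha = 0.2, mu_log = log(300)) {
  set.seed(seed)
  mu <- rlnorm(n, mu_log, 1)
  m <- matrix(rnbinom(n * 4, mu = rep(mu, 4), size = 1 / alpha), n, 4)
  dimnames(m) <- list(sprintf("sg%04d", seq_len(n)), paste0("s", 1:4))
  m
}

test_that("size factors: symmetry, exact doubling, and brute-force agreement", {
  m <- random_counts(100, c("a", "b"), seed = 2)
  m[, "b"] <- m[, "a"]
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  m2 <- cbind(s1 = m[, "a"], s2 = 2L * m[, "a"])
  sf <- estimate_size_factors(m2)
  # geometric-mean-1 scaling forces (1/sqrt(2), sqrt(2))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  m3 <- random_counts(50, paste0("s", 1:4), seed = 3, lambda = 30)
  expect_equal(unname(estimate_size_factors(m3)), oracle_size_factors(m3),
               tolerance = 1e-9)

  zeros <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
                  dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(estimate_size_factors(zeros), "pseudo_reference")
  expect_length(estimate_size_factors(zeros, pseudo_reference = TRUE), 2L)
})

test_that("dispersion estimation recovers the generating regimes", {
  # Poisson counts: final alpha collapses toward zero
  set.seed(4)
  mu <- rlnorm(3000, log(500), 0.8)
  m <- matrix(rpois(3000 * 4, rep(mu, 4)), 3000, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  sf <- estimate_size_factors(m)
  disp <- estimate_dispersions(m, sf, two_group)
  expect_lt(median(disp$final), 0.01)

  # NB alpha = 0.2: median recovered within [0.1, 0.3]
  m2 <- null_matrix(n = 2000, seed = 5, alpha = 0.2)
  disp2 <- estimate_dispersions(m2, estimate_size_factors(m2), two_group)
  expect_gt(median(disp2$final), 0.1)
  expect_lt(median(disp2$final), 0.3)

  # constant counts: raw dispersion is exactly zero
  mc <- matrix(7L, 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  dispc <- estimate_dispersions(mc, rep(1, 4), two_group)
  expect_true(all(dispc$raw == 0))

  # no replication: trend-only fallback with a warning
  expect_warning(
    estimate_dispersions(m2[, c(1, 3)], rep(1, 2), c("c", "t")),
    "trend-only")
})

test_that("Wald test: null identity, closed-form fold change, flat null p", {
  # identical counts in both groups: lfc 0, p 1
  m <- matrix(rep(c(50L, 120L), each = 4), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  tab <- nb_wald_test(m, rep(1, 4), 0.1, two_group)
  expect_lt(max(abs(tab$log2fc)), 1e-8)
  expect_equal(tab$p_value, c(1, 1), tolerance = 1e-9)

  # control (100,100) vs treated (800,800): lfc = log2(800.5/100.5)
  m2 <- matrix(c(100L, 100L, 800L, 800L), 1, 4,
               dimnames = list("g1", paste0("s", 1:4)))
  tab2 <- nb_wald_test(m2, rep(1, 4), 0.05, two_group)
  expect_equal(tab2$log2fc, log2(800.5 / 100.5), tolerance = 1e-9)
  expect_equal(tab2$log2fc, 3, tolerance = 0.02)
  expect_equal(tab2$treated_raw_count, 800L)

  # all-zero guides are reported flat and flagged
  m3 <- rbind(g1 = c(5L, 6L, 7L, 8L), g0 = c(0L, 0L, 0L, 0L))
  colnames(m3) <- paste0("s", 1:4)
  tab3 <- nb_wald_test(m3, rep(1, 4), 0.1, two_group)
  expect_equal(tab3$p_value[2], 1)
  expect_equal(tab3$log2fc[2], 0)
  expect_true(tab3$all_zero[2])

  # null simulation: p-values indistinguishable from U(0,1)
  m4 <- null_matrix(seed = 6)
  sf <- estimate_size_factors(m4)
  disp <- estimate_dispersions(m4, sf, two_group)
  tab4 <- nb_wald_test(m4, sf, disp, two_group)
  D <- suppressWarnings(ks.test(tab4$p_value, "punif")$statistic)
  expect_lt(unname(D), 1.6276 / sqrt(nrow(m4)))  # alpha = 0.01 critical value
})

test_that("group-label swap negates log2fc and preserves p", {
  for (seed in 1:3) {
    m <- null_matrix(n = 300, seed = seed)
    sf <- estimate_size_factors(m)
    disp <- estimate_dispersions(m, sf, two_group)
    a <- nb_wald_test(m, sf, disp, two_group, treated_level = "t")
    b <- nb_wald_test(m, sf, disp, two_group, treated_level = "c")
    keep <- !a$all_zero
    expect_equal(a$log2fc[keep], -b$log2fc[keep], tolerance = 1e-6)
    expect_equal(a$p_value[keep], b$p_value[keep], tolerance = 1e-6)
  }
})

test_that("depth rescaling of one sample moves its size factor, not the fold changes", {
  m <- null_matrix(n = 400, seed = 9)
  sf1 <- estimate_size_factors(m)
  disp <- estimate_dispersions(m, sf1, two_group)
  t1 <- nb_wald_test(m, sf1, disp$final, two_group)
  m2 <- m
  m2[, 1] <- m2[, 1] * 3L
  sf2 <- estimate_size_factors(m2)
  expect_equal(unname(sf2[1] / sf1[1] / (sf2[2] / sf1[2])), 3,
               tolerance = 1e-9)
  t2 <- nb_wald_test(m2, sf2, disp$final, two_group)
  # pseudo-count-free group mean ratios are exactly invariant ...
  q1 <- sweep(m, 2, sf1, "/"); q2 <- sweep(m2, 2, sf2, "/")
  r1 <- rowMeans(q1[, 3:4]) / rowMeans(q1[, 1:2])
  r2 <- rowMeans(q2[, 3:4]) / rowMeans(q2[, 1:2])
  expect_equal(r1, r2, tolerance = 1e-9)
  # ... and the reported pseudo-counted log2fc moves only negligibly
  expect_equal(t1$log2fc, t2$log2fc, tolerance = 5e-3)
})

test_that("type-I error at nominal 0.05 stays in [0.03, 0.07]", {
  rates <- sapply(1:20, function(seed) {
    m <- null_matrix(seed = 400 + seed)
    sf <- estimate_size_factors(m)
    disp <- estimate_dispersions(m, sf, two_group)
    mean(nb_wald_test(m, sf, disp, two_group)$p_value < 0.05)
  })
  expect_gte(mean(rates), 0.03)
  expect_lte(mean(rates), 0.07)
})

test_that("screen_da agrees with DESeq2 on normalization and effect ranking", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  n <- 500
  mu <- rlnorm(n, log(200), 0.8)
  fc <- rep(1, n); fc[1:25] <- 6
  m <- cbind(matrix(rnbinom(n * 2, mu = rep(mu, 2), size = 8), n, 2),
             matrix(rnbinom(n * 2, mu = rep(mu * fc, 2), size = 8), n, 2))
  dimnames(m) <- list(sprintf("sg%03d", 1:n), paste0("s", 1:4))
  sf <- estimate_size_factors(m)

  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, data.frame(condition = factor(two_group, levels = c("c", "t"))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref_sf <- DESeq2::sizeFactors(dds)
  # identical median-of-ratios estimator up to the geometric-mean rescaling
  expect_equal(unname(sf / ref_sf) / mean(sf / ref_sf), rep(1, 4),
               tolerance = 1e-6)

  res <- DESeq2::results(dds)
  disp <- estimate_dispersions(m, sf, two_group)
  tab <- nb_wald_test(m, sf, disp, two_group)
  expect_gt(cor(tab$log2fc, res$log2FoldChange), 0.98)
  expect_gt(cor(rank(tab$p_value), rank(res$pvalue)), 0.9)
  # both tools flag essentially the same strong guides
  expect_gte(length(intersect(order(tab$p_value)[1:20],
                              order(res$pvalue)[1:20])), 16L)
})
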