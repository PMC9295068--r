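make_fastq <- function(reads, path = tempfile(fileext = ".fastq")) {
  con <- file(path, "wt")
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@r", i), reads[i], "+",
                 strrep("I", nchar(reads[i]))), con)
  }
  close(con)
  path
}

test_that("match_read resolves exact, 1-mismatch and tied spacers", {
  lib <- toy_library(n_genes = 3, guides_per_gene = 2, n_ctrl = 0)
  idx <- build_spacer_index(lib)
  sp <- lib$spacer[1]

  exact <- match_read(paste0(sp, "GTTTAA"), idx, quant_config())
  expect_equal(exact$status, "assigned")
  expect_equal(exact$id, lib$sgrna_id[1])

  mut <- sp
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(sp, 3, 3))[1]
  expect_equal(match_read(mut, idx, quant_config(max_mismatch = 0))$status,
               "unassigned")
  one <- match_read(mut, idx, quant_config(max_mismatch = 1))
  expect_equal(one$status, "assigned")
  expect_equal(one$id, lib$sgrna_id[1])

  # a spacer at Hamming distance 1 from two guides is ambiguous
  df <- as.data.frame(lib)
  df$spacer[2] <- mut  # now distance 1 from both spacer[1]-mutant positions
  substr(df$spacer[2], 7, 7) <- setdiff(c("A", "C", "G", "T"),
                                        substr(df$spacer[2], 7, 7))[1]
  lib2 <- sgrna_library(df)
  idx2 <- build_spacer_index(lib2)
  # read differing from spacer 1 at pos 3 and from spacer 2 at pos 7
  tie_read <- df$spacer[1]
  substr(tie_read, 3, 3) <- substr(mut, 3, 3)
  d1 <- mapply(function(a, b) sum(a != b),
               strsplit(tie_read, ""), strsplit(df$spacer[1], ""))
  d2 <- mapply(function(a, b) sum(a != b),
               strsplit(tie_read, ""), strsplit(df$spacer[2], ""))
  expect_equal(unname(c(d1, d2)), c(1, 1))
  expect_equal(match_read(tie_read, idx2,
                          quant_config(max_mismatch = 1))$status, "ambiguous")
})

test_that("quantify_sample bins every read exactly once", {
  lib <- toy_library(n_genes = 2, n_ctrl = 1)
  idx <- build_spacer_index(lib)
  reads <- c(paste0(lib$spacer[1], "GTTT"), paste0(lib$spacer[1], "ACGT"),
             strrep("A", 24))
  q <- quantify_sample(make_fastq(reads), idx, quant_config())
  expect_equal(unname(q$counts[lib$sgrna_id[1]]), 2L)
  expect_equal(unname(q$tally), c(2L, 1L, 0L))

  empty <- quantify_sample(make_fastq(character(0)), idx, quant_config())
  expect_true(all(empty$counts == 0L))
  expect_equal(sum(empty$tally), 0L)
})

test_that("read-count conservation holds on randomized reads", {
  lib <- toy_library(n_genes = 5, guides_per_gene = 3, n_ctrl = 5)
  idx <- build_spacer_index(lib)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(50:150, 1)
    reads <- vapply(seq_len(n), function(i) {
      if (runif(1) < 0.5) {
        sp <- sample(lib$spacer, 1)
        if (runif(1) < 0.3) {  # inject a substitution
          pos <- sample(20, 1)
          substr(sp, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
        }
        paste0(sp, strrep("G", 10))
      } else {
        paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
              collapse = "")
      }
    }, character(1))
    for (mm in 0:1) {
      q <- quantify_sample(reads, idx, quant_config(max_mismatch = mm))
      expect_identical(sum(q$tally), length(reads))
      expect_identical(sum(q$counts), unname(q$tally["assigned"]))
    }
  }
})

test_that("quantification agrees with the brute-force matcher", {
  lib <- toy_library(n_genes = 8, guides_per_gene = 3, n_ctrl = 6)
  idx <- build_spacer_index(lib)
  set.seed(42)
  reads <- vapply(1:120, function(i) {
    sp <- sample(lib$spacer, 1)
    if (runif(1) < 0.4) {
      pos <- sample(20, 1)
      substr(sp, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (runif(1) < 0.1) sp <- paste(
      sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    paste0(sp, "GTTTAAGAGC")
  }, character(1))
  for (mm in 0:1) {
    cfg <- quant_config(max_mismatch = mm)
    got <- quantify_sample(reads, idx, cfg)
    want <- integer(nrow(lib))
    names(want) <- lib$sgrna_id
    tally <- c(assigned = 0L, unassigned = 0L, ambiguous = 0L)
    for (r in reads) {
      res <- oracle_match(r, lib$spacer, lib$sgrna_id, 0, 20, mm)
      tally[res$status] <- tally[res$status] + 1L
      if (res$status == "assigned") want[res$id] <- want[res$id] + 1L
    }
    expect_identical(got$counts, want)
    expect_identical(got$tally, tally)
  }
})

test_that("simulator FASTQ with zero error rate is recovered exactly", {
  cfg <- sim_config(n_genes = 6, n_controls = 10, seed = 5)
  set.seed(5)
  lib <- sim_library(cfg)
  idx <- build_spacer_index(lib)
  truth <- setNames(rpois(nrow(lib), 15), lib$sgrna_id)
  fq <- tempfile(fileext = ".fastq")
  write_sim_fastq(truth, lib, fq, read_length = 40, spacer_offset = 4)
  q <- quantify_sample(fq, idx, quant_config(spacer_offset = 4))
  expect_identical(q$counts, truth + 0L)
  expect_equal(unname(q$tally[["assigned"]]), sum(truth))
})

test_that("malformed FASTQ records are reported by number", {
  path <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+"), path)
  lib <- toy_library()
  expect_error(quantify_sample(path, build_spacer_index(lib), quant_config()),
               "record|truncated")
})

test_that("count matrices assemble deterministically and round-trip as TSV", {
  lib <- toy_library(n_genes = 2, n_ctrl = 1)
  per <- list(s1 = setNames(c(3L, 0L, 5L, 1L, 2L), lib$sgrna_id),
              s2 = setNames(c(0L, 0L, 0L, 0L, 0L), lib$sgrna_id))
  meta <- data.frame(sample_id = c("s1", "s2"),
                     condition = c("control_cell", "lenvatinib_cell"),
                     replicate = c("R1", "R1"))
  sc <- assemble_count_matrix(per, meta)
  expect_equal(dim(sc$counts), c(5L, 2L))
  expect_true(all(sc$counts[, "s2"] == 0L))  # empty sample column retained

  cpath <- tempfile(fileext = ".tsv"); spath <- tempfile(fileext = ".tsv")
  write_counts(sc, cpath, spath)
  back <- read_counts(cpath, spath)
  expect_identical(back$counts, sc$counts)
  expect_identical(back$sample_meta$condition, sc$sample_meta$condition)

  # mismatched guide universe across samples is a hard error
  per_bad <- per
  names(per_bad$s2) <- paste0("x", names(per_bad$s2))
  expect_error(assemble_count_matrix(per_bad, meta), "different libraries")
})
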