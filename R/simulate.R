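#' Screen simulation configuration
#'
#' Parameterizes the synthetic pooled-screen generator. The default values
#' reproduce the design of a two-half genome-scale knockout screen for drug
#' resistance in liver-cancer cells: ~3 guides per gene plus 1000
#' non-targeting controls, infection at low MOI (~0.3) so most transduced
#' cells carry a single guide, >=400 cells per guide maintained through
#' passaging, three rounds of drug selection in vitro, then engraftment and
#' metastasis bottlenecks in vivo, sequenced to ~500 reads per guide with
#' negative-binomial overdispersion.
#'
#' Knockout fitness acts at the gene level: all guides of a gene share its
#' multiplier. Resistance genes have multiplier > 1 (their knockouts enrich
#' under drug); suppressor genes < 1; everything else is neutral (1).
#'
#' @param n_genes number of genes in the synthetic library.
#' @param guides_per_gene guides per gene (default 3).
#' @param n_controls non-targeting control guides (default 1000).
#' @param moi expected lentiviral integrations per cell (default 0.3).
#' @param coverage cells per guide at infection (default 400).
#' @param selection_rounds rounds of drug selection in vitro (default 3).
#' @param resistance_genes named numeric vector: gene id -> fitness
#'   multiplier under drug (> 1 enriches).
#' @param suppressor_genes named numeric vector: gene id -> multiplier < 1.
#' @param bottleneck_sizes named list/vector with elements `primary_tumor`
#'   and `lung_metastasis`: fraction of the incoming population surviving
#'   the engraftment and metastasis bottlenecks (defaults 0.2 and 0.02,
#'   severe enough to generate the mild between-sample heterogeneity of
#'   real in vivo arms without collapsing library representation).
#' @param in_vivo_rounds drug-selection rounds applied after each in vivo
#'   bottleneck (default 2).
#' @param seq_depth mean sequencing reads per guide (default 500).
#' @param nb_dispersion technical sequencing overdispersion alpha in
#'   \eqn{Var = \mu + \alpha\mu^2} (default 0.01, the extra-Poisson noise
#'   of PCR and resequencing; replicate-to-replicate biological divergence
#'   arises mechanistically from independent infection and selection).
#' @param error_rate per-base substitution probability when emitting FASTQ
#'   (default 0).
#' @param library_skew log-normal sigma of the initial per-guide plasmid
#'   abundance (default 0.5).
#' @param spacer_length spacer length in nt (default 20).
#' @param n_replicates independent infection replicates (default 2).
#' @param seed integer RNG seed; the whole simulation is a deterministic
#'   function of the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 19050L, guides_per_gene = 3L,
                       n_controls = 1000L, moi = 0.3, coverage = 400L,
                       selection_rounds = 3L,
                       resistance_genes = numeric(0),
                       suppressor_genes = numeric(0),
                       bottleneck_sizes = list(primary_tumor = 0.2,
                                               lung_metastasis = 0.02),
                       in_vivo_rounds = 2L,
                       seq_depth = 500, nb_dispersion = 0.01,
                       error_rate = 0, library_skew = 0.5,
                       spacer_length = 20L, n_replicates = 2L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              guides_per_gene = as.integer(guides_per_gene),
              n_controls = as.integer(n_controls),
              moi = moi, coverage = as.integer(coverage),
              selection_rounds = as.integer(selection_rounds),
              resistance_genes = resistance_genes,
              suppressor_genes = suppressor_genes,
              bottleneck_sizes = as.list(bottleneck_sizes),
              in_vivo_rounds = as.integer(in_vivo_rounds),
              seq_depth = seq_depth, nb_dispersion = nb_dispersion,
              error_rate = error_rate, library_skew = library_skew,
              spacer_length = as.integer(spacer_length),
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0L, guides_per_gene > 0L, n_controls >= 0L,
              moi > 0, coverage > 0L, selection_rounds >= 0L,
              seq_depth > 0, nb_dispersion >= 0, error_rate >= 0,
              error_rate < 1, library_skew >= 0, n_replicates >= 1L)
    if (length(resistance_genes) > 0L) stopifnot(all(resistance_genes > 0))
    if (length(suppressor_genes) > 0L) stopifnot(all(suppressor_genes > 0))
  })
  class(cfg) <- "sim_config"
  cfg
}

# Random unique ACGT spacers.
random_spacers <- function(n, k) {
  draw <- function(m) {
    do.call(paste0, as.data.frame(
      matrix(sample(c("A", "C", "G", "T"), m * k, replace = TRUE), m, k)))
  }
  out <- unique(draw(n))
  while (length(out) < n) out <- unique(c(out, draw(n - length(out))))
  out[seq_len(n)]
}

#' Build the synthetic guide library for a simulation
#'
#' @param cfg a [sim_config()].
#' @return An [sgrna_library()] with `n_genes * guides_per_gene` gene guides
#'   plus `n_controls` non-targeting controls, random unique spacers.
#' @export
sim_library <- function(cfg) {
  genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
  gene_ids <- as.vector(t(outer(genes, seq_len(cfg$guides_per_gene),
                                function(g, i) paste0(g, "_sg", i))))
  ctrl_ids <- if (cfg$n_controls > 0L) {
    sprintf("ctrl_%04d", seq_len(cfg$n_controls))
  } else character(0)
  n <- length(gene_ids) + length(ctrl_ids)
  sgrna_library(data.frame(
    sgrna_id = c(gene_ids, ctrl_ids),
    spacer = random_spacers(n, cfg$spacer_length),
    target_id = c(rep(genes, each = cfg$guides_per_gene),
                  if (cfg$n_controls > 0L)
                    sprintf("control_%04d", seq_len(cfg$n_controls))),
    target_class = c(rep("gene", length(gene_ids)),
                     rep("non_targeting", length(ctrl_ids))),
    stringsAsFactors = FALSE), spacer_length = cfg$spacer_length,
    name = "synthetic")
}

# Gene-level fitness multipliers expanded to per-guide vector.
guide_fitness <- function(lib, cfg) {
  fit <- rep(1, nrow(lib))
  names(fit) <- lib$sgrna_id
  for (g in names(cfg$resistance_genes)) {
    fit[lib$target_id == g] <- cfg$resistance_genes[[g]]
  }
  for (g in names(cfg$suppressor_genes)) {
    fit[lib$target_id == g] <- cfg$suppressor_genes[[g]]
  }
  fit[lib$target_class == "non_targeting"] <- 1
  fit
}

#' Simulate low-MOI lentiviral infection
#'
#' Each of `n_cells` cells receives a Poisson(`moi`) number of viral
#' integrations; uninfected cells are discarded by selection. Every
#' integration independently draws a guide from the initial (log-normal
#' skewed) plasmid abundance distribution and founds one knockout lineage,
#' so multiply-infected cells contribute one lineage per integration.
#'
#' @param cfg a [sim_config()].
#' @param initial_freq per-guide plasmid frequencies (default: log-normal
#'   with sigma `cfg$library_skew`, drawn here).
#' @param n_cells number of cells exposed to virus. The default,
#'   `coverage * n_guides / (1 - exp(-moi))`, exposes enough cells that the
#'   *infected* (selectable) population carries `coverage` lineages per
#'   guide, matching protocols that state coverage after transduction.
#' @return list with `population` (integer lineage count per guide),
#'   `initial_freq`, `n_cells`, `infected_fraction` and
#'   `single_integration_fraction` (share of infected cells with exactly
#'   one integration).
#' @export
simulate_infection <- function(cfg, initial_freq = NULL, n_cells = NULL) {
  n_guides <- cfg$n_genes * cfg$guides_per_gene + cfg$n_controls
  if (is.null(n_cells)) {
    n_cells <- ceiling(cfg$coverage * n_guides / (1 - exp(-cfg$moi)))
  }
  if (is.null(initial_freq)) {
    w <- stats::rlnorm(n_guides, meanlog = 0, sdlog = cfg$library_skew)
    initial_freq <- w / sum(w)
  }
  stopifnot(length(initial_freq) == n_guides)
  integrations <- stats::rpois(n_cells, cfg$moi)
  infected <- integrations > 0L
  n_int <- sum(integrations)
  population <- as.integer(stats::rmultinom(1L, n_int, initial_freq)[, 1L])
  list(population = population,
       initial_freq = initial_freq,
       n_cells = n_cells,
       infected_fraction = mean(infected),
       single_integration_fraction =
         if (any(infected)) mean(integrations[infected] == 1L) else NA_real_)
}

#' Apply rounds of selection to a guide population
#'
#' Each round multiplies the expected abundance of every guide lineage by
#' its gene's fitness multiplier, then multinomially resamples back to the
#' constant population size (cells are split/passaged at fixed density).
#' Guides of resistance genes therefore enrich geometrically: multiplier m
#' over r rounds gives an expected m^r relative enrichment.
#'
#' @param population integer lineage count per guide.
#' @param fitness per-guide fitness multiplier (>= 0), recycled if scalar.
#' @param rounds number of selection rounds.
#' @return integer population of the same total size.
#' @export
apply_selection <- function(population, fitness = 1, rounds = 1L) {
  stopifnot(length(population) >= 1L, all(population >= 0), rounds >= 0L)
  fitness <- rep_len(fitness, length(population))
  size <- sum(population)
  pop <- as.numeric(population)
  for (r in seq_len(rounds)) {
    expected <- pop * fitness
    if (sum(expected) <= 0) stop("selection drove the population extinct ",
                                 "(all expected abundances zero)")
    pop <- as.numeric(stats::rmultinom(1L, size, expected / sum(expected)))
  }
  as.integer(pop)
}

#' Apply a population bottleneck
#'
#' Samples `size_out` cells without replacement from the incoming
#' population (multivariate hypergeometric), modelling engraftment or
#' metastatic seeding. Guide richness can only decrease.
#'
#' @param population integer lineage count per guide.
#' @param size_out number of surviving cells; must be positive and at most
#'   the population total.
#' @return integer population summing to `size_out`.
#' @export
apply_bottleneck <- function(population, size_out) {
  total <- sum(population)
  size_out <- as.integer(round(size_out))
  if (size_out <= 0L) stop("size_out must be positive")
  if (size_out > total) stop("size_out exceeds population size")
  out <- integer(length(population))
  remaining <- total
  left <- size_out
  for (i in seq_along(population)) {
    if (left == 0L) break
    # draws from guide i when `left` balls are taken from `remaining`
    out[i] <- stats::rhyper(1L, population[i], remaining - population[i], left)
    left <- left - out[i]
    remaining <- remaining - population[i]
  }
  out
}

#' Simulate sequencing counts for a population
#'
#' Reads per guide follow a negative binomial with mean proportional to the
#' guide's frequency in the population times the target depth, and variance
#' \eqn{\mu + \alpha\mu^2}. `nb_dispersion = 0` gives the Poisson limit.
#'
#' @param population integer lineage count per guide.
#' @param seq_depth mean reads per guide.
#' @param nb_dispersion overdispersion alpha.
#' @return integer read count per guide.
#' @export
sequence_counts <- function(population, seq_depth, nb_dispersion = 0) {
  stopifnot(sum(population) > 0, seq_depth > 0, nb_dispersion >= 0)
  freq <- population / sum(population)
  mu <- freq * seq_depth * length(population)
  counts <- integer(length(mu))
  pos <- mu > 0
  counts[pos] <- if (nb_dispersion < 1e-12) {
    stats::rpois(sum(pos), mu[pos])
  } else {
    stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / nb_dispersion)
  }
  counts
}

#' Emit simulated FASTQ reads for a counted sample
#'
#' Writes one read per count: the guide spacer at `spacer_offset`, padded
#' with a constant vector-backbone context to `read_length`, with optional
#' uniform per-base substitution errors.
#'
#' @param counts integer read count per guide, named by sgrna_id.
#' @param lib the [sgrna_library()].
#' @param path output FASTQ path.
#' @param read_length total read length (default 50).
#' @param spacer_offset 0-based spacer position within the read (default 0).
#' @param error_rate per-base substitution probability.
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(counts, lib, path, read_length = 50L,
                            spacer_offset = 0L, error_rate = 0) {
  stopifnot(identical(names(counts), lib$sgrna_id))
  backbone <- paste(rep(c("G", "T", "T", "T", "A", "A", "G", "A", "G", "C"),
                        length.out = read_length + spacer_offset + 64L),
                    collapse = "")
  prefix <- substr(backbone, 1L, spacer_offset)
  k <- attr(lib, "spacer_length")
  suffix_len <- read_length - spacer_offset - k
  stopifnot(suffix_len >= 0L)
  suffix <- substr(backbone, 1L, suffix_len)
  reads <- rep(paste0(prefix, lib$spacer, suffix), counts)
  if (length(reads) > 0L && error_rate > 0) {
    mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE)),
                  nrow = length(reads), byrow = TRUE)
    hit <- which(matrix(stats::runif(length(mat)) < error_rate,
                        nrow = nrow(mat)))
    if (length(hit) > 0L) {
      mat[hit] <- vapply(mat[hit],
                         function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                            1L), character(1))
    }
    reads <- apply(mat, 1L, paste, collapse = "")
  }
  qual <- strrep("I", read_length)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(reads) > 0L) {
    writeLines(paste0("@read", seq_along(reads), "\n", reads, "\n+\n", qual),
               con, sep = "\n")
  }
  invisible(path)
}

#' Simulate a complete pooled resistance screen
#'
#' Runs the full generative model for `n_replicates` independent
#' infections. Each replicate follows the staged lineage
#' `control_cell -> lenvatinib_cell -> primary_tumor -> lung_metastasis`:
#' the infected pool is passaged without drug (control arm) and through
#' `selection_rounds` rounds of drug selection (drug arm); the drug-treated
#' pool passes the engraftment bottleneck and further in vivo selection
#' (primary tumor), and that tumor passes the metastasis bottleneck plus in
#' vivo selection again (lung metastasis). Every sample is then sequenced
#' with NB noise. Identical configurations (including seed) give identical
#' output.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `screen_sim`: list with `library` (the
#'   [sgrna_library()]), `counts` (a [screen_counts()], guides x
#'   (4 conditions x replicates)), and `truth` — a list with per-gene
#'   `fitness`, per-replicate `initial_freq` and per-stage `populations`,
#'   plus `abundance_ratio` (gene x condition matrix of true frequency
#'   ratios vs the control arm, averaged over replicates) and
#'   `enriched_genes` (genes with ratio > 2 per condition).
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  lib <- sim_library(cfg)
  fit <- guide_fitness(lib, cfg)
  stages <- c("control_cell", "lenvatinib_cell", "primary_tumor",
              "lung_metastasis")
  reps <- paste0("R", seq_len(cfg$n_replicates))
  samples <- as.vector(outer(stages, reps, paste, sep = "_"))
  counts <- matrix(0L, nrow(lib), length(samples),
                   dimnames = list(lib$sgrna_id, samples))
  # one plasmid pool: the library skew is shared by all infection replicates
  w <- stats::rlnorm(nrow(lib), meanlog = 0, sdlog = cfg$library_skew)
  plasmid_freq <- w / sum(w)
  populations <- list()
  initial_freq <- list()
  for (r in reps) {
    inf <- simulate_infection(cfg, initial_freq = plasmid_freq)
    initial_freq[[r]] <- inf$initial_freq
    pops <- list()
    # control arm: passaging without drug for the same number of splits
    pops$control_cell <- apply_selection(inf$population, 1,
                                         cfg$selection_rounds)
    pops$lenvatinib_cell <- apply_selection(inf$population, fit,
                                            cfg$selection_rounds)
    b1 <- max(1L, round(cfg$bottleneck_sizes$primary_tumor *
                          sum(pops$lenvatinib_cell)))
    pops$primary_tumor <- apply_selection(
      apply_bottleneck(pops$lenvatinib_cell, b1), fit, cfg$in_vivo_rounds)
    b2 <- max(1L, round(cfg$bottleneck_sizes$lung_metastasis *
                          sum(pops$primary_tumor)))
    pops$lung_metastasis <- apply_selection(
      apply_bottleneck(pops$primary_tumor, b2), fit, cfg$in_vivo_rounds)
    populations[[r]] <- pops
    for (st in stages) {
      counts[, paste(st, r, sep = "_")] <-
        sequence_counts(pops[[st]], cfg$seq_depth, cfg$nb_dispersion)
    }
  }
  meta <- data.frame(sample_id = samples,
                     condition = rep(stages, times = cfg$n_replicates),
                     replicate = rep(reps, each = length(stages)),
                     stringsAsFactors = FALSE)
  genes <- unique(lib$target_id[lib$target_class == "gene"])
  ratio <- sapply(setdiff(stages, "control_cell"), function(st) {
    num <- den <- numeric(length(genes))
    for (r in reps) {
      fs <- populations[[r]][[st]] / sum(populations[[r]][[st]])
      fc <- populations[[r]]$control_cell / sum(populations[[r]]$control_cell)
      num <- num + vapply(genes, function(g)
        sum(fs[lib$target_id == g]), numeric(1))
      den <- den + vapply(genes, function(g)
        sum(fc[lib$target_id == g]), numeric(1))
    }
    num / pmax(den, .Machine$double.xmin)
  })
  rownames(ratio) <- genes
  enriched <- apply(ratio, 2L, function(x) genes[x > 2], simplify = FALSE)
  gene_fit <- vapply(genes, function(g)
    fit[match(g, lib$target_id)], numeric(1))
  truth <- list(fitness = gene_fit, initial_freq = initial_freq,
                populations = populations, abundance_ratio = ratio,
                enriched_genes = enriched)
  structure(list(library = lib,
                 counts = screen_counts(counts, meta),
                 truth = truth,
                 config = cfg),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cfg <- x$config
  cat("simulated pooled screen: ", cfg$n_genes, " genes x ",
      cfg$guides_per_gene, " guides + ", cfg$n_controls,
      " controls, ", cfg$n_replicates, " replicates\n", sep = "")
  cat("  resistance genes: ",
      if (length(cfg$resistance_genes)) paste(names(cfg$resistance_genes),
                                              collapse = ", ") else "none",
      "\n", sep = "")
  print(x$counts)
  invisible(x)
}
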