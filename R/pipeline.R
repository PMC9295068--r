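#' Run the full screen-analysis pipeline
#'
#' Orchestrates simulate/load -> quantify -> QC -> per-comparison NB
#' differential abundance -> gene aggregation -> hit calling as one
#' seeded, logged, reproducible run. The run is a pure function of
#' (inputs, configuration, seed): rerunning with the same configuration
#' reproduces every output file byte for byte.
#'
#' The configuration is a named list (or path to a YAML file) with:
#' \describe{
#'   \item{seed}{integer RNG seed (default 1).}
#'   \item{out_dir}{output directory.}
#'   \item{simulate}{optional list of [sim_config()] arguments; when
#'     present the screen is simulated.}
#'   \item{library, counts, samples}{paths to a library TSV and a
#'     counts/sample-sheet TSV pair, for runs on existing data.}
#'   \item{fastq}{optional named list sample_id -> FASTQ path, plus
#'     `quant` (list of [quant_config()] arguments) and `samples` sheet,
#'     for quantification from reads.}
#'   \item{comparisons}{list of `c(treated, control)` pairs; default:
#'     each non-control condition vs `control_cell`.}
#'   \item{hitcall}{optional list of [hitcall_config()] arguments.}
#' }
#'
#' @param config named list or YAML file path.
#' @return An object of class `screen_run`: list with `counts`, `library`,
#'   `qc`, `fits`, `genes`, `hits`, `out_dir`, invisibly written under
#'   `out_dir/{qc,guides,genes,hits}`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  stopifnot(!is.null(out_dir))
  for (d in file.path(out_dir, c("qc", "guides", "genes", "hits"))) {
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  }
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  stamp <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", stage,
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
    log_lines <<- c(log_lines, line)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stamp(stage, paste("FAILED:", conditionMessage(e)))
      writeLines(c(log_lines, "run INCOMPLETE"), log_path)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stamp(stage, sprintf("done in %.2fs", proc.time()[["elapsed"]] - t0))
    out
  }

  set.seed(seed)
  stamp("config", paste("seed =", seed))

  # ---- inputs ----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- timed("simulate", {
      args <- config$simulate
      args$seed <- seed
      do.call(sim_config, args)
    })
    sim <- timed("simulate", simulate_screen(sim))
    lib <- sim$library
    counts <- sim$counts
    truth <- sim$truth
  } else if (!is.null(config$fastq)) {
    lib <- timed("library", read_sgrna_library(config$library))
    idx <- build_spacer_index(lib)
    qcfg <- do.call(quant_config, if (is.null(config$quant)) list() else
      config$quant)
    per_sample <- timed("quant", lapply(config$fastq, quantify_sample,
                                        index = idx, cfg = qcfg))
    meta <- utils::read.delim(config$samples, colClasses = "character")
    counts <- timed("quant",
                    assemble_count_matrix(lapply(per_sample, `[[`, "counts"),
                                          meta))
    truth <- NULL
  } else {
    lib <- timed("library", read_sgrna_library(config$library))
    counts <- timed("counts", read_counts(config$counts, config$samples))
    truth <- NULL
  }

  # ---- validate comparisons before any statistics ----------------------
  conditions <- unique(counts$sample_meta$condition)
  comparisons <- config$comparisons
  if (is.null(comparisons)) {
    control <- "control_cell"
    if (!control %in% conditions) {
      stop("no 'control_cell' condition and no explicit comparisons given")
    }
    comparisons <- lapply(setdiff(conditions, control),
                          function(tr) c(tr, control))
  }
  for (cmp in comparisons) {
    if (length(cmp) != 2L || !all(unlist(cmp) %in% conditions)) {
      stop("comparison references undeclared condition(s): ",
           paste(unlist(cmp), collapse = " vs "))
    }
  }

  # ---- QC --------------------------------------------------------------
  qc <- timed("qc", screen_qc(counts))
  jsonlite::write_json(
    list(pearson = qc$pearson, unique_sgrnas = as.list(qc$unique_sgrnas),
         count_summaries = qc$count_summaries, ks = qc$ks,
         size_factors = as.list(qc$size_factors)),
    file.path(out_dir, "qc", "qc_report.json"), digits = NA, pretty = TRUE)

  # ---- differential abundance + aggregation ----------------------------
  fits <- list()
  genes <- list()
  for (cmp in comparisons) {
    cmp <- unlist(cmp)
    nm <- cmp[1L]
    fits[[nm]] <- timed(paste0("diffabund:", nm),
                        screen_da(counts, treated = cmp[1L],
                                  control = cmp[2L]))
    utils::write.table(fits[[nm]]$table,
                       file.path(out_dir, "guides", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    genes[[nm]] <- timed(paste0("genes:", nm),
                         aggregate_genes(fits[[nm]], lib))
    utils::write.table(as.data.frame(genes[[nm]]),
                       file.path(out_dir, "genes", paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- hit calling -----------------------------------------------------
  hcfg <- do.call(hitcall_config, if (is.null(config$hitcall)) list() else
    config$hitcall)
  if (!all(names(fits) %in% names(hcfg$top_n))) {
    nn <- setdiff(names(fits), names(hcfg$top_n))
    extra <- stats::setNames(rep(min(hcfg$top_n), length(nn)), nn)
    hcfg$top_n <- c(hcfg$top_n, extra)
  }
  hits <- timed("hitcall", call_hits(fits, lib, counts = counts, cfg = hcfg))
  write_hit_report(hits, file.path(out_dir, "hits"))

  # ---- provenance ------------------------------------------------------
  resolved <- config
  resolved$seed <- seed
  resolved$package_version <-
    as.character(utils::packageVersion("poolscreen"))
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  stamp("run", "complete")
  writeLines(log_lines, log_path)

  structure(list(counts = counts, library = lib, qc = qc, fits = fits,
                 genes = genes, hits = hits, truth = truth,
                 out_dir = out_dir),
            class = "screen_run")
}

#' @export
print.screen_run <- function(x, ...) {
  cat("screen pipeline run ->", x$out_dir, "\n")
  print(x$counts)
  print(x$hits)
  invisible(x)
}
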