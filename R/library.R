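#' sgRNA library objects
#'
#' An `sgrna_library` holds the guide annotation universe of a pooled CRISPR
#' screen: one row per guide with its unique id, fixed-length nucleotide
#' spacer, target (gene symbol, miRNA id, or control label) and target class.
#' The design mirrors genome-scale knockout libraries distributed in two
#' halves with gene-targeting, miRNA-targeting and non-targeting guides.
#'
#' @param records data.frame with columns `sgrna_id`, `spacer`, `target_id`,
#'   `target_class`. `target_class` must be one of `"gene"`, `"miRNA"`,
#'   `"non_targeting"`. Spacers are case-folded to upper case.
#' @param spacer_length integer, declared spacer length in nt (default 20).
#' @param name character, library name.
#'
#' @return An object of class `sgrna_library`: the validated `records`
#'   data.frame with attributes `spacer_length` and `name`. Duplicate
#'   spacers are permitted but flagged (see [library_report()]); duplicate
#'   `sgrna_id`s are an error.
#' @export
sgrna_library <- function(records, spacer_length = 20L, name = "library") {
  stopifnot(is.data.frame(records))
  required <- c("sgrna_id", "spacer", "target_id", "target_class")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("library records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records[required], stringsAsFactors = FALSE)
  for (cn in required) records[[cn]] <- as.character(records[[cn]])
  records$spacer <- toupper(records$spacer)
  spacer_length <- as.integer(spacer_length)
  if (is.na(spacer_length) || spacer_length <= 0L) {
    stop("spacer_length must be a positive integer")
  }

  if (nrow(records) > 0L) {
    dup <- records$sgrna_id[duplicated(records$sgrna_id)]
    if (length(dup) > 0L) {
      stop("duplicate sgrna_id(s): ", paste(unique(dup), collapse = ", "))
    }
    bad_alpha <- grepl("[^ACGT]", records$spacer)
    if (any(bad_alpha)) {
      stop("non-ACGT spacer at row(s): ",
           paste(which(bad_alpha), collapse = ", "),
           " (id ", paste(records$sgrna_id[bad_alpha], collapse = ", "), ")")
    }
    bad_len <- nchar(records$spacer) != spacer_length
    if (any(bad_len)) {
      stop("spacer length != ", spacer_length, " at row(s): ",
           paste(which(bad_len), collapse = ", "))
    }
    bad_class <- !records$target_class %in% c("gene", "miRNA", "non_targeting")
    if (any(bad_class)) {
      stop("unknown target_class at row(s): ",
           paste(which(bad_class), collapse = ", "))
    }
  }
  rownames(records) <- NULL
  structure(records,
            spacer_length = spacer_length,
            name = name,
            class = c("sgrna_library", "data.frame"))
}

#' Read an sgRNA library annotation table
#'
#' Reads the strict 4-column tab-delimited dialect used throughout this
#' package: a header line `sgrna_id  spacer  target_id  target_class`
#' followed by one row per guide. Malformed rows are rejected with
#' row-numbered errors.
#'
#' @param path path to a tab-delimited annotation file.
#' @param spacer_length declared spacer length in nt (default 20).
#' @param name library name; defaults to the file base name.
#' @return An [sgrna_library()].
#' @export
read_sgrna_library <- function(path, spacer_length = 20L,
                               name = sub("\\.[^.]*$", "", basename(path))) {
  records <- utils::read.delim(path, header = TRUE, sep = "\t",
                               colClasses = "character",
                               stringsAsFactors = FALSE, quote = "",
                               comment.char = "")
  sgrna_library(records, spacer_length = spacer_length, name = name)
}

#' Write an sgRNA library annotation table
#'
#' @param lib an [sgrna_library()].
#' @param path output path; tab-delimited, header included.
#' @return `path`, invisibly.
#' @export
write_sgrna_library <- function(lib, path) {
  stopifnot(inherits(lib, "sgrna_library"))
  utils::write.table(as.data.frame(lib), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Merge two sgRNA libraries
#'
#' Concatenates two half-libraries (e.g. the A and B halves of a two-part
#' genome-scale design) into one. The guide id sets must be disjoint and the
#' declared spacer lengths equal.
#'
#' @param a,b [sgrna_library()] objects with equal `spacer_length`.
#' @param name name of the merged library.
#' @return An [sgrna_library()] with `nrow(a) + nrow(b)` records.
#' @export
merge_libraries <- function(a, b, name = paste(attr(a, "name"), attr(b, "name"),
                                               sep = "+")) {
  stopifnot(inherits(a, "sgrna_library"), inherits(b, "sgrna_library"))
  if (attr(a, "spacer_length") != attr(b, "spacer_length")) {
    stop("spacer_length differs between libraries (",
         attr(a, "spacer_length"), " vs ", attr(b, "spacer_length"), ")")
  }
  collisions <- intersect(a$sgrna_id, b$sgrna_id)
  if (length(collisions) > 0L) {
    stop("sgrna_id collision(s) between libraries: ",
         paste(utils::head(collisions, 20L), collapse = ", "),
         if (length(collisions) > 20L) ", ..." else "")
  }
  sgrna_library(rbind(as.data.frame(a), as.data.frame(b)),
                spacer_length = attr(a, "spacer_length"), name = name)
}

#' Build an exact spacer lookup index
#'
#' Maps every distinct spacer sequence to the set of guide ids carrying it.
#' Spacers shared by more than one guide are recorded as ambiguous; reads
#' matching them are discarded downstream, mirroring multi-mapping discard
#' behaviour of alignment-based quantification.
#'
#' @param lib an [sgrna_library()].
#' @return An object of class `spacer_index`: list with elements `map`
#'   (named list, spacer -> character vector of sgrna_ids), `ambiguous`
#'   (spacers mapping to >1 id) and `spacer_length`.
#' @export
build_spacer_index <- function(lib) {
  stopifnot(inherits(lib, "sgrna_library"))
  if (nrow(lib) == 0L) {
    map <- list()
  } else {
    map <- split(lib$sgrna_id, lib$spacer)
  }
  structure(list(map = map,
                 ambiguous = names(map)[lengths(map) > 1L],
                 ids = lib$sgrna_id,
                 spacer_length = attr(lib, "spacer_length")),
            class = "spacer_index")
}

#' Library validation report
#'
#' Summarizes a library for QC: record counts per target class, number of
#' distinct targets, and duplicate-spacer diagnostics. Duplicate spacers are
#' legal (real two-half libraries contain a few) but are surfaced here.
#'
#' @param lib an [sgrna_library()].
#' @param json_path optional path; when given the report is also written as
#'   JSON.
#' @return A list with elements `name`, `n_sgrnas`, `spacer_length`,
#'   `per_class` (named counts), `n_targets`, `n_duplicate_spacers`,
#'   `duplicate_spacers`.
#' @export
library_report <- function(lib, json_path = NULL) {
  stopifnot(inherits(lib, "sgrna_library"))
  classes <- c("gene", "miRNA", "non_targeting")
  per_class <- vapply(classes, function(cl) sum(lib$target_class == cl),
                      integer(1))
  dup_spacers <- unique(lib$spacer[duplicated(lib$spacer)])
  report <- list(
    name = attr(lib, "name"),
    n_sgrnas = nrow(lib),
    spacer_length = attr(lib, "spacer_length"),
    per_class = as.list(per_class),
    n_targets = length(unique(lib$target_id[lib$target_class != "non_targeting"])),
    n_duplicate_spacers = length(dup_spacers),
    duplicate_spacers = dup_spacers
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.sgrna_library <- function(x, ...) {
  rep <- library_report(x)
  cat("sgRNA library '", rep$name, "': ", rep$n_sgrnas, " guides (",
      rep$spacer_length, " nt spacers)\n", sep = "")
  cat("  gene-targeting: ", rep$per_class$gene,
      "; miRNA-targeting: ", rep$per_class$miRNA,
      "; non-targeting: ", rep$per_class$non_targeting, "\n", sep = "")
  cat("  distinct targets: ", rep$n_targets,
      "; duplicate spacers: ", rep$n_duplicate_spacers, "\n", sep = "")
  invisible(x)
}

#' @export
print.spacer_index <- function(x, ...) {
  cat("spacer index: ", length(x$map), " distinct ", x$spacer_length,
      "-nt spacers, ", length(x$ambiguous), " ambiguous\n", sep = "")
  invisible(x)
}
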