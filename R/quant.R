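#' Read-quantification configuration
#'
#' Controls how the guide spacer is located inside each sequencing read and
#' how strictly it is matched against the library. Quantification uses exact
#' hash lookup of the extracted spacer window, optionally retrying all
#' single-substitution neighbours (`max_mismatch = 1`). Amplicon designs
#' differ, so the spacer position is always an explicit input: either a
#' 0-based `spacer_offset`, or a constant 5' anchor sequence immediately
#' preceding the spacer (`anchor5`).
#'
#' @param spacer_offset 0-based position of the spacer within the read.
#'   Ignored when `anchor5` is given.
#' @param anchor5 optional constant 5' flank; the spacer is taken as the
#'   window immediately following its first exact occurrence in the read.
#' @param max_mismatch 0 or 1 substitutions tolerated.
#' @param min_read_length reads shorter than this are counted as unassigned.
#' @param reverse_complement also try the reverse complement of the
#'   extracted spacer (off by default; library-prep orientation is
#'   construct-specific).
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(spacer_offset = 0L, anchor5 = NULL,
                         max_mismatch = 0L, min_read_length = 20L,
                         reverse_complement = FALSE) {
  max_mismatch <- as.integer(max_mismatch)
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  spacer_offset <- as.integer(spacer_offset)
  if (is.na(spacer_offset) || spacer_offset < 0L) {
    stop("spacer_offset must be a non-negative 0-based position")
  }
  if (!is.null(anchor5)) {
    anchor5 <- toupper(as.character(anchor5))
    if (grepl("[^ACGT]", anchor5)) stop("anchor5 must be an ACGT string")
  }
  structure(list(spacer_offset = spacer_offset, anchor5 = anchor5,
                 max_mismatch = max_mismatch,
                 min_read_length = as.integer(min_read_length),
                 reverse_complement = isTRUE(reverse_complement)),
            class = "quant_config")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

# Extract the spacer window from each read (NA when the window does not fit).
extract_spacers <- function(reads, index, cfg) {
  k <- index$spacer_length
  if (is.null(cfg$anchor5)) {
    start <- cfg$spacer_offset + 1L
    out <- substr(reads, start, start + k - 1L)
    out[nchar(reads) < start + k - 1L] <- NA_character_
  } else {
    pos <- regexpr(cfg$anchor5, reads, fixed = TRUE)
    start <- ifelse(pos > 0L, pos + nchar(cfg$anchor5), NA_integer_)
    out <- ifelse(is.na(start) | nchar(reads) < start + k - 1L,
                  NA_character_, substr(reads, start, start + k - 1L))
  }
  out[nchar(reads) < cfg$min_read_length] <- NA_character_
  out
}

# All 3*k single-substitution neighbours of one spacer.
mismatch_neighbors <- function(spacer) {
  chars <- strsplit(spacer, "", fixed = TRUE)[[1]]
  k <- length(chars)
  out <- character(0)
  for (i in seq_len(k)) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[i])) {
      v <- chars
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# Resolve one extracted spacer against the index: list(status, id).
resolve_spacer <- function(spacer, index, cfg) {
  if (is.na(spacer) || grepl("[^ACGT]", spacer)) {
    return(list(status = "unassigned", id = NA_character_))
  }
  candidates <- spacer
  if (cfg$reverse_complement) candidates <- c(candidates, revcomp(spacer))
  hits <- unique(unlist(index$map[candidates], use.names = FALSE))
  if (length(hits) == 0L && cfg$max_mismatch == 1L) {
    nb <- unlist(lapply(candidates, mismatch_neighbors), use.names = FALSE)
    hits <- unique(unlist(index$map[nb], use.names = FALSE))
  }
  if (length(hits) == 1L) list(status = "assigned", id = hits)
  else if (length(hits) > 1L) list(status = "ambiguous", id = NA_character_)
  else list(status = "unassigned", id = NA_character_)
}

#' Match a single read against the spacer index
#'
#' Extracts the spacer window from `read` and resolves it by exact lookup,
#' falling back to single-substitution neighbour enumeration when
#' `max_mismatch = 1`. A unique hit assigns the read; hits to more than one
#' distinct guide (including spacers shared by several guides) are
#' ambiguous; no hit is unassigned.
#'
#' @param read a nucleotide string.
#' @param index a [build_spacer_index()] result.
#' @param cfg a [quant_config()].
#' @return list with `status` (`"assigned"`, `"unassigned"` or
#'   `"ambiguous"`) and `id` (the sgrna_id, or `NA`).
#' @export
match_read <- function(read, index, cfg = quant_config()) {
  stopifnot(is.character(read), length(read) == 1L)
  resolve_spacer(extract_spacers(toupper(read), index, cfg), index, cfg)
}

# Locate the first structurally malformed FASTQ record, for error messages.
scan_fastq_defect <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  n_rec <- n %/% 4L
  if (n %% 4L != 0L) {
    return(paste0("truncated record ", n_rec + 1L,
                  " (line count not a multiple of 4)"))
  }
  for (r in seq_len(n_rec)) {
    b <- (r - 1L) * 4L
    if (!startsWith(lines[b + 1L], "@")) {
      return(paste0("record ", r, ": header does not start with '@'"))
    }
    if (!startsWith(lines[b + 3L], "+")) {
      return(paste0("record ", r, ": separator does not start with '+'"))
    }
    if (nchar(lines[b + 2L]) != nchar(lines[b + 4L])) {
      return(paste0("record ", r, ": sequence and quality lengths differ"))
    }
  }
  NULL
}

read_fastq_sequences <- function(path) {
  defect <- scan_fastq_defect(path)
  if (!is.null(defect)) {
    stop("malformed FASTQ '", path, "': ", defect, call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop("malformed FASTQ '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  toupper(as.character(seqs))
}

#' Quantify one sample's FASTQ against a guide library
#'
#' Counts reads per guide by spacer matching. Every read ends in exactly one
#' of three bins, so `assigned + unassigned + ambiguous` always equals the
#' number of input reads, and the per-guide counts sum to `assigned`.
#' Ambiguous reads are discarded, not fractionally assigned.
#'
#' @param fastq path to a FASTQ file (gz-transparent), or a character vector
#'   of read sequences.
#' @param index a [build_spacer_index()] result.
#' @param cfg a [quant_config()].
#' @return list with `counts` (integer vector named by sgrna_id, in library
#'   order) and `tally` (named integer vector `assigned`, `unassigned`,
#'   `ambiguous`).
#' @export
quantify_sample <- function(fastq, index, cfg = quant_config()) {
  reads <- if (length(fastq) == 1L && file.exists(fastq)) {
    read_fastq_sequences(fastq)
  } else {
    toupper(as.character(fastq))
  }
  counts <- integer(length(index$ids))
  names(counts) <- index$ids
  tally <- c(assigned = 0L, unassigned = 0L, ambiguous = 0L)
  if (length(reads) == 0L) return(list(counts = counts, tally = tally))

  spacers <- extract_spacers(reads, index, cfg)
  # exact unique hits resolved vectorized; the rest go through the slow path
  keys <- names(index$map)
  pos <- match(spacers, keys)
  exact_unique <- !is.na(pos) & !(keys[ifelse(is.na(pos), 1L, pos)] %in%
                                    index$ambiguous)
  if (any(exact_unique)) {
    ids <- unlist(index$map[pos[exact_unique]], use.names = FALSE)
    tab <- table(ids)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    tally["assigned"] <- tally["assigned"] + sum(exact_unique)
  }
  rest <- which(!exact_unique)
  for (i in rest) {
    res <- resolve_spacer(spacers[i], index, cfg)
    tally[res$status] <- tally[res$status] + 1L
    if (res$status == "assigned") counts[res$id] <- counts[res$id] + 1L
  }
  stopifnot(sum(tally) == length(reads), sum(counts) == tally[["assigned"]])
  list(counts = counts, tally = tally)
}

#' Screen count matrix
#'
#' Container for the guides-by-samples integer count matrix plus per-sample
#' metadata. Canonical condition labels for the four screen arms are
#' `control_cell`, `lenvatinib_cell`, `primary_tumor`, `lung_metastasis`,
#' but arbitrary labels are accepted.
#'
#' @param counts integer matrix, guides in rows (rownames = sgrna_id),
#'   samples in columns (colnames = sample_id).
#' @param sample_meta data.frame with columns `sample_id`, `condition`,
#'   `replicate`; rows match columns of `counts`.
#' @return An object of class `screen_counts`: list with `counts` and
#'   `sample_meta`.
#' @export
screen_counts <- function(counts, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sgrna_id rownames and sample_id colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  stopifnot(is.data.frame(sample_meta),
            all(c("sample_id", "condition", "replicate") %in%
                  names(sample_meta)))
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (!identical(as.character(sample_meta$sample_id), colnames(counts))) {
    stop("sample_meta$sample_id must match counts columns in order")
  }
  rownames(sample_meta) <- NULL
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "screen_counts")
}

#' Assemble a count matrix from per-sample quantifications
#'
#' @param per_sample_counts named list of integer count vectors, one per
#'   sample, all named by the same library's sgrna_ids in the same order
#'   (as returned by [quantify_sample()]).
#' @param sample_meta data.frame with `sample_id`, `condition`, `replicate`;
#'   `sample_id` must match `names(per_sample_counts)`.
#' @return A [screen_counts()] object with deterministic row and column
#'   order (library order, sample sheet order).
#' @export
assemble_count_matrix <- function(per_sample_counts, sample_meta) {
  stopifnot(length(per_sample_counts) >= 1L)
  ids <- names(per_sample_counts[[1L]])
  for (v in per_sample_counts) {
    if (!identical(names(v), ids)) {
      stop("samples were quantified against different libraries ",
           "(guide id sets differ)")
    }
  }
  m <- do.call(cbind, per_sample_counts)
  rownames(m) <- ids
  colnames(m) <- names(per_sample_counts)
  sample_meta <- sample_meta[match(colnames(m), sample_meta$sample_id), ,
                             drop = FALSE]
  screen_counts(m, sample_meta)
}

#' Write / read a screen count matrix as TSV
#'
#' The count matrix is written as a TSV with an `sgrna_id` column followed
#' by one column per sample; the sample sheet as a 3-column TSV. Writing
#' then reading reproduces the object exactly.
#'
#' @param x a [screen_counts()] object.
#' @param counts_path,samples_path output/input paths.
#' @return `write_counts`: the paths, invisibly. `read_counts`: a
#'   [screen_counts()] object.
#' @export
write_counts <- function(x, counts_path, samples_path) {
  stopifnot(inherits(x, "screen_counts"))
  df <- data.frame(sgrna_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$sample_meta, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, samples_path))
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- utils::read.delim(counts_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$sgrna_id
  meta <- utils::read.delim(samples_path, header = TRUE, sep = "\t",
                            colClasses = "character",
                            stringsAsFactors = FALSE)
  screen_counts(m, meta)
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("screen counts: ", nrow(x$counts), " guides x ", ncol(x$counts),
      " samples\n", sep = "")
  tab <- table(x$sample_meta$condition)
  cat("  conditions: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  total reads per sample: ",
      paste(colnames(x$counts),
            formatC(colSums(x$counts), format = "d"), sep = ":",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
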