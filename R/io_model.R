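#' Barcode library construction
#'
#' A barcode library couples an aligned block of COI sequences with a
#' per-record metadata table. All sequences must have equal (aligned)
#' length and unique record ids.
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (upper- or lower-case; gaps as `-`, missing data as `N` or other IUPAC
#'   ambiguity codes). Names are the record ids.
#' @param metadata Data frame with at least columns `record_id` and
#'   `species_label`; optional columns `site_id`, `region`, `source` and any
#'   extra columns are preserved. Records absent from `metadata` get
#'   `species_label = "unknown"` with a warning.
#' @return An object of class `barcode_library`: a list with elements
#'   `sequences` (named uppercase character vector), `metadata` (data frame,
#'   one row per record, same order as `sequences`) and `alignment_length`.
#' @export
barcode_library <- function(sequences, metadata = NULL) {
  if (length(sequences) == 0L) stop("library must contain at least one sequence")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named by record id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (any(lens == 0L)) stop("empty sequence for record ", ids[which(lens == 0L)[1L]])
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must all have equal length; observed lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  }
  if (is.null(metadata)) {
    metadata <- data.frame(record_id = ids, species_label = "unknown",
                           stringsAsFactors = FALSE)
  }
  if (!all(c("record_id", "species_label") %in% names(metadata))) {
    stop("metadata must contain columns 'record_id' and 'species_label'")
  }
  if (anyDuplicated(metadata$record_id)) stop("duplicate record_id in metadata")
  missing <- setdiff(ids, metadata$record_id)
  if (length(missing)) {
    warning(length(missing), " record(s) absent from metadata; species_label set to 'unknown': ",
            paste(utils::head(missing, 5L), collapse = ", "))
    pad <- metadata[rep(NA_integer_, length(missing)), , drop = FALSE]
    pad$record_id <- missing
    pad$species_label <- "unknown"
    metadata <- rbind(metadata, pad)
  }
  metadata <- metadata[match(ids, metadata$record_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(sequences = sequences, metadata = metadata,
                 alignment_length = unname(lens[1L])),
            class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("barcode_library:", length(x$sequences), "records,",
      x$alignment_length, "aligned sites,",
      length(unique(x$metadata$species_label)), "species labels\n")
  invisible(x)
}

#' Number of records in a library
#' @param lib A `barcode_library`.
#' @return Integer count of records.
#' @export
n_records <- function(lib) length(lib$sequences)

#' Read a barcode library from FASTA and metadata TSV
#'
#' @param fasta_path Path to an aligned FASTA file.
#' @param metadata_path Optional path to a UTF-8 tab-separated table with a
#'   header row containing at least `record_id` and `species_label`.
#' @return A `barcode_library`.
#' @export
read_library <- function(fasta_path, metadata_path = NULL) {
  if (!file.exists(fasta_path)) stop("cannot read FASTA file: ", fasta_path)
  dna <- ape::read.FASTA(fasta_path)
  seqs <- toupper(vapply(as.character(dna), paste, collapse = "", ""))
  names(seqs) <- names(dna)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate FASTA id: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  meta <- NULL
  if (!is.null(metadata_path)) {
    if (!file.exists(metadata_path)) stop("cannot read metadata file: ", metadata_path)
    meta <- utils::read.delim(metadata_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, colClasses = "character",
                              fileEncoding = "UTF-8")
  }
  barcode_library(seqs, meta)
}

#' Write a barcode library to FASTA (and optionally metadata TSV)
#'
#' @param lib A `barcode_library`.
#' @param fasta_path Output FASTA path.
#' @param metadata_path Optional output TSV path.
#' @return Invisibly, `lib`.
#' @export
write_library <- function(lib, fasta_path, metadata_path = NULL) {
  con <- file(fasta_path, "w")
  on.exit(close(con))
  for (i in seq_along(lib$sequences)) {
    writeLines(c(paste0(">", names(lib$sequences)[i]), lib$sequences[i]), con)
  }
  if (!is.null(metadata_path)) {
    utils::write.table(lib$metadata, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(lib)
}

#' Ungapped length of each record
#' @param lib A `barcode_library`.
#' @return Named integer vector of sequence lengths excluding `-` characters.
#' @export
ungapped_lengths <- function(lib) {
  vapply(lib$sequences, function(s) nchar(gsub("-", "", s, fixed = TRUE)), 1L)
}

#' Filter records by ungapped sequence length
#'
#' Length is counted over non-gap characters, so libraries pooling amplicons
#' of unequal recovered length (e.g. 459-651 bp COI fragments padded in one
#' alignment) are filtered on what was actually sequenced.
#'
#' @param lib A `barcode_library`.
#' @param min_len Minimum ungapped length in bp (default 400).
#' @return List with `library` (filtered `barcode_library`, or `NULL` when no
#'   record passes) and `report` (a `qc_report`).
#' @export
length_filter <- function(lib, min_len = 400) {
  stopifnot(min_len >= 0)
  lens <- ungapped_lengths(lib)
  keep <- lens >= min_len
  report <- qc_report(
    n_input = n_records(lib),
    n_passed = sum(keep),
    flagged_ids = names(lens)[!keep],
    flagged_reason = rep("below_min_length", sum(!keep)),
    min_len = min(lens), max_len = max(lens), step = "length_filter"
  )
  out <- NULL
  if (any(keep)) {
    out <- barcode_library(lib$sequences[keep],
                           lib$metadata[keep, , drop = FALSE])
  } else {
    message("length_filter: no record passed min_len = ", min_len)
  }
  list(library = out, report = report)
}

qc_report <- function(n_input, n_passed, flagged_ids, flagged_reason,
                      min_len, max_len, step) {
  stopifnot(n_passed <= n_input, length(flagged_ids) == n_input - n_passed)
  structure(list(step = step, n_input = n_input, n_passed = n_passed,
                 n_flagged = n_input - n_passed, flagged_ids = flagged_ids,
                 flagged_reason = flagged_reason,
                 min_len = min_len, max_len = max_len),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report [%s]: %d input, %d passed, %d flagged (lengths %d-%d bp)\n",
              x$step, x$n_input, x$n_passed, x$n_flagged, x$min_len, x$max_len))
  invisible(x)
}

# Vertebrate mitochondrial stop codons; AGA/AGG code for stops rather than
# arginine under this code.
VERT_MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Screen sequences for mitochondrial stop codons
#'
#' Each record's ungapped sequence is scanned in the three forward reading
#' frames; a record passes if at least one frame contains no stop codon of
#' the vertebrate mitochondrial code (TAA, TAG, AGA, AGG). Codons containing
#' ambiguity characters never match a stop. A clean frame in a functional
#' COI fragment is expected; stops in every frame indicate a pseudogene
#' (NUMT) or sequencing error.
#'
#' @param lib A `barcode_library`.
#' @param stops Character vector of stop codons (default: vertebrate
#'   mitochondrial code).
#' @return A `qc_report`; `flagged_ids` lists records with a stop in all
#'   three frames or shorter than one codon.
#' @export
stop_codon_screen <- function(lib, stops = VERT_MITO_STOPS) {
  lens <- ungapped_lengths(lib)
  flagged <- character(0)
  reason <- character(0)
  for (i in seq_along(lib$sequences)) {
    s <- gsub("-", "", lib$sequences[i], fixed = TRUE)
    if (nchar(s) < 3L) {
      flagged <- c(flagged, names(lib$sequences)[i])
      reason <- c(reason, "shorter_than_one_codon")
      next
    }
    if (!any(vapply(0:2, function(off) frame_is_clean(s, off, stops), TRUE))) {
      flagged <- c(flagged, names(lib$sequences)[i])
      reason <- c(reason, "stop_codon_all_frames")
    }
  }
  qc_report(n_input = n_records(lib), n_passed = n_records(lib) - length(flagged),
            flagged_ids = flagged, flagged_reason = reason,
            min_len = min(lens), max_len = max(lens), step = "stop_codon_screen")
}

frame_is_clean <- function(seq, offset, stops) {
  n <- nchar(seq) - offset
  n_codons <- n %/% 3L
  if (n_codons < 1L) return(TRUE)
  starts <- offset + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  !any(codons %in% stops)
}

#' Collapse identical haplotypes
#'
#' Records with byte-identical aligned sequences (gaps and ambiguity codes
#' included) are collapsed to a single representative, the first in input
#' order. Typically applied before tree-based species delimitation, where
#' zero-length duplicate tips are uninformative or harmful.
#'
#' @param lib A `barcode_library`.
#' @return List with `library` (the pruned `barcode_library`) and `members`
#'   (named list mapping each representative's record id to the ids of all
#'   records sharing its haplotype — a partition of the input ids).
#' @export
collapse_haplotypes <- function(lib) {
  first <- !duplicated(lib$sequences)
  reps <- names(lib$sequences)[first]
  key <- match(lib$sequences, lib$sequences[first])
  members <- split(names(lib$sequences), factor(key, levels = seq_along(reps)))
  names(members) <- reps
  pruned <- barcode_library(lib$sequences[first], lib$metadata[first, , drop = FALSE])
  list(library = pruned, members = members)
}

#' Read and write trees in newick format
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] with a
#' syntax pre-check that reports the character offset of the first
#' unbalanced parenthesis or missing terminal semicolon.
#'
#' @param path File path.
#' @return `read_newick` returns an [ape::phylo] tree; `write_newick`
#'   invisibly returns `path`.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("cannot read newick file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  validate_newick(txt)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("malformed newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick: could not parse tree")
  tr
}

#' @param tree An [ape::phylo] tree.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

validate_newick <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed newick: unbalanced ')' at character ", i)
    }
  }
  if (depth > 0L) stop("malformed newick: ", depth,
                       " unclosed '(' by character ", length(chars))
  if (!grepl(";\\s*$", txt)) stop("malformed newick: missing terminal ';' at character ",
                                  length(chars))
  invisible(TRUE)
}
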