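# Reading, sanitizing and labelling protein sequences.
#
# Compositions downstream are defined over the 20 natural amino acids only,
# so sanitation deletes (rather than remaps) ambiguity codes (B, J, O, U, X,
# Z), gap characters and stop marks, and the sequence length L used by every
# descriptor is the post-filter length.

#' Construct a protein sequence record
#'
#' @param id Single non-empty identifier string.
#' @param residues Residue string. With `sanitize = TRUE` it is uppercased and
#'   stripped of non-standard characters first.
#' @param sanitize Sanitize `residues` on construction?
#' @return An object of class `protein_sequence` with fields `id` and
#'   `residues`; `length()` returns the residue count L.
#' @export
protein_sequence <- function(id, residues, sanitize = FALSE) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("'id' must be a single non-empty string")
  }
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    stop("'residues' must be a single string")
  }
  if (sanitize) residues <- sanitize_residues(residues)
  structure(list(id = id, residues = residues), class = "protein_sequence")
}

#' @export
length.protein_sequence <- function(x) nchar(x$residues)

#' @export
print.protein_sequence <- function(x, ...) {
  res <- x$residues
  if (nchar(res) > 60) res <- paste0(substr(res, 1, 57), "...")
  cat(sprintf("<protein_sequence> %s (%d aa)\n%s\n", x$id, nchar(x$residues), res))
  invisible(x)
}

#' Sanitize residues to the 20-letter amino acid alphabet
#'
#' Uppercases the input and removes every character outside [AA20]
#' (ambiguity codes, gaps, `*`, whitespace, digits).  Deletion, not remapping:
#' the length L that normalizes all compositions is recomputed on the filtered
#' string.
#'
#' @param raw Single raw residue string.
#' @return The filtered uppercase string.
#' @export
sanitize_residues <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("'raw' must be a single string")
  }
  if (!nzchar(raw)) stop("empty sequence")
  kept <- gsub(sprintf("[^%s]", paste(AA20, collapse = "")), "", toupper(raw))
  if (!nzchar(kept)) {
    stop("sequence empty after removing non-standard residues")
  }
  kept
}

#' Sanitize a sequence
#'
#' Generic wrapper around [sanitize_residues()]; idempotent.
#'
#' @param x A `protein_sequence` or a single residue string.
#' @return Object of the same type with sanitized residues.
#' @export
sanitize <- function(x) UseMethod("sanitize")

#' @export
sanitize.character <- function(x) sanitize_residues(x)

#' @export
sanitize.protein_sequence <- function(x) {
  x$residues <- sanitize_residues(x$residues)
  x
}

#' Read a FASTA file
#'
#' One record per `>` header, order preserved, ids taken as the first
#' whitespace-delimited token of the header.  Sequences are returned verbatim
#' (not sanitized) so that callers can decide how to treat non-standard
#' residues.
#'
#' @param path Path to a FASTA file.
#' @return List of [protein_sequence] records.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  n_headers <- sum(startsWith(readLines(path, warn = FALSE), ">"))
  if (n_headers == 0L) stop("no records in FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- as.character(set)
  lapply(seq_along(seqs), function(i) protein_sequence(ids[[i]], seqs[[i]]))
}

#' Write sequences to a FASTA file
#'
#' @param sequences List of [protein_sequence] records (may be empty, yielding
#'   a valid empty file).
#' @param path Output path.
#' @param width Residues per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  if (length(sequences) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  ids <- vapply(sequences, `[[`, character(1), "id")
  res <- vapply(sequences, `[[`, character(1), "residues")
  set <- Biostrings::BStringSet(stats::setNames(res, ids))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a labeled two-class dataset
#'
#' @param sequences List of [protein_sequence] records with unique ids.
#' @param labels Character/factor vector of `"T"`/`"NT"`, either aligned with
#'   `sequences` or named by sequence id.
#' @return `labeled_dataset` with fields `sequences`, `ids`, `labels`
#'   (factor with levels `NT`, `T`).
#' @export
labeled_dataset <- function(sequences, labels) {
  ids <- vapply(sequences, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  labels_chr <- as.character(labels)
  if (!is.null(names(labels))) {
    labels_chr <- as.character(labels)[match(ids, names(labels))]
  }
  if (length(labels_chr) != length(sequences) || anyNA(labels_chr)) {
    stop("labels must provide one T/NT value for every sequence id")
  }
  if (length(labels_chr) && !all(labels_chr %in% c("T", "NT"))) {
    stop("labels must be 'T' or 'NT'")
  }
  structure(list(sequences = sequences,
                 ids = ids,
                 labels = factor(labels_chr, levels = c("NT", "T"))),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$sequences)

#' Per-class record counts of a labeled dataset
#'
#' @param data A [labeled_dataset].
#' @return Named integer vector with entries `NT` and `T`.
#' @export
class_counts <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  tab <- table(data$labels)
  c(NT = unname(tab[["NT"]]), T = unname(tab[["T"]]))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cc <- if (length(x)) class_counts(x) else c(NT = 0L, T = 0L)
  cat(sprintf("<labeled_dataset> %d sequences (T: %d, NT: %d)\n",
              length(x), cc[["T"]], cc[["NT"]]))
  invisible(x)
}

#' Read a label table
#'
#' Two tab-delimited columns, `id<TAB>T|NT`.  A header line (`id  label`) and
#' `#` comment lines are tolerated and skipped.
#'
#' @param path Path to the table.
#' @return Named character vector of labels keyed by id.
#' @export
read_label_table <- function(path) {
  if (!file.exists(path)) stop("label table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) stop("label table line ", bad[1], ": expected 2 tab-delimited columns")
  mat <- do.call(rbind, fields)
  if (mat[1, 2] %in% c("label", "Label")) mat <- mat[-1, , drop = FALSE]
  if (nrow(mat) && !all(mat[, 2] %in% c("T", "NT"))) {
    stop("label table contains labels other than 'T'/'NT'")
  }
  stats::setNames(mat[, 2], mat[, 1])
}

#' Write a label table
#'
#' @param labels Named character vector (or factor) of `T`/`NT` keyed by id.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  lines <- c("id\tlabel",
             if (length(labels)) paste(names(labels), as.character(labels), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Load a labeled dataset from FASTA plus label table
#'
#' @param fasta_path FASTA file of protein sequences.
#' @param label_path Two-column label table (see [read_label_table()]).
#' @param sanitize Sanitize sequences after reading (default `TRUE`).
#' @return A [labeled_dataset].
#' @export
read_labeled_dataset <- function(fasta_path, label_path, sanitize = TRUE) {
  seqs <- read_fasta(fasta_path)
  if (sanitize) seqs <- lapply(seqs, sanitize.protein_sequence)
  labels <- read_label_table(label_path)
  labeled_dataset(seqs, labels)
}
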