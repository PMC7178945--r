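# psi-composition: averaging a composition descriptor over the query and the
# gap-free aligned regions of its (PSI-)BLAST homologs.
#
# Retrieval is an interface with two implementations: an external BLAST+
# subprocess (psiblast / blastp) and an in-memory stub fed by fixture tables
# in the same tabular dialect, so every unit test runs without a database.

# Tabular dialect shared with the homology-transfer module: the 12 standard
# columns plus the aligned query/subject strings used for region extraction.
HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "evalue", "bitscore",
                 "qstart", "qend", "sstart", "send", "qlen", "slen")
ALN_COLUMNS <- c(HIT_COLUMNS, "qseq", "sseq")

#' Homolog search configuration
#'
#' @param mode `"psi"` (iterated PSI-BLAST search, default) or `"blast"`
#'   (single-pass blastp).
#' @param db Path to a BLAST-formatted protein database (required for the
#'   external backend, ignored by stubs).
#' @param iterations PSI-BLAST iteration count, default 3 (psi mode only).
#' @param evalue E-value cutoff for retained hits, default 0.001.
#' @param backend `NULL` for the external BLAST+ subprocess, or a function
#'   `(query, config) -> data.frame` in the `ALN_COLUMNS` dialect (see
#'   [blast_backend_stub()]).
#' @param exclude_self Drop full-length 100\%-identity hits, emulating a
#'   reference database purged of the query itself.
#' @param executable Path of the external executable; defaults to `psiblast`
#'   or `blastp` found on the PATH.
#' @return List with class `search_config`.
#' @export
search_config <- function(mode = c("psi", "blast"), db = NULL, iterations = 3L,
                          evalue = 0.001, backend = NULL, exclude_self = FALSE,
                          executable = NULL) {
  mode <- match.arg(mode)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) stop("iterations must be >= 1")
  if (!is.numeric(evalue) || evalue <= 0) stop("e-value cutoff must be > 0")
  if (!is.null(backend) && !is.function(backend)) stop("backend must be NULL or a function")
  if (is.null(backend) && is.null(db)) stop("an external search needs a database path")
  structure(list(mode = mode, db = db, iterations = iterations, evalue = evalue,
                 backend = backend, exclude_self = exclude_self,
                 executable = executable),
            class = "search_config")
}

#' In-memory search backend from a fixture hit table
#'
#' Wraps a data frame (or a file readable by [read_alignment_table()]) in the
#' 14-column alignment dialect as a search backend: each call returns the rows
#' whose `qseqid` matches the query id.
#'
#' @param hits Data frame with `ALN_COLUMNS`, or a path to such a table.
#' @return A function usable as the `backend` of [search_config()].
#' @export
blast_backend_stub <- function(hits) {
  if (is.character(hits)) hits <- read_alignment_table(hits)
  if (!all(ALN_COLUMNS %in% names(hits))) {
    stop("stub hit table must contain columns: ", paste(ALN_COLUMNS, collapse = ", "))
  }
  force(hits)
  function(query, config) hits[hits$qseqid == query$id, , drop = FALSE]
}

#' Read a 14-column alignment table
#'
#' Tab-delimited `ALN_COLUMNS` dialect (the 12 standard BLAST tabular columns
#' plus `qseq`/`sseq`); `#` comment lines are skipped.
#'
#' @param path Path to the table.
#' @return Data frame with typed columns.
#' @export
read_alignment_table <- function(path) {
  parse_hit_lines(path, n_cols = 14L, col_names = ALN_COLUMNS)
}

# Shared line-level parser for the 12- and 14-column dialects.
parse_hit_lines <- function(path, n_cols, col_names) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  numeric_cols <- c("pident", "evalue", "bitscore")
  integer_cols <- c("length", "qstart", "qend", "sstart", "send", "qlen", "slen")
  if (!length(lines)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), n_cols), col_names))
    for (cn in intersect(numeric_cols, col_names)) df[[cn]] <- numeric(0)
    for (cn in intersect(integer_cols, col_names)) df[[cn]] <- integer(0)
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != n_cols)
  if (length(bad)) {
    stop("line ", lineno[bad[1]], ": expected ", n_cols,
         " tab-delimited columns, found ", lengths(fields)[bad[1]])
  }
  mat <- do.call(rbind, fields)
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(df) <- col_names
  for (cn in intersect(c(numeric_cols, integer_cols), col_names)) {
    val <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(val)) {
      stop("line ", lineno[which(is.na(val))[1]], ": non-numeric value in column '", cn, "'")
    }
    df[[cn]] <- if (cn %in% integer_cols) as.integer(round(val)) else val
  }
  bad_coord <- with(df, which(qstart > qend | sstart > send | qend > qlen | send > slen))
  if (length(bad_coord)) {
    stop("line ", lineno[bad_coord[1]], ": inconsistent alignment coordinates")
  }
  df
}

#' Construct a homolog set
#'
#' Holds a query and the gap-free aligned subject regions `h_1 ... h_n`
#' retained from a homology search. Regions are gap-stripped and sanitized on
#' construction; empty regions are dropped.
#'
#' @param query A sanitized [protein_sequence].
#' @param regions Character vector of aligned subject substrings (may contain
#'   `-` gap characters, which are stripped).
#' @param mode,iterations,evalue Provenance of the search.
#' @return Object of class `homolog_set` with fields `query`, `regions`, `n`,
#'   `provenance`.
#' @export
homolog_set <- function(query, regions = character(0), mode = "psi",
                        iterations = NA_integer_, evalue = NA_real_) {
  stopifnot(inherits(query, "protein_sequence"))
  regions <- vapply(regions, function(r) gsub("-", "", r, fixed = TRUE), character(1),
                    USE.NAMES = FALSE)
  nonempty <- nzchar(regions)
  if (!all(nonempty)) {
    warning(sum(!nonempty), " empty aligned region(s) dropped")
    regions <- regions[nonempty]
  }
  regions <- vapply(regions, sanitize_residues, character(1), USE.NAMES = FALSE)
  structure(list(query = query, regions = regions, n = length(regions),
                 provenance = list(mode = mode, iterations = iterations,
                                   evalue = evalue)),
            class = "homolog_set")
}

#' @export
print.homolog_set <- function(x, ...) {
  cat(sprintf("<homolog_set> query=%s n=%d mode=%s\n",
              x$query$id, x$n, x$provenance$mode))
  invisible(x)
}

#' Collect homologous aligned regions for a query
#'
#' Runs the configured search backend, keeps hits at or below the e-value
#' cutoff, retains one region per subject (its best-scoring HSP), strips
#' alignment gaps from the subject's aligned segment and sanitizes it.
#' Unaligned subject stretches never enter the set, and the query itself is
#' not among the regions (it enters the psi average separately).
#'
#' @param query A sanitized [protein_sequence].
#' @param config A [search_config()].
#' @return A [homolog_set].
#' @export
collect_homologs <- function(query, config) {
  stopifnot(inherits(query, "protein_sequence"), inherits(config, "search_config"))
  backend <- config$backend %||% blast_backend_system
  hits <- backend(query, config)
  if (!is.data.frame(hits) || !all(ALN_COLUMNS %in% names(hits))) {
    stop("search backend returned an unparseable hit table")
  }
  hits <- hits[hits$evalue <= config$evalue, , drop = FALSE]
  if (isTRUE(config$exclude_self)) {
    self <- hits$pident >= 100 & hits$qlen == hits$slen &
      (hits$qend - hits$qstart + 1L) == hits$qlen &
      (hits$send - hits$sstart + 1L) == hits$slen
    hits <- hits[!self, , drop = FALSE]
  }
  if (nrow(hits) > 1L) {
    hits <- hits[order(-hits$bitscore), , drop = FALSE]
    hits <- hits[!duplicated(hits$sseqid), , drop = FALSE]
  }
  homolog_set(query, regions = hits$sseq, mode = config$mode,
              iterations = if (config$mode == "psi") config$iterations else 1L,
              evalue = config$evalue)
}

# External BLAST+ backend: runs psiblast/blastp with tabular output including
# aligned sequence strings, keeping hits from the final PSI-BLAST iteration.
blast_backend_system <- function(query, config) {
  exe <- config$executable %||% if (config$mode == "psi") "psiblast" else "blastp"
  if (!nzchar(Sys.which(exe))) stop("external search tool not found on PATH: ", exe)
  qfile <- tempfile(fileext = ".fasta")
  on.exit(unlink(qfile), add = TRUE)
  write_fasta(list(query), qfile)
  outfmt <- paste("7", paste(ALN_COLUMNS, collapse = " "))
  args <- c("-query", qfile, "-db", config$db,
            "-evalue", format(config$evalue, scientific = TRUE),
            "-outfmt", shQuote(outfmt))
  if (config$mode == "psi") args <- c(args, "-num_iterations", config$iterations)
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    stop(exe, " failed with exit status ", status, ": ",
         paste(utils::tail(out, 5), collapse = " | "))
  }
  # outfmt 7 interleaves "# Iteration: k" comments; keep the final block.
  iter_marks <- grep("^# Iteration:", out)
  if (length(iter_marks)) out <- out[seq(from = iter_marks[length(iter_marks)], to = length(out))]
  tfile <- tempfile(fileext = ".tsv")
  on.exit(unlink(tfile), add = TRUE)
  writeLines(out, tfile)
  read_alignment_table(tfile)
}

#' psi-composition: average a descriptor over query and homolog regions
#'
#' Returns `(1 / (n + 1)) * sum of descriptor(P_x)` for `x` in the query and
#' the `n` homolog regions, with the same component length and ordering as
#' the plain descriptor. For PseAAC, regions no longer than `lambda` cannot
#' contribute (the correlation factors are undefined) and are skipped with a
#' warning, `n` counting only contributors; likewise single-residue regions
#' for PAAC.
#'
#' @param homologs A [homolog_set].
#' @param kind `"AAC"`, `"PAAC"` or `"PseAAC"`.
#' @param params [pseaac_params] when `kind = "PseAAC"`.
#' @return `composition_vector` with attribute `n_contributing`.
#' @export
psi_compose <- function(homologs, kind = c("AAC", "PAAC", "PseAAC"),
                        params = pseaac_params()) {
  stopifnot(inherits(homologs, "homolog_set"))
  kind <- match.arg(kind)
  min_len <- switch(kind, AAC = 1L, PAAC = 2L, PseAAC = params$lambda + 1L)
  regions <- homologs$regions
  usable <- nchar(regions) >= min_len
  if (any(!usable)) {
    warning(sum(!usable), " region(s) shorter than the ", kind,
            " minimum length (", min_len, ") skipped")
    regions <- regions[usable]
  }
  contributors <- c(homologs$query$residues, regions)
  vecs <- lapply(contributors, compute_descriptor, kind = kind, params = params)
  avg <- Reduce(`+`, lapply(vecs, unclass)) / length(vecs)
  out <- composition_vector(avg, kind)
  attr(out, "n_contributing") <- length(vecs) - 1L
  out
}

#' blast-composition: psi-composition over a single-pass BLAST search
#'
#' Identical contract to [psi_compose()], but the regions come from a
#' single-pass search (`mode = "blast"`) at the configured e-value cutoff;
#' the mode affects retrieval only.
#'
#' @param query A sanitized [protein_sequence].
#' @param config A [search_config()]; its mode is forced to `"blast"`.
#' @inheritParams psi_compose
#' @return `composition_vector`.
#' @export
blast_compose <- function(query, config, kind = c("AAC", "PAAC", "PseAAC"),
                          params = pseaac_params()) {
  config$mode <- "blast"
  psi_compose(collect_homologs(query, config), kind = kind, params = params)
}

#' Feature matrix of psi-compositions
#'
#' @param homolog_sets List of [homolog_set] objects (one per sequence).
#' @param kind Descriptor kind.
#' @param params [pseaac_params] for PseAAC.
#' @return Numeric matrix, rows named by query id.
#' @export
psi_feature_matrix <- function(homolog_sets, kind, params = pseaac_params()) {
  rows <- lapply(homolog_sets, psi_compose, kind = kind, params = params)
  mat <- do.call(rbind, lapply(rows, unclass))
  rownames(mat) <- vapply(homolog_sets, function(h) h$query$id, character(1))
  mat
}
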