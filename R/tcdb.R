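# Annotation transfer by homology: a query is called a transporter when a
# BLAST hit against a curated transporter classification database passes one
# of three threshold profiles (an exact match; a strict similarity rule with
# coverage and length conditions; a permissive e-value-only rule).

#' Parse a 12-column BLAST tabular file
#'
#' Tab-delimited, in the declared column order
#' `qseqid sseqid pident length evalue bitscore qstart qend sstart send qlen
#' slen` (BLAST `-outfmt 6` with explicit columns). `#` comment lines are
#' skipped; any other malformed line is an error naming its line number.
#'
#' @param path Path to the hit table.
#' @return Data frame of hits (classes `blast_hits`, `data.frame`), order
#'   preserved; zero rows for an empty file.
#' @export
parse_blast_tabular <- function(path) {
  df <- parse_hit_lines(path, n_cols = 12L, col_names = HIT_COLUMNS)
  class(df) <- c("blast_hits", "data.frame")
  df
}

#' Write a 12-column BLAST tabular file
#'
#' @param hits Data frame with `HIT_COLUMNS`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hits, path) {
  stopifnot(all(HIT_COLUMNS %in% names(hits)))
  utils::write.table(hits[, HIT_COLUMNS, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a homology threshold profile
#'
#' Any field may be left unset (`NULL`/`NA`); only set fields are tested by
#' [predict_by_homology()].
#'
#' @param name Profile name.
#' @param max_evalue Maximum e-value (0 means the tool reported exactly 0).
#' @param min_pident Minimum percent identity, in \[0, 100\].
#' @param min_query_coverage,min_subject_coverage Minimum fraction of the
#'   query/subject length spanned by the alignment coordinates, in \[0, 1\].
#' @param max_length_diff Maximum `|qlen - slen| / max(qlen, slen)`, in
#'   \[0, 1\].
#' @return Object of class `threshold_profile`.
#' @export
threshold_profile <- function(name, max_evalue = NA_real_, min_pident = NA_real_,
                              min_query_coverage = NA_real_,
                              min_subject_coverage = NA_real_,
                              max_length_diff = NA_real_) {
  num1 <- function(x) { x <- x %||% NA_real_; stopifnot(length(x) == 1L); as.numeric(x) }
  p <- list(name = name,
            max_evalue = num1(max_evalue),
            min_pident = num1(min_pident),
            min_query_coverage = num1(min_query_coverage),
            min_subject_coverage = num1(min_subject_coverage),
            max_length_diff = num1(max_length_diff))
  if (!is.na(p$max_evalue) && p$max_evalue < 0) stop("max_evalue must be >= 0")
  if (!is.na(p$min_pident) && (p$min_pident < 0 || p$min_pident > 100)) {
    stop("min_pident must be in [0, 100]")
  }
  for (f in c("min_query_coverage", "min_subject_coverage", "max_length_diff")) {
    if (!is.na(p[[f]]) && (p[[f]] < 0 || p[[f]] > 1)) stop(f, " must be in [0, 1]")
  }
  structure(p, class = "threshold_profile")
}

#' @export
print.threshold_profile <- function(x, ...) {
  set <- Filter(function(v) !is.na(v), x[-1])
  cat(sprintf("<threshold_profile> %s: %s\n", x$name,
              paste(names(set), unlist(set), sep = "=", collapse = ", ")))
  invisible(x)
}

#' The three built-in transporter-database threshold profiles
#'
#' * `TCDB_exact`: reported e-value exactly 0 and 100\% identity (an exact
#'   match).
#' * `TCDB_high`: e-value <= 1e-20, identity >= 40\%, query and subject
#'   coverage >= 70\%, length difference <= 10\%.
#' * `TCDB_med`: e-value <= 1e-8 only.
#'
#' @return Named list of three [threshold_profile] objects.
#' @export
builtin_profiles <- function() {
  list(
    TCDB_exact = threshold_profile("TCDB_exact", max_evalue = 0, min_pident = 100),
    TCDB_high = threshold_profile("TCDB_high", max_evalue = 1e-20, min_pident = 40,
                                  min_query_coverage = 0.70,
                                  min_subject_coverage = 0.70,
                                  max_length_diff = 0.10),
    TCDB_med = threshold_profile("TCDB_med", max_evalue = 1e-8)
  )
}

# Vectorized test of every set field of a profile against a hit table.
# Coverage is computed from the inclusive alignment coordinate spans, not
# gap-adjusted alignment lengths, so it is reproducible from the 12 standard
# tabular columns; length difference is normalized by the longer sequence.
hits_pass <- function(hits, profile) {
  ok <- rep(TRUE, nrow(hits))
  if (!is.na(profile$max_evalue)) ok <- ok & hits$evalue <= profile$max_evalue
  if (!is.na(profile$min_pident)) ok <- ok & hits$pident >= profile$min_pident
  if (!is.na(profile$min_query_coverage)) {
    ok <- ok & (hits$qend - hits$qstart + 1L) / hits$qlen >= profile$min_query_coverage
  }
  if (!is.na(profile$min_subject_coverage)) {
    ok <- ok & (hits$send - hits$sstart + 1L) / hits$slen >= profile$min_subject_coverage
  }
  if (!is.na(profile$max_length_diff)) {
    ok <- ok & abs(hits$qlen - hits$slen) / pmax(hits$qlen, hits$slen) <= profile$max_length_diff
  }
  ok
}

#' Rule-based transporter call from BLAST hits
#'
#' The query is labelled `T` iff any hit satisfies every set field of the
#' profile; otherwise `NT`. The first passing hit (input order) is recorded.
#'
#' @param hits `blast_hits` data frame, all rows sharing one `qseqid` (may be
#'   empty).
#' @param profile A [threshold_profile].
#' @param qseqid Query id used when `hits` is empty.
#' @return One-row data frame: `id`, `label` (`"T"`/`"NT"`), `source`
#'   (profile name), `hit` (passing subject id or `NA`).
#' @export
predict_by_homology <- function(hits, profile, qseqid = NULL) {
  stopifnot(inherits(profile, "threshold_profile"))
  qids <- unique(hits$qseqid)
  if (length(qids) > 1L) {
    stop("hits contain multiple query ids: ", paste(qids, collapse = ", "))
  }
  id <- if (length(qids) == 1L) qids else qseqid %||% NA_character_
  pass <- if (nrow(hits)) hits_pass(hits, profile) else logical(0)
  if (any(pass)) {
    data.frame(id = id, label = "T", source = profile$name,
               hit = hits$sseqid[which(pass)[1]], stringsAsFactors = FALSE)
  } else {
    data.frame(id = id, label = "NT", source = profile$name,
               hit = NA_character_, stringsAsFactors = FALSE)
  }
}

#' Homology calls for many queries under many profiles
#'
#' @param hits Hit table covering any number of query ids.
#' @param ids Query ids to report (queries without hits get `NT`).
#' @param profiles List of [threshold_profile] objects
#'   (default [builtin_profiles()]).
#' @return Data frame: `id` plus one `T`/`NT` column per profile.
#' @export
homology_predictions <- function(hits, ids, profiles = builtin_profiles()) {
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (pr in profiles) {
    out[[pr$name]] <- vapply(ids, function(qid) {
      predict_by_homology(hits[hits$qseqid == qid, , drop = FALSE], pr,
                          qseqid = qid)$label
    }, character(1), USE.NAMES = FALSE)
  }
  out
}
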