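# Seeded generators for every input the pipeline consumes: two-class
# sequence sets whose classes differ in residue composition, homolog sets at
# a target percent identity, and BLAST hit tables in the package's tabular
# dialects.  Each generator is a pure function of its configuration (seed
# included); realism is limited to what the consuming modules need.

#' Simulation configuration
#'
#' Defaults state the testing world used throughout the package: 200
#' sequences per class of 200-600 residues (uniform), the transporter class
#' enriched in hydrophobic residues and the non-transporter class in
#' charged/polar residues (a coarse caricature of membrane-spanning versus
#' soluble proteins), 5 homologs per query at 90\% identity.
#'
#' @param seed Master seed fixing every generated artifact.
#' @param n_per_class Sequences per class.
#' @param length_range Integer min/max sequence length (uniform draw).
#' @param bias_T,bias_NT Named positive multipliers applied to the uniform
#'   residue frequencies of each class (unnamed residues keep weight 1).
#' @param n_hits Homologs per query.
#' @param identity Target fractional identity of simulated homologs, in
#'   \[0, 1\].
#' @return List with class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_per_class = 200L,
                              length_range = c(200L, 600L),
                              bias_T = c(L = 2, I = 2, V = 2, F = 2, A = 1.5, M = 1.5),
                              bias_NT = c(D = 2, E = 2, K = 2, R = 2, N = 1.5,
                                          Q = 1.5, S = 1.5),
                              n_hits = 5L, identity = 0.9) {
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || any(is.na(length_range)) ||
      length_range[1] < 1L || length_range[1] > length_range[2]) {
    stop("degenerate length bounds")
  }
  for (b in list(bias_T, bias_NT)) {
    if (length(b) && (is.null(names(b)) || any(b <= 0) || !all(names(b) %in% AA20))) {
      stop("class biases must be positive multipliers named by residue")
    }
  }
  if (identity < 0 || identity > 1) stop("identity must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
                 length_range = length_range, bias_T = bias_T, bias_NT = bias_NT,
                 n_hits = as.integer(n_hits), identity = identity),
            class = "simulation_config")
}

residue_probs <- function(bias) {
  w <- stats::setNames(rep(1, 20), AA20)
  w[names(bias)] <- bias
  w / sum(w)
}

random_sequence <- function(L, probs) {
  paste(sample(AA20, L, replace = TRUE, prob = probs), collapse = "")
}

#' Simulate a two-class labeled dataset
#'
#' Class `T` sequences are drawn with the `bias_T` residue frequencies, class
#' `NT` with `bias_NT`; lengths are uniform over `length_range`. Ids are
#' `T0001...` / `NT0001...`. Deterministic under the config seed.
#'
#' @param config A [simulation_config()].
#' @return A [labeled_dataset] (empty when `n_per_class = 0`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_per_class
  with_seed(config$seed, {
    make_class <- function(label, probs) {
      lapply(seq_len(n), function(i) {
        L <- sample(seq(config$length_range[1], config$length_range[2]), 1L)
        protein_sequence(sprintf("%s%04d", label, i), random_sequence(L, probs))
      })
    }
    seqs_T <- make_class("T", residue_probs(config$bias_T))
    seqs_NT <- make_class("NT", residue_probs(config$bias_NT))
  })
  seqs <- c(seqs_T, seqs_NT)
  labeled_dataset(seqs, rep(c("T", "NT"), each = n))
}

#' Simulate a homolog set at a target identity
#'
#' Each region is the query mutated independently at each position with
#' probability `1 - identity`, substitutions drawn uniformly from the other
#' 19 residues.
#'
#' @param query A sanitized [protein_sequence].
#' @param n_hits Number of regions (>= 0).
#' @param identity Target fractional identity in \[0, 1\].
#' @param seed Seed.
#' @return A [homolog_set] with provenance `mode = "psi"`.
#' @export
simulate_homolog_set <- function(query, n_hits, identity, seed = 1L) {
  stopifnot(inherits(query, "protein_sequence"))
  n_hits <- as.integer(n_hits)
  if (is.na(n_hits) || n_hits < 0L) stop("n_hits must be >= 0")
  if (identity < 0 || identity > 1) stop("identity must be in [0, 1]")
  res <- strsplit(query$residues, "", fixed = TRUE)[[1]]
  regions <- with_seed(seed, {
    vapply(seq_len(n_hits), function(i) {
      mutated <- res
      flip <- stats::runif(length(res)) < (1 - identity)
      if (any(flip)) {
        mutated[flip] <- vapply(mutated[flip], function(r) {
          sample(setdiff(AA20, r), 1L)
        }, character(1))
      }
      paste(mutated, collapse = "")
    }, character(1))
  })
  homolog_set(query, regions, mode = "psi", iterations = 3L, evalue = 0.001)
}

#' Simulate an alignment fixture table for psi-composition
#'
#' One block of `n_hits` full-length, gap-free alignments per query, regions
#' generated by [simulate_homolog_set()]; the table is in the 14-column
#' `ALN_COLUMNS` dialect consumed by [blast_backend_stub()].
#'
#' @param data A [labeled_dataset] (or list of sequences).
#' @param n_hits Homologs per query.
#' @param identity Target fractional identity.
#' @param seed Master seed; each query uses a derived sub-seed.
#' @return Data frame in the alignment dialect.
#' @export
simulate_alignment_table <- function(data, n_hits, identity, seed = 1L) {
  sequences <- if (inherits(data, "labeled_dataset")) data$sequences else data
  if (!length(sequences) || n_hits == 0L) {
    return(parse_hit_lines(textConnection_path(character(0)), 14L, ALN_COLUMNS))
  }
  seeds <- derive_seeds(seed, length(sequences))
  blocks <- lapply(seq_along(sequences), function(i) {
    q <- sequences[[i]]
    hs <- simulate_homolog_set(q, n_hits, identity, seed = seeds[i])
    if (hs$n == 0L) return(NULL)
    L <- length(q)
    pid <- vapply(hs$regions, function(r) {
      100 * mean(strsplit(r, "")[[1]] == strsplit(q$residues, "")[[1]])
    }, numeric(1), USE.NAMES = FALSE)
    data.frame(qseqid = q$id,
               sseqid = sprintf("%s_hom%02d", q$id, seq_len(hs$n)),
               pident = round(pid, 2), length = L, evalue = 1e-50,
               bitscore = round(2 * L * pid / 100, 1),
               qstart = 1L, qend = L, sstart = 1L, send = L,
               qlen = L, slen = L, qseq = q$residues, sseq = hs$regions,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, blocks)
}

# Internal: materialize lines as a temp file path (used for empty tables).
textConnection_path <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

#' Simulate a transporter-database hit table
#'
#' In profile-aware mode, every `T`-labelled query receives one strong hit
#' (reported e-value 0, 100\% identity, full mutual coverage, equal lengths)
#' that passes all three built-in profiles, plus incidental mediocre hits;
#' every `NT`-labelled query receives only weak hits (e-value above 1e-3,
#' low identity, partial coverage) that fail all three. Rule predictions on
#' the table therefore reproduce the labels exactly. In non-aware mode all
#' queries draw from the weak/mediocre distributions.
#'
#' @param data A [labeled_dataset].
#' @param profile_aware Couple hits to labels (default `TRUE`).
#' @param seed Seed.
#' @return Data frame in the 12-column `HIT_COLUMNS` dialect.
#' @export
simulate_blast_hits <- function(data, profile_aware = TRUE, seed = 1L) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (!length(data)) {
    return(parse_blast_tabular(textConnection_path(character(0))))
  }
  qlens <- vapply(data$sequences, length, integer(1))
  labels <- as.character(data$labels)
  rows <- with_seed(seed, {
    lapply(seq_along(data$ids), function(i) {
      id <- data$ids[i]; L <- qlens[i]
      weak <- function(n, tag) {
        if (n == 0L) return(NULL)
        span <- pmin(L, pmax(20L, as.integer(stats::runif(n, 0.2, 0.5) * L)))
        slen <- as.integer(L * stats::runif(n, 1.3, 2.0))
        data.frame(qseqid = id, sseqid = sprintf("TCDB_%s_%s%02d", id, tag, seq_len(n)),
                   pident = round(stats::runif(n, 18, 32), 2), length = span,
                   evalue = 10 ^ stats::runif(n, -3, -1),
                   bitscore = round(stats::runif(n, 25, 60), 1),
                   qstart = 1L, qend = span, sstart = 1L, send = span,
                   qlen = L, slen = slen, stringsAsFactors = FALSE)
      }
      n_weak <- sample(0:3, 1L)
      if (profile_aware && labels[i] == "T") {
        strong <- data.frame(qseqid = id, sseqid = paste0("TCDB_", id, "_exact"),
                             pident = 100, length = L, evalue = 0,
                             bitscore = round(2.1 * L, 1), qstart = 1L, qend = L,
                             sstart = 1L, send = L, qlen = L, slen = L,
                             stringsAsFactors = FALSE)
        rbind(strong, weak(n_weak, "w"))
      } else {
        weak(n_weak + (profile_aware && labels[i] == "NT"), "w")
      }
    })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- parse_blast_tabular(textConnection_path(character(0)))
  class(out) <- c("blast_hits", "data.frame")
  out
}
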