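# Composition descriptors.
#
# AAC: the 20 residue fractions c_i = F_i / L.
# PAAC: the 400 overlapping-dipeptide fractions d_ij = F_ij / (L - 1),
#   row-major over the alphabetical residue order.
# PseAAC: Chou's pseudo amino acid composition; the 20 residue frequencies
#   are extended with lambda sequence-order correlation factors theta_j, each
#   the mean squared difference of standardized hydrophobicity, hydrophilicity
#   and side-chain mass between residues j positions apart, and the whole
#   vector is renormalized with weight omega on the theta tail so it sums to 1.

# Residue physicochemical property tables (alphabetical A..Y order).
# Hydrophobicity after Tanford (1962), hydrophilicity after Hopp & Woods
# (1981), side-chain masses from standard biochemistry tables; the same raw
# values are used by the canonical pseudo amino acid composition servers.
# Downstream code only ever sees the standardized (mean 0, population
# variance 1) versions, so the descriptor is invariant to affine changes of
# these raw scales.
.raw_properties <- list(
  hydrophobicity = c(
    A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
    G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
    M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
    S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26),
  hydrophilicity = c(
    A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
    G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
    M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
    S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
  side_chain_mass = c(
    A =  15.0, C =  47.0, D =  59.0, E =  73.0, F =  91.0,
    G =   1.0, H =  82.0, I =  57.0, K =  73.0, L =  57.0,
    M =  75.0, N =  58.0, P =  42.0, Q =  72.0, R = 101.0,
    S =  31.0, T =  45.0, V =  43.0, W = 130.0, Y = 107.0)
)

#' Standardize a 20-residue property table
#'
#' Centers by the 20-residue mean and divides by the population (divide by
#' 20) standard deviation, so the output has mean 0 and population variance 1.
#'
#' @param raw Numeric vector of 20 per-residue values, named by residue (any
#'   order) or given in alphabetical [AA20] order.
#' @return Standardized numeric vector in [AA20] order with attribute
#'   `standardized = TRUE`.
#' @export
standardize_property <- function(raw) {
  if (!is.numeric(raw) || length(raw) != 20L) {
    stop("a property table must hold exactly 20 numeric values")
  }
  if (!is.null(names(raw))) {
    if (!setequal(names(raw), AA20)) stop("property table names must be the 20 residues")
    raw <- raw[AA20]
  } else {
    names(raw) <- AA20
  }
  mu <- mean(raw)
  sd_pop <- sqrt(mean((raw - mu)^2))
  if (sd_pop <= .Machine$double.eps * max(1, abs(mu))) {
    stop("constant property table: zero variance, cannot standardize")
  }
  structure((raw - mu) / sd_pop, standardized = TRUE)
}

#' Built-in physicochemical property tables
#'
#' Returns the hydrophobicity (Tanford), hydrophilicity (Hopp-Woods) and
#' side-chain mass tables used by the PseAAC correlation function, either raw
#' or standardized via [standardize_property()].
#'
#' @param standardized Return standardized tables (default) or raw values.
#' @return Named list of three numeric vectors in [AA20] order.
#' @export
property_tables <- function(standardized = TRUE) {
  if (standardized) lapply(.raw_properties, standardize_property) else .raw_properties
}

# Internal: residue string of a protein_sequence or plain character input,
# validated against the 20-letter alphabet.
as_residue_string <- function(seq) {
  res <- if (inherits(seq, "protein_sequence")) seq$residues else {
    if (!is.character(seq) || length(seq) != 1L) stop("expected a protein_sequence or a residue string")
    seq
  }
  if (!nzchar(res)) stop("empty sequence")
  res
}

# Internal: residues as indices into AA20; errors on characters outside the
# alphabet (callers must sanitize first).
residue_index <- function(seq) {
  res <- as_residue_string(seq)
  idx <- match(strsplit(res, "", fixed = TRUE)[[1]], AA20)
  if (anyNA(idx)) {
    stop("sequence contains non-standard residues; run sanitize() first")
  }
  idx
}

composition_vector <- function(values, kind) {
  structure(values, kind = kind, class = c("composition_vector", "numeric"))
}

#' @export
print.composition_vector <- function(x, ...) {
  cat(sprintf("<composition_vector> kind=%s length=%d sum=%.6f\n",
              attr(x, "kind"), length(x), sum(x)))
  print(unclass(x)[seq_len(min(10L, length(x)))])
  if (length(x) > 10L) cat("...\n")
  invisible(x)
}

#' Amino acid composition (AAC)
#'
#' The fraction of each of the 20 natural amino acids, `c_i = F_i / L`.
#'
#' @param seq A [protein_sequence] or sanitized residue string.
#' @return `composition_vector` of length 20 (named `A`..`Y`), summing to 1.
#' @export
compute_aac <- function(seq) {
  idx <- residue_index(seq)
  counts <- tabulate(idx, nbins = 20L)
  composition_vector(stats::setNames(counts / length(idx), AA20), "AAC")
}

# Pair names in row-major alphabetical order: AA, AC, ..., YY.
paac_component_names <- function() {
  as.vector(t(outer(AA20, AA20, paste0)))
}

#' Pair (dipeptide) amino acid composition (PAAC)
#'
#' Fractions of the 400 overlapping adjacent residue pairs,
#' `d_ij = F_ij / (L - 1)`, ordered row-major by first then second residue.
#'
#' @inheritParams compute_aac
#' @return `composition_vector` of length 400, summing to 1 for L >= 2.
#' @export
compute_paac <- function(seq) {
  idx <- residue_index(seq)
  L <- length(idx)
  if (L < 2L) stop("dipeptide composition requires at least 2 residues")
  pair_code <- (idx[-L] - 1L) * 20L + idx[-1L]
  counts <- tabulate(pair_code, nbins = 400L)
  composition_vector(stats::setNames(counts / (L - 1), paac_component_names()), "PAAC")
}

#' PseAAC parameter set
#'
#' @param lambda Sequence-order depth (positive integer, default 30); must be
#'   smaller than the sequence length at descriptor time.
#' @param omega Weight of the sequence-order tail, default 0.05. The
#'   conventional user range is \[0.05, 0.7\]; values outside it (down to 0)
#'   are accepted with a warning so limiting behaviour can be studied.
#' @return List with class `pseaac_params`.
#' @export
pseaac_params <- function(lambda = 30L, omega = 0.05) {
  lambda <- as.integer(lambda)
  if (is.na(lambda) || lambda < 1L) stop("lambda must be a positive integer")
  if (!is.numeric(omega) || length(omega) != 1L || is.na(omega) || omega < 0) {
    stop("omega must be a single non-negative number")
  }
  if (omega < 0.05 || omega > 0.7) {
    warning("omega = ", omega, " is outside the conventional range [0.05, 0.7]")
  }
  structure(list(lambda = lambda, omega = omega), class = "pseaac_params")
}

#' Sequence-order correlation factors
#'
#' `theta_j` is the mean, over all residue pairs `j` positions apart, of the
#' correlation function `Theta(R_i, R_{i+j})` = mean of the squared
#' differences of the three standardized properties. All factors are >= 0.
#'
#' @inheritParams compute_aac
#' @param lambda Maximum positional lag; must satisfy `lambda < L`.
#' @param props List of three standardized property tables
#'   (default [property_tables()]).
#' @return Numeric vector `theta_1 ... theta_lambda`.
#' @export
theta_factors <- function(seq, lambda, props = property_tables()) {
  idx <- residue_index(seq)
  L <- length(idx)
  lambda <- as.integer(lambda)
  if (lambda < 1L) stop("lambda must be >= 1")
  if (lambda >= L) {
    stop("lambda (", lambda, ") must be smaller than the sequence length (", L, ")")
  }
  h1 <- props[[1]][idx]
  h2 <- props[[2]][idx]
  m  <- props[[3]][idx]
  vapply(seq_len(lambda), function(j) {
    a <- seq_len(L - j)
    b <- a + j
    mean(((h1[b] - h1[a])^2 + (h2[b] - h2[a])^2 + (m[b] - m[a])^2) / 3)
  }, numeric(1))
}

#' Pseudo amino acid composition (PseAAC)
#'
#' The 20 residue frequencies and the lambda correlation factors of
#' [theta_factors()], jointly normalized: component `i <= 20` is
#' `f_i / (1 + omega * sum(theta))` and component `20 + j` is
#' `omega * theta_j / (1 + omega * sum(theta))`, so the vector sums to 1.
#'
#' @inheritParams compute_aac
#' @param params A [pseaac_params] object (lambda, omega).
#' @param clamp When the sequence is too short (`L <= lambda`), error by
#'   default; with `clamp = TRUE` reduce lambda to `L - 1` with a warning.
#' @param props Standardized property tables, as in [theta_factors()].
#' @return `composition_vector` of length `20 + lambda`, components named
#'   `A`..`Y`, `theta1`..`theta<lambda>`.
#' @export
compute_pseaac <- function(seq, params = pseaac_params(), clamp = FALSE,
                           props = property_tables()) {
  idx <- residue_index(seq)
  L <- length(idx)
  lambda <- params$lambda
  if (lambda >= L) {
    if (!clamp) {
      stop("lambda (", lambda, ") must be smaller than the sequence length (",
           L, "); use clamp = TRUE to reduce it")
    }
    lambda <- L - 1L
    warning("lambda clamped to L - 1 = ", lambda, " for a short sequence")
  }
  f <- tabulate(idx, nbins = 20L) / L            # sums to 1
  theta <- theta_factors(seq, lambda, props)
  denom <- 1 + params$omega * sum(theta)
  values <- c(f, params$omega * theta) / denom
  names(values) <- c(AA20, paste0("theta", seq_len(lambda)))
  composition_vector(values, "PseAAC")
}

# Internal dispatcher used by the homolog-averaging and feature-matrix code.
compute_descriptor <- function(seq, kind, params = NULL, clamp = FALSE) {
  switch(kind,
    AAC = compute_aac(seq),
    PAAC = compute_paac(seq),
    PseAAC = compute_pseaac(seq, params %||% pseaac_params(), clamp = clamp),
    stop("unknown descriptor kind: ", kind)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Descriptor component names as serialized table headers
#'
#' @param kind One of `"AAC"`, `"PAAC"`, `"PseAAC"`.
#' @param lambda PseAAC depth (ignored otherwise).
#' @return Character vector like `AAC_A`, `PAAC_AC`, `PseAAC_theta1`.
#' @export
descriptor_colnames <- function(kind, lambda = 30L) {
  base <- switch(kind,
    AAC = AA20,
    PAAC = paac_component_names(),
    PseAAC = c(AA20, paste0("theta", seq_len(lambda))),
    stop("unknown descriptor kind: ", kind))
  paste(kind, base, sep = "_")
}

#' Write a descriptor table
#'
#' One row per sequence id, tab-delimited, header naming each component
#' (`<kind>_<component>`).
#'
#' @param mat Numeric matrix with row names = sequence ids and descriptor
#'   components as columns (as built by [descriptor_matrix()]).
#' @param kind Descriptor kind used to prefix column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(mat, kind, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  colnames(df) <- c("id", paste(kind, colnames(mat), sep = "_"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a feature matrix of plain descriptors
#'
#' @param sequences List of sanitized [protein_sequence] records.
#' @param kind `"AAC"`, `"PAAC"` or `"PseAAC"`.
#' @param params [pseaac_params] for PseAAC.
#' @return Numeric matrix, rows named by sequence id.
#' @export
descriptor_matrix <- function(sequences, kind, params = pseaac_params()) {
  rows <- lapply(sequences, compute_descriptor, kind = kind, params = params)
  mat <- do.call(rbind, lapply(rows, unclass))
  rownames(mat) <- vapply(sequences, `[[`, character(1), "id")
  mat
}
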