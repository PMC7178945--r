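# Independent straight-line oracles: deliberately naive loop implementations
# used to check the vectorized package code. They share nothing with the
# implementation paths they verify.

ALPHA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_aac <- function(res) {
  chars <- strsplit(res, "")[[1]]
  out <- stats::setNames(numeric(20), ALPHA)
  for (ch in chars) out[ch] <- out[ch] + 1
  out / length(chars)
}

oracle_paac <- function(res) {
  chars <- strsplit(res, "")[[1]]
  L <- length(chars)
  out <- numeric(400)
  names(out) <- as.vector(t(outer(ALPHA, ALPHA, paste0)))
  for (i in seq_len(L - 1)) {
    pair <- paste0(chars[i], chars[i + 1])
    out[pair] <- out[pair] + 1
  }
  out / (L - 1)
}

# Standardization straight from its definition (population sd).
oracle_standardize <- function(raw) {
  m <- sum(raw) / 20
  s <- sqrt(sum((raw - m)^2) / 20)
  (raw - m) / s
}

oracle_theta <- function(res, lambda, raw_props) {
  chars <- strsplit(res, "")[[1]]
  L <- length(chars)
  std <- lapply(raw_props, oracle_standardize)
  Theta <- function(a, b) {
    mean(c((std[[1]][b] - std[[1]][a])^2,
           (std[[2]][b] - std[[2]][a])^2,
           (std[[3]][b] - std[[3]][a])^2))
  }
  out <- numeric(lambda)
  for (j in seq_len(lambda)) {
    acc <- 0
    for (i in seq_len(L - j)) acc <- acc + Theta(chars[i], chars[i + j])
    out[j] <- acc / (L - j)
  }
  out
}

oracle_pseaac <- function(res, lambda, omega, raw_props) {
  chars <- strsplit(res, "")[[1]]
  L <- length(chars)
  f <- stats::setNames(numeric(20), ALPHA)
  for (ch in chars) f[ch] <- f[ch] + 1
  f <- f / L
  theta <- oracle_theta(res, lambda, raw_props)
  denom <- sum(f) + omega * sum(theta)
  c(f / denom, omega * theta / denom)
}

# Brute-force homology-rule filter: one hit at a time, one condition at a
# time, all five Table-style thresholds.
oracle_hit_passes <- function(hit, profile) {
  ok <- TRUE
  if (!is.na(profile$max_evalue) && !(hit$evalue <= profile$max_evalue)) ok <- FALSE
  if (!is.na(profile$min_pident) && !(hit$pident >= profile$min_pident)) ok <- FALSE
  if (!is.na(profile$min_query_coverage)) {
    if (!((hit$qend - hit$qstart + 1) / hit$qlen >= profile$min_query_coverage)) ok <- FALSE
  }
  if (!is.na(profile$min_subject_coverage)) {
    if (!((hit$send - hit$sstart + 1) / hit$slen >= profile$min_subject_coverage)) ok <- FALSE
  }
  if (!is.na(profile$max_length_diff)) {
    if (!(abs(hit$qlen - hit$slen) / max(hit$qlen, hit$slen) <= profile$max_length_diff)) ok <- FALSE
  }
  ok
}

oracle_homology_label <- function(hits, profile) {
  for (r in seq_len(nrow(hits))) {
    if (oracle_hit_passes(hits[r, ], profile)) return("T")
  }
  "NT"
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Strip class/kind attributes from a composition vector, keeping names.
plain <- function(v) stats::setNames(as.numeric(v), names(v))
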