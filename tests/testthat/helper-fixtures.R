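# Fixture builders used across test files. Everything is generated in code
# under a caller-supplied seed; no binary fixtures.

random_residues <- function(L, seed = NULL) {
  draw <- function() paste(sample(ALPHA, L, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else { set.seed(seed); draw() }
}

make_sequences <- function(n, L = 120L, seed = 1L, prefix = "seq") {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    protein_sequence(sprintf("%s%03d", prefix, i),
                     paste(sample(ALPHA, L, replace = TRUE), collapse = ""))
  })
}

# Random-but-valid 12-column hit tables for homology-rule tests. Includes
# exact matches (evalue 0, pident 100) with positive probability.
random_hit_table <- function(n, seed = 1L, qseqid = "q1") {
  set.seed(seed)
  qlen <- sample(100:1000, n, replace = TRUE)
  slen <- pmax(50L, as.integer(qlen * runif(n, 0.5, 1.8)))
  qstart <- sample.int(50, n, replace = TRUE)
  qend <- pmin(qlen, qstart + as.integer(runif(n, 0.3, 1.0) * qlen))
  sstart <- sample.int(50, n, replace = TRUE)
  send <- pmin(slen, sstart + as.integer(runif(n, 0.3, 1.0) * slen))
  exact <- runif(n) < 0.1
  data.frame(
    qseqid = qseqid,
    sseqid = sprintf("db%04d", seq_len(n)),
    pident = ifelse(exact, 100, round(runif(n, 10, 100), 2)),
    length = pmax(qend - qstart + 1L, send - sstart + 1L),
    evalue = ifelse(exact, 0, 10^runif(n, -40, 0)),
    bitscore = round(runif(n, 30, 2000), 1),
    qstart = qstart, qend = qend, sstart = sstart, send = send,
    qlen = qlen, slen = ifelse(exact, qlen, slen),
    stringsAsFactors = FALSE)
}

# Alignment-dialect table (14 columns) describing full-length gap-free hits
# whose sseq strings are supplied by the caller.
aln_table_row <- function(qseq_obj, sseqid, sseq, evalue = 1e-30, bitscore = 100,
                          sstart = 1L, send = NULL, slen = NULL) {
  L <- length(qseq_obj)
  n_res <- nchar(gsub("-", "", sseq))
  send <- send %||% (sstart + n_res - 1L)
  slen <- slen %||% send
  data.frame(qseqid = qseq_obj$id, sseqid = sseqid, pident = 90, length = nchar(sseq),
             evalue = evalue, bitscore = bitscore, qstart = 1L, qend = L,
             sstart = sstart, send = send, qlen = L, slen = slen,
             qseq = qseq_obj$residues, sseq = sseq, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# End-to-end fixture: a seeded two-class dataset plus fixture-backed homolog
# and hit providers, as produced by the synthetic module.
make_pipeline_fixture <- function(n_per_class, seed, n_hits = 3L, identity = 0.9,
                                  length_range = c(120L, 220L)) {
  sc <- simulation_config(seed = seed, n_per_class = n_per_class,
                          length_range = length_range, n_hits = n_hits,
                          identity = identity)
  data <- simulate_dataset(sc)
  aln <- simulate_alignment_table(data, n_hits, identity, seed = seed + 1L)
  hits <- simulate_blast_hits(data, profile_aware = TRUE, seed = seed + 2L)
  list(data = data,
       aln = aln,
       hits = hits,
       homolog_provider = homolog_provider_from_table(aln),
       hits_provider = hits_provider_from_table(hits))
}

small_stacking_config <- function(fx, seed = 1L) {
  stacking_config(homolog_provider = fx$homolog_provider,
                  hits_provider = fx$hits_provider,
                  svm_grid = list(C = c(1, 8), gamma = c(0.05, 0.5)),
                  svm_cv_k = 3L, meta_k = 5L,
                  gbm_trees = c(30L, 60L), gbm_depth = 1:2, seed = seed)
}
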