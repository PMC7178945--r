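stub_config <- function(aln, ...) {
  search_config(mode = "psi", backend = blast_backend_stub(aln), ...)
}

test_that("collect_homologs strips gaps and keeps alignment bookkeeping", {
  q <- protein_sequence("q1", random_residues(120, seed = 31))
  # aligned span of 41 columns holding 39 subject residues and 2 gaps
  span <- strsplit(random_residues(39, seed = 32), "")[[1]]
  sseq <- paste(append(span, c("-", "-"), after = 10), collapse = "")
  aln <- aln_table_row(q, "subj1", sseq, sstart = 10L)
  hs <- collect_homologs(q, stub_config(aln))
  expect_identical(hs$n, 1L)
  expect_identical(nchar(hs$regions), 39L)
  expect_false(grepl("-", hs$regions, fixed = TRUE))

  expect_identical(homolog_set(q, "AC-DE")$regions, "ACDE")
})

test_that("zero hits give an empty homolog set and psi reduces to plain", {
  q <- protein_sequence("q1", random_residues(90, seed = 33))
  empty <- aln_table_row(q, "x", "ACDE")[0, ]
  hs <- collect_homologs(q, stub_config(empty))
  expect_identical(hs$n, 0L)
  for (kind in c("AAC", "PAAC")) {
    expect_equal(plain(psi_compose(hs, kind)),
                 plain(compute_descriptor(q, kind)), tolerance = 1e-12)
  }
  expect_equal(plain(psi_compose(hs, "PseAAC", params = pseaac_params(5))),
               plain(compute_pseaac(q, pseaac_params(5))), tolerance = 1e-12)
})

test_that("psi_compose averages descriptor vectors over query and regions", {
  q <- protein_sequence("q1", "AAAA")
  hs <- homolog_set(q, "CCCC")
  v <- psi_compose(hs, "AAC")
  expect_equal(unname(v[c("A", "C")]), c(0.5, 0.5), ignore_attr = TRUE)

  # all regions identical to the query: mean of equal vectors
  hs2 <- homolog_set(q, c("AAAA", "AAAA"))
  expect_equal(plain(psi_compose(hs2, "AAC")), plain(compute_aac(q)))

  # two mocked regions with known compositions: mean of three vectors
  q3 <- protein_sequence("q3", "ACACAC")
  hs3 <- homolog_set(q3, c("DDDD", "EEEE"))
  manual <- (oracle_aac("ACACAC") + oracle_aac("DDDD") + oracle_aac("EEEE")) / 3
  expect_equal(plain(psi_compose(hs3, "AAC")), manual, tolerance = 1e-12)
})

test_that("psi_compose is order-invariant and a convex combination", {
  q <- protein_sequence("q1", random_residues(70, seed = 34))
  regions <- replicate(4, random_residues(70))
  a <- psi_compose(homolog_set(q, regions), "AAC")
  b <- psi_compose(homolog_set(q, rev(regions)), "AAC")
  expect_equal(unclass(a), unclass(b))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(sum(a), 1, tolerance = 1e-12)
})

test_that("retrieval keeps the best HSP per subject and honours the cutoff", {
  q <- protein_sequence("q1", random_residues(100, seed = 35))
  aln <- rbind(
    aln_table_row(q, "s1", random_residues(50, seed = 36), evalue = 1e-30, bitscore = 80),
    aln_table_row(q, "s1", random_residues(60, seed = 37), evalue = 1e-40, bitscore = 150),
    aln_table_row(q, "s2", random_residues(40, seed = 38), evalue = 0.5, bitscore = 20))
  hs <- collect_homologs(q, stub_config(aln))
  # s2 fails the 0.001 cutoff; s1 contributes only its higher-scoring HSP
  expect_identical(hs$n, 1L)
  expect_identical(nchar(hs$regions), 60L)
})

test_that("self-hit exclusion drops full-length exact matches", {
  q <- protein_sequence("q1", random_residues(80, seed = 39))
  self <- aln_table_row(q, "self", q$residues)
  self$pident <- 100
  other <- aln_table_row(q, "other", random_residues(80, seed = 40))
  aln <- rbind(self, other)
  expect_identical(collect_homologs(q, stub_config(aln))$n, 2L)
  expect_identical(collect_homologs(q, stub_config(aln, exclude_self = TRUE))$n, 1L)
})

test_that("regions shorter than the PseAAC depth are skipped with a warning", {
  q <- protein_sequence("q1", random_residues(50, seed = 41))
  hs <- homolog_set(q, c(random_residues(50), "ACD"))
  expect_warning(v <- psi_compose(hs, "PseAAC", params = pseaac_params(lambda = 10)),
                 "skipped")
  expect_identical(attr(v, "n_contributing"), 1L)
  expect_equal(sum(v), 1, tolerance = 1e-12)
})

test_that("stubbed retrieval and composition are deterministic; blast mode differs only in retrieval", {
  q <- protein_sequence("q1", random_residues(60, seed = 42))
  aln <- rbind(aln_table_row(q, "s1", random_residues(60, seed = 43)),
               aln_table_row(q, "s2", random_residues(60, seed = 44)))
  v1 <- psi_compose(collect_homologs(q, stub_config(aln)), "AAC")
  v2 <- psi_compose(collect_homologs(q, stub_config(aln)), "AAC")
  expect_identical(v1, v2)
  v3 <- blast_compose(q, stub_config(aln), "AAC")
  expect_equal(unclass(v1), unclass(v3))
})

test_that("alignment tables round-trip through the 14-column dialect", {
  q <- protein_sequence("q1", random_residues(40, seed = 45))
  aln <- rbind(aln_table_row(q, "s1", random_residues(40, seed = 46)),
               aln_table_row(q, "s2", random_residues(35, seed = 47)))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(aln, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back <- read_alignment_table(f)
  expect_equal(back$sseq, aln$sseq)
  expect_equal(back$evalue, aln$evalue)
})
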