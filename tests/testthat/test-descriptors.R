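raw_props <- property_tables(standardized = FALSE)

test_that("AAC matches counts on hand and random cases", {
  v <- compute_aac(protein_sequence("q", "AAAAA"))
  expect_equal(unname(v[["A"]]), 1)
  expect_equal(sum(v), 1)

  v <- compute_aac("ACAC")
  expect_equal(unname(v[c("A", "C")]), c(0.5, 0.5), ignore_attr = TRUE)

  set.seed(21)
  for (i in 1:10) {
    res <- random_residues(200)
    expect_equal(plain(compute_aac(res)), oracle_aac(res), tolerance = 1e-12)
  }
})

test_that("PAAC counts overlapping dipeptides over L - 1", {
  v <- compute_paac("AAA")
  expect_equal(unname(v[["AA"]]), 1)
  v <- compute_paac("ACA")
  expect_equal(unname(v[c("AC", "CA")]), c(0.5, 0.5), ignore_attr = TRUE)
  expect_error(compute_paac("A"), "at least 2")

  set.seed(22)
  res <- random_residues(300)
  expect_equal(plain(compute_paac(res)), oracle_paac(res), tolerance = 1e-12)
  expect_equal(sum(compute_paac(res)), 1, tolerance = 1e-12)
})

test_that("property standardization yields mean 0 / population variance 1", {
  for (tab in raw_props) {
    std <- standardize_property(tab)
    expect_lt(abs(mean(std)), 1e-9)
    expect_lt(abs(mean(std^2) - 1), 1e-9)
    # componentwise against the direct definition
    expect_equal(unname(plain(std)), unname(oracle_standardize(tab[AA20])),
                 tolerance = 1e-12)
  }
  expect_error(standardize_property(rep(3, 20)), "zero variance")
  expect_error(standardize_property(1:19), "exactly 20")
})

test_that("theta factors match the brute-force double loop", {
  expect_equal(theta_factors("AAAAAA", 3), rep(0, 3))

  # two-residue hand case: theta_1 is exactly Theta(A, C)
  std <- lapply(raw_props, oracle_standardize)
  th_ac <- mean(vapply(std, function(p) (p[["C"]] - p[["A"]])^2, numeric(1)))
  expect_equal(theta_factors("AC", 1), th_ac)

  set.seed(23)
  res <- random_residues(100)
  expect_equal(theta_factors(res, 5), oracle_theta(res, 5, raw_props),
               tolerance = 1e-12)
  expect_true(all(theta_factors(res, 10) >= 0))
  expect_error(theta_factors("ACDE", 4), "smaller than the sequence length")
})

test_that("PseAAC matches the straight-line oracle and normalizes to 1", {
  set.seed(24)
  res <- random_residues(80)
  got <- compute_pseaac(res, pseaac_params(lambda = 2, omega = 0.05))
  expect_equal(unname(plain(got)),
               unname(oracle_pseaac(res, 2, 0.05, raw_props)), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  expect_length(got, 22)

  # homopolymer: theta tail is zero, head equals the AAC
  hp <- compute_pseaac("GGGGGGGG", pseaac_params(lambda = 3))
  expect_equal(unname(hp[1:20]), unname(plain(compute_aac("GGGGGGGG"))),
               ignore_attr = TRUE)
  expect_equal(unname(hp[21:23]), rep(0, 3), ignore_attr = TRUE)
})

test_that("PseAAC handles short sequences per the clamp contract", {
  short <- protein_sequence("s", "ACDEF")
  expect_error(compute_pseaac(short, pseaac_params(lambda = 10)), "clamp")
  expect_warning(v <- compute_pseaac(short, pseaac_params(lambda = 10), clamp = TRUE),
                 "clamped")
  expect_length(v, 20 + 4)
})

test_that("omega -> 0 limit of PseAAC is the AAC with a zero tail", {
  set.seed(25)
  res <- random_residues(60)
  v <- suppressWarnings(compute_pseaac(res, pseaac_params(lambda = 4, omega = 1e-12)))
  expect_equal(unname(v[1:20]), unname(plain(compute_aac(res))),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(sum(v[21:24]), 1e-9)
  expect_warning(pseaac_params(omega = 0.9), "outside the conventional range")
})

test_that("AAC is permutation invariant; PAAC and theta are not", {
  set.seed(26)
  res <- random_residues(60)
  chars <- strsplit(res, "")[[1]]
  shuffled <- paste(sample(chars), collapse = "")
  expect_equal(plain(compute_aac(res)), plain(compute_aac(shuffled)))
  # a concrete counterexample for the order-sensitive descriptors
  expect_false(isTRUE(all.equal(plain(compute_paac("ACACAC")),
                                plain(compute_paac("AAACCC")))))
  expect_false(isTRUE(all.equal(theta_factors("ACACAC", 2),
                                theta_factors("AAACCC", 2))))
})

test_that("component ordering and serialized headers are stable", {
  expect_identical(names(compute_aac("ACDE")), AA20)
  expect_identical(names(compute_paac("ACDE"))[1:3], c("AA", "AC", "AD"))
  expect_identical(descriptor_colnames("PseAAC", lambda = 2)[21:22],
                   c("PseAAC_theta1", "PseAAC_theta2"))
  mat <- descriptor_matrix(make_sequences(3, L = 30, seed = 5), "AAC")
  f <- tempfile(fileext = ".tsv")
  write_descriptor_table(mat, "AAC", f)
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_identical(header, c("id", paste0("AAC_", AA20)))
})
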