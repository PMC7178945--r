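test_that("parse_blast_tabular handles well-formed, empty and malformed input", {
  line <- "q1\tdb1\t97.50\t200\t1e-50\t350.2\t1\t200\t5\t204\t210\t240"
  hits <- parse_blast_tabular(write_lines_tmp(line))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$sseqid, "db1")
  expect_equal(hits$pident, 97.5)
  expect_equal(hits$evalue, 1e-50)
  expect_identical(hits$send, 204L)

  empty <- parse_blast_tabular(write_lines_tmp(character(0)))
  expect_identical(nrow(empty), 0L)

  eleven <- paste(strsplit(line, "\t")[[1]][1:11], collapse = "\t")
  expect_error(parse_blast_tabular(write_lines_tmp(eleven)), "line 1.*12")
  bad_num <- sub("97.50", "high", line)
  expect_error(parse_blast_tabular(write_lines_tmp(bad_num)), "line 1.*pident")
})

test_that("builtin profiles encode the three published threshold sets", {
  p <- builtin_profiles()
  expect_named(p, c("TCDB_exact", "TCDB_high", "TCDB_med"))

  set_fields <- function(pr) {
    names(Filter(function(v) !is.na(v), unclass(pr)[-1]))
  }
  expect_identical(set_fields(p$TCDB_med), "max_evalue")
  expect_equal(p$TCDB_med$max_evalue, 1e-8)
  expect_length(set_fields(p$TCDB_high), 5)
  expect_equal(p$TCDB_high$max_evalue, 1e-20)
  expect_equal(p$TCDB_high$min_pident, 40)
  expect_equal(p$TCDB_high$min_query_coverage, 0.70)
  expect_equal(p$TCDB_high$min_subject_coverage, 0.70)
  expect_equal(p$TCDB_high$max_length_diff, 0.10)
  expect_identical(set_fields(p$TCDB_exact), c("max_evalue", "min_pident"))
  expect_equal(p$TCDB_exact$max_evalue, 0)
  expect_equal(p$TCDB_exact$min_pident, 100)
  # immutable constants
  expect_identical(builtin_profiles(), builtin_profiles())
})

test_that("predict_by_homology applies the rule semantics", {
  p <- builtin_profiles()
  exact_hit <- data.frame(qseqid = "q", sseqid = "s", pident = 100, length = 100,
                          evalue = 0, bitscore = 300, qstart = 1L, qend = 100L,
                          sstart = 1L, send = 100L, qlen = 100L, slen = 100L)
  expect_identical(predict_by_homology(exact_hit, p$TCDB_exact)$label, "T")

  med_hit <- function(e) transform(exact_hit, evalue = e)
  expect_identical(predict_by_homology(med_hit(1e-7), p$TCDB_med)$label, "NT")
  expect_identical(predict_by_homology(med_hit(1e-9), p$TCDB_med)$label, "T")

  none <- exact_hit[0, ]
  for (pr in p) {
    expect_identical(predict_by_homology(none, pr, qseqid = "q")$label, "NT")
  }

  mixed <- rbind(exact_hit, transform(exact_hit, qseqid = "q2"))
  expect_error(predict_by_homology(mixed, p$TCDB_med), "multiple query ids")
})

test_that("rule predictions agree with the brute-force filter on random hits", {
  p <- builtin_profiles()
  hits <- random_hit_table(50, seed = 61)
  for (pr in p) {
    for (i in seq_len(nrow(hits))) {
      expect_identical(
        predict_by_homology(hits[i, , drop = FALSE], pr)$label,
        oracle_homology_label(hits[i, , drop = FALSE], pr),
        info = sprintf("%s hit %d", pr$name, i))
    }
    expect_identical(predict_by_homology(hits, pr)$label,
                     oracle_homology_label(hits, pr))
  }
})

test_that("relaxing any threshold never flips T to NT; exact implies med", {
  p <- builtin_profiles()
  relaxed <- threshold_profile("relaxed", max_evalue = 1e-10, min_pident = 30,
                               min_query_coverage = 0.5, min_subject_coverage = 0.5,
                               max_length_diff = 0.3)
  for (s in 1:30) {
    hits <- random_hit_table(10, seed = 600 + s, qseqid = "q")
    strict_label <- predict_by_homology(hits, p$TCDB_high)$label
    if (strict_label == "T") {
      expect_identical(predict_by_homology(hits, relaxed)$label, "T")
    }
    if (predict_by_homology(hits, p$TCDB_exact)$label == "T") {
      expect_identical(predict_by_homology(hits, p$TCDB_med)$label, "T")
    }
  }
})

test_that("homology_predictions reports one column per profile per query", {
  hits <- rbind(random_hit_table(5, seed = 62, qseqid = "a"),
                random_hit_table(5, seed = 63, qseqid = "b"))
  preds <- homology_predictions(hits, ids = c("a", "b", "c"))
  expect_identical(names(preds), c("id", "TCDB_exact", "TCDB_high", "TCDB_med"))
  expect_identical(nrow(preds), 3L)
  expect_identical(preds$TCDB_med[preds$id == "c"], "NT")
})
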