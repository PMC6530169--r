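test_that("smith_waterman handles identity and all-mismatch cases", {
  r <- smith_waterman("alba", "alba")
  expect_identical(r$score, 8L)
  expect_identical(r$query_span, c(0L, 4L))
  expect_identical(r$record_span, c(0L, 4L))
  expect_identical(r$aligned_pairs, 4L)

  z <- smith_waterman("aaa", "ttt")
  expect_identical(z$score, 0L)
  expect_identical(z$query_span, c(0L, 0L))
  expect_identical(z$record_span, c(0L, 0L))

  expect_error(smith_waterman("", "abc"), "empty")
  # case folding
  expect_identical(smith_waterman("ALBA", "alba")$score, 8L)
})

test_that("smith_waterman equals the brute-force oracle on random pairs", {
  set.seed(101)
  for (i in 1:300) {
    a <- random_string(4, 30)
    b <- random_string(4, 30)
    expect_identical(smith_waterman(a, b)$score, oracle_sw_score(a, b),
                     label = paste("pair", a, "/", b))
  }
  # non-default parameters too
  p <- align_params(match = 3, mismatch = -2, gap = -2)
  for (i in 1:50) {
    a <- random_string(4, 20); b <- random_string(4, 20)
    expect_identical(smith_waterman(a, b, p)$score,
                     oracle_sw_score(a, b, 3L, -2L, -2L))
  }
})

test_that("record_coverage is the record-span fraction", {
  aln <- smith_waterman("quercus alba", "quercus alba")
  expect_equal(record_coverage(aln, "quercus alba"), 1.0)
  fake <- structure(list(score = 20L, query_span = c(0L, 10L),
                         record_span = c(0L, 10L), aligned_pairs = 10L),
                    class = "alignment_result")
  expect_equal(record_coverage(fake, "abcdefghijkl"), 10 / 12)
  z <- smith_waterman("aaa", "ttt")
  expect_equal(record_coverage(z, "ttt"), 0)
})

test_that("initials_constraint compares genus and epithet initials", {
  expect_true(initials_constraint("quercus albaa", "quercus alba"))
  expect_false(initials_constraint("uercus alba", "quercus alba"))
  expect_false(initials_constraint("quercus", "quercus alba"))
  expect_true(initials_constraint("q alba extra", "quercus alba"))
  expect_false(initials_constraint("quercus rlba", "quercus alba"))
})

test_that("resolve_name matches exact hits with full coverage", {
  tab <- tiny_table()
  idx <- build_index(tab)
  r <- resolve_name(idx, tab, "Quercus alba")
  expect_identical(r$decision, "match")
  expect_identical(r$matched_name, "quercus alba")
  expect_equal(r$coverage, 1.0)
  expect_identical(r$alignment$score, 2L * nchar("quercus alba"))
  expect_true(all(r$constraints_passed))
})

test_that("resolve_name picks the constrained nearest neighbor", {
  tab <- tiny_table()
  idx <- build_index(tab)
  r <- resolve_name(idx, tab, "Quercus albaa")
  expect_identical(r$decision, "match")
  expect_identical(r$matched_id, "ub1")
  # exhaustive check: ub1 is the nearest record passing both constraints
  d <- vapply(tab$records$canonical_name, oracle_osa, integer(1),
              a = "quercus albaa")
  expect_identical(unname(tab$records$record_id[which.min(d)]), "ub1")

  # genus absent from the dictionary -> no record passes initials
  r2 <- resolve_name(idx, tab, "Fagus grandifolia")
  expect_identical(r2$decision, "no_match")
  expect_null(r2$matched_id)
  ok <- vapply(tab$records$canonical_name, function(nm) {
    aln <- smith_waterman("fagus grandifolia", nm)
    record_coverage(aln, nm) > 0.8 && initials_constraint("fagus grandifolia", nm)
  }, logical(1))
  expect_false(any(ok))
})

test_that("synonyms resolve to themselves with the accepted id attached", {
  tab <- tiny_table()
  idx <- build_index(tab)
  r <- resolve_name(idx, tab, "Poa annua")
  expect_identical(r$matched_id, "ub3")
  expect_identical(r$accepted_id, "ub1")
  expect_identical(r$accepted_name, "quercus alba")
})

test_that("every match satisfies both constraints (soundness property)", {
  tab <- generate_taxonomy(60, 8, 0.15, seed = 13)
  idx <- build_index(tab)
  bench <- make_benchmark(tab, 80, typo_model(1), distractor_fraction = 0.1,
                          seed = 14)
  for (i in seq_len(nrow(bench$items))) {
    r <- resolve_name(idx, tab, bench$items$query[i])
    if (r$decision == "match") {
      expect_true(r$coverage > 0.8)
      expect_true(initials_constraint(r$normalized_query, r$matched_name))
      expect_true(all(r$constraints_passed))
    } else {
      expect_null(r$matched_id)
      expect_null(r$accepted_id)
    }
  }
})

test_that("exact-hit dominance holds on a synthetic dictionary", {
  tab <- generate_taxonomy(30, 5, seed = 23)
  idx <- build_index(tab)
  set.seed(24)
  for (i in sample(nrow(tab$records), 15)) {
    nm <- tab$records$canonical_name[i]
    r <- resolve_name(idx, tab, nm)
    expect_identical(r$decision, "match")
    expect_identical(r$matched_name, nm)
    expect_equal(r$coverage, 1.0)
    expect_identical(r$alignment$score, 2L * nchar(nm))
  }
})

test_that("resolve_names returns the tabular interface and writes output", {
  tab <- tiny_table()
  idx <- build_index(tab)
  res <- resolve_names(idx, tab, c("Quercus alba", "Fagus grandifolia"))
  expect_identical(res$decision, c("match", "no_match"))
  expect_identical(res$accepted_id, c("ub1", NA_character_))
  p <- tempfile(fileext = ".tsv")
  write_resolutions(res, p)
  back <- read.delim(p, colClasses = "character", na.strings = "")
  expect_identical(back$decision, res$decision)
  pj <- tempfile(fileext = ".jsonl")
  write_resolutions(res, pj, format = "jsonl")
  expect_length(readLines(pj), 2L)
})
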