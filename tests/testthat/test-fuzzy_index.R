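test_that("ngrams pads with boundary markers and enumerates all windows", {
  expect_setequal(ngrams("alba", 3), c("#al", "alb", "lba", "ba#"))
  expect_length(ngrams("alba", 3), 4L)
  expect_identical(ngrams("aa", 3), c("#aa", "aa#"))
  # |padded| - n + 1 windows, enumerated independently by substring walk
  s <- "quercus alba"
  padded <- paste0("#", s, "#")
  manual <- vapply(1:(nchar(padded) - 2L),
                   function(i) substr(padded, i, i + 2L), character(1))
  expect_identical(ngrams(s, 3), manual)
  expect_length(ngrams(s, 3), nchar(s) + 2L - 3L + 1L) # 12 windows
  expect_error(ngrams("ab", 5), "too short")
})

test_that("build_index posting mass equals total gram counts", {
  tab1 <- taxonomy_table(data.frame(
    record_id = "ub1", raw_name = "Poa annua", canonical_name = "poa annua",
    status = "accepted", accepted_id = "ub1", rank = "species",
    kingdom = "Plantae", sources = "t", stringsAsFactors = FALSE))
  idx1 <- build_index(tab1)
  for (g in ngrams("poa annua", 3)) {
    expect_true(1L %in% get(g, envir = idx1$postings))
  }

  tab2 <- tiny_table()
  idx2 <- build_index(tab2)
  # records sharing the genus share the genus-region grams
  shared <- intersect(ngrams("quercus alba", 3), ngrams("quercus rubra", 3))
  for (g in shared) {
    expect_setequal(unique(get(g, envir = idx2$postings)), c(1L, 2L))
  }

  # conservation on a large synthetic table, computed two ways
  tab3 <- generate_taxonomy(100, 10, seed = 3)
  idx3 <- build_index(tab3)
  posting_mass <- sum(vapply(ls(idx3$postings),
                             function(g) length(get(g, envir = idx3$postings)),
                             integer(1)))
  expect_identical(posting_mass, sum(idx3$gram_counts))
  expect_identical(sum(idx3$gram_counts),
                   sum(nchar(tab3$records$canonical_name) + 2L - 2L))
})

test_that("query_candidates ranks by similarity with exact hits first", {
  tab <- tiny_table()
  idx <- build_index(tab)
  r <- query_candidates(idx, "quercus alba", k = 10)
  expect_identical(r$record_id[1], "ub1")
  expect_equal(r$retrieval_score[1], 1.0)
  expect_identical(r$rank, seq_len(nrow(r)))
  expect_true(all(diff(r$retrieval_score) <= 0))
  expect_lte(nrow(r), 3L) # no more candidates than records
  expect_true(all(r$retrieval_score >= 0 & r$retrieval_score <= 1))
  expect_true(all((r$retrieval_score == 1) == (r$canonical_name == "quercus alba")))

  # one-typo query: winner must agree with an exhaustive oracle scan
  q <- "quercus albaa"
  d <- vapply(tab$records$canonical_name, oracle_osa, integer(1), a = q)
  expect_identical(query_candidates(idx, q)$canonical_name[1],
                   unname(tab$records$canonical_name[which.min(d)]))

  expect_error(query_candidates(idx, "poa"), "4 characters")
  expect_error(query_candidates(idx, "  "), "empty|4 characters")
})

test_that("retrieval is deterministic and complete for close queries", {
  tab <- generate_taxonomy(200, 10, seed = 19)
  idx <- build_index(tab)
  set.seed(20)
  names <- tab$records$canonical_name
  for (trial in 1:60) {
    src <- sample(length(names), 1L)
    e <- sample(1:2, 1L)
    q <- corrupt(names[src], typo_model(n_edits = e))
    r1 <- query_candidates(idx, q, k = 10)
    r2 <- query_candidates(idx, q, k = 10)
    expect_identical(r1, r2)
    # the true source survives retrieval (it is within distance <= 2)
    expect_true(names[src] %in% r1$canonical_name,
                label = paste("query", q, "missing", names[src]))
  }
})

test_that("dl_distance agrees with the pure-R oracle", {
  set.seed(31)
  for (i in 1:300) {
    a <- random_string(4, 20)
    b <- random_string(4, 20)
    expect_identical(dl_distance(a, b), oracle_osa(a, b))
  }
  # transposition counts as one edit
  expect_identical(dl_distance("quercus", "qeurcus"), 1L)
  expect_identical(dl_distance("abc", "abc"), 0L)
})

test_that("index persistence round-trips and validates its header", {
  tab <- generate_taxonomy(20, 5, seed = 8)
  idx <- build_index(tab)
  p <- tempfile(fileext = ".idx")
  save_index(idx, p)
  idx2 <- load_index(p)
  q <- corrupt(tab$records$canonical_name[7], typo_model(1), seed = 9)
  expect_identical(query_candidates(idx, q), query_candidates(idx2, q))

  junk <- tempfile()
  saveRDS(list(magic = "something else"), junk)
  expect_error(load_index(junk), "not a taxonmatch index")
})
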