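# Word index, seed-and-extend search, expectation values, BLAST interop.

test_that("the word index posts every N-free word on the plus strand", {
  idx <- build_word_index(c(t1 = "ACGTACG"), word_size = 4)
  expect_identical(idx$n_postings, 4L)           # 7 - 4 + 1
  p <- idx$postings[["ACGT"]]
  expect_identical(p[, "pos"], c(pos = 1L))

  # an N in every window leaves nothing to index
  idx_n <- build_word_index(c(t1 = "ACGNACGNACG"), word_size = 4)
  expect_identical(idx_n$n_postings, 0L)

  set.seed(5L)
  idx_1kb <- build_word_index(c(t1 = random_dna(1000L)), word_size = 7)
  expect_identical(idx_1kb$n_postings, 994L)     # L - w + 1

  expect_error(build_word_index(character(0)), "non-empty")
  expect_error(build_word_index(c("ACGTACGT")), "names")
})

test_that("a verbatim planted query is found on the plus strand at 100%", {
  set.seed(21L)
  q <- random_dna(30L)
  txome <- c(bg = random_dna(300L), target = random_dna(300L))
  substr(txome[["target"]], 101, 130) <- q
  h <- seed_extend_search(q, txome, search_params(), query_id = "q")
  hit <- h[h$subject_id == "target" & h$strand == "plus", ][1L, ]
  expect_identical(hit$identity_pct, 100)
  expect_identical(hit$score, 30L * 2L)
  expect_identical(c(hit$q_start, hit$q_end), c(1L, 30L))
  expect_identical(c(hit$s_start, hit$s_end), c(101L, 130L))
})

test_that("a planted reverse complement is found on the minus strand", {
  set.seed(22L)
  q <- random_dna(30L)
  txome <- c(target = random_dna(300L))
  substr(txome[["target"]], 51, 80) <- revcomp(q)
  h <- seed_extend_search(q, txome, search_params(), query_id = "q")
  hit <- h[h$strand == "minus", ][1L, ]
  expect_identical(hit$identity_pct, 100)
  expect_true(hit$s_start > hit$s_end)           # BLAST minus convention
  expect_identical(c(hit$s_start, hit$s_end), c(80L, 51L))
  expect_identical(c(hit$q_start, hit$q_end), c(1L, 30L))
})

test_that("a query shorter than the word size is rejected naming both lengths", {
  txome <- c(t1 = random_dna(100L))
  expect_error(seed_extend_search("ACGTA", txome, search_params()),
               "length 5.*word size 7")
})

test_that("batch search skips (with a warning) variants too short to seed", {
  set.seed(23L)
  txome <- c(t1 = random_dna(200L))
  v <- data.frame(
    variant_id = c("p|rev|S-C", "p|fwd|S-C"),
    sequence = c("AATAAA", random_dna(30L)),
    stringsAsFactors = FALSE
  )
  expect_warning(h <- search_variants(v, txome, search_params()),
                 "p\\|rev\\|S-C")
  expect_false("p|rev|S-C" %in% h$query_id)
})

test_that("best seeded scores equal the independent Smith-Waterman oracle", {
  set.seed(33L)
  params <- search_params()
  for (i in 1:60) {
    pair <- seeded_pair(sample(20:60, 1), sample(100:500, 1))
    h <- seed_extend_search(pair$q, c(s1 = pair$s), params)
    plus <- h[h$strand == "plus", ]
    expect_gt(nrow(plus), 0L)
    expect_identical(max(plus$score), as.integer(sw_oracle_score(pair$q, pair$s)))
  }
})

test_that("minus-strand scores equal plus-strand scores of the reverse complement", {
  set.seed(44L)
  txome <- setNames(replicate(5, random_dna(400L)), paste0("t", 1:5))
  q <- random_dna(40L)
  substr(txome[["t2"]], 11, 50) <- revcomp(q)
  substr(txome[["t4"]], 101, 140) <- q
  params <- search_params()
  h_q <- seed_extend_search(q, txome, params)
  h_rc <- seed_extend_search(revcomp(q), txome, params)
  minus_q <- h_q[h_q$strand == "minus", c("subject_id", "score")]
  plus_rc <- h_rc[h_rc$strand == "plus", c("subject_id", "score")]
  ord <- function(d) d[order(d$subject_id), , drop = FALSE]
  expect_identical(ord(minus_q)$score, ord(plus_rc)$score)
})

test_that("the E-value filter and target cap are sound, and runs are deterministic", {
  set.seed(55L)
  txome <- setNames(replicate(12, random_dna(300L)), sprintf("t%02d", 1:12))
  q <- random_dna(25L)
  for (i in 1:6) substr(txome[[i]], 40, 64) <- q    # several real targets
  params <- search_params(evalue_max = 10, max_targets = 3)
  h <- seed_extend_search(q, txome, params)
  expect_true(all(h$evalue <= 10))
  expect_lte(length(unique(h$subject_id)), 3L)
  expect_false(is.unsorted(h$evalue))
  expect_identical(h, seed_extend_search(q, txome, params))
})

test_that("expectation values are monotone in score and linear in database size", {
  lk <- c(lambda = 0.625, K = 0.41)
  e <- evalue_from_score(10:40, 42, 1e5, lk)
  expect_true(all(diff(e) < 0))
  expect_equal(evalue_from_score(20, 42, 2e5, lk),
               2 * evalue_from_score(20, 42, 1e5, lk))
  # direct reimplementation of the formula, 6 significant digits
  expect_equal(signif(evalue_from_score(40, 42, 1e5, lk), 6),
               signif(0.41 * 42 * 1e5 * exp(-0.625 * 40), 6))
  expect_equal(bit_score(40, lk), (0.625 * 40 - log(0.41)) / log(2))
})

test_that("the shipped lambda agrees with the Karlin sum equation root", {
  lam <- solve_karlin_lambda(2, -3)
  expect_lt(abs(lam - 0.625) / 0.625, 0.02)
  # and the root actually solves the equation
  expect_equal(0.25 * exp(lam * 2) + 0.75 * exp(lam * -3), 1, tolerance = 1e-9)
  expect_error(solve_karlin_lambda(3, -1), "negative")
})

test_that("an unsupported scoring scheme demands explicit lambda and K", {
  expect_error(search_params(match = 5, mismatch = -4), "lambda_k")
  p <- search_params(match = 5, mismatch = -4,
                     lambda_k = c(lambda = 0.3, K = 0.2))
  expect_identical(p$lambda_k[["lambda"]], 0.3)
})

test_that("search params validate their invariants", {
  expect_error(search_params(word_size = 3))
  expect_error(search_params(evalue_max = 0))
  expect_error(search_params(max_targets = 0))
  expect_error(search_params(match = -1, mismatch = -3))
})

test_that("BLAST tabular rows parse with strand inferred from coordinates", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\ts1\t100.000\t30\t0\t0\t1\t30\t61\t90\t1e-10\t55.4",
    "q1\ts2\t95.000\t20\t1\t0\t1\t20\t120\t61\t0.5\t30.1",
    "q2\ts1\t90.000\t10\t1\t0\t5\t14\t7\t16\t2.5\t15.0"
  ), path)
  h <- parse_blast_tabular(path)
  expect_identical(nrow(h), 3L)
  expect_identical(h$strand, c("plus", "minus", "plus"))
  expect_identical(h$s_start, c(61L, 120L, 7L))
  expect_identical(h$identity_pct, c(100, 95, 90))

  writeLines("q1\ts1\tnot-enough-columns", path)
  expect_error(parse_blast_tabular(path), "line 1")
  writeLines("q1\ts1\tABC\t30\t0\t0\t1\t30\t61\t90\t1e-10\t55.4", path)
  expect_error(parse_blast_tabular(path), "line 1.*non-numeric")
})

test_that("hit tables round-trip through the 12-column tabular format", {
  set.seed(66L)
  txome <- setNames(replicate(4, random_dna(300L)), paste0("t", 1:4))
  q <- random_dna(30L)
  substr(txome[["t1"]], 11, 40) <- q
  substr(txome[["t3"]], 51, 80) <- revcomp(q)
  h <- seed_extend_search(q, txome, search_params())
  path <- tempfile(fileext = ".tsv")
  write_blast_tabular(h, path)
  back <- parse_blast_tabular(path)
  expect_identical(back$subject_id, h$subject_id)
  expect_identical(back$strand, h$strand)
  expect_identical(back[, c("q_start", "q_end", "s_start", "s_end",
                            "align_len", "mismatches", "gap_opens")],
                   h[, c("q_start", "q_end", "s_start", "s_end",
                         "align_len", "mismatches", "gap_opens")])
  expect_equal(back$identity_pct, h$identity_pct, tolerance = 1e-3)
  expect_equal(back$evalue, h$evalue, tolerance = 1e-5)
})
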