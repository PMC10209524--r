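test_that("character matching requires equal unambiguous nucleotides", {
  expect_true(chars_match("A", "A"))
  expect_false(chars_match("N", "N"))
  expect_false(chars_match("A", "C"))
  expect_false(chars_match(">", ">"))
  expect_false(chars_match("a", "a"))
})

test_that("seed extension is maximal and respects the length filter", {
  r <- mem_genome("ACGTACGTAC")
  expect_equal(unname(extend_seed(r, r, 0, 0, K = 4, L = 5)), c(0, 0, 10))
  r2 <- mem_genome("TTACGTAA")
  q2 <- mem_genome("GGACGTCC")
  expect_equal(unname(extend_seed(r2, q2, 2, 2, K = 4, L = 4)), c(2, 2, 4))
  expect_null(extend_seed(r2, q2, 2, 2, K = 4, L = 5))
})

test_that("every emitted triple is exact inside and non-matching at flanks", {
  pr <- make_pair(seq_len = 3000, divergence = 0.02, seed = 51)
  p <- mem_params(50)
  idx <- build_seed_index(pr$ref, p)
  tri <- mems_distinct(scan_query(pr$ref, pr$query, idx, p)$triples)
  expect_gt(nrow(tri), 0)
  rs <- strsplit(pr$ref$text, "")[[1]]
  qs <- strsplit(pr$query$text, "")[[1]]
  for (i in seq_len(nrow(tri))) {
    r0 <- tri[i, 1]; q0 <- tri[i, 2]; len <- tri[i, 3]
    inside <- chars_match(rs[(r0 + 1):(r0 + len)], qs[(q0 + 1):(q0 + len)])
    expect_true(all(inside))
    expect_gte(len, p$L)
    if (r0 > 0 && q0 > 0)
      expect_false(chars_match(rs[r0], qs[q0]))
    if (r0 + len < pr$ref$total_length && q0 + len < pr$query$total_length)
      expect_false(chars_match(rs[r0 + len + 1], qs[q0 + len + 1]))
  }
})

test_that("containment cache skips only same-diagonal contained seeds", {
  cc <- diagonal_cache()
  expect_false(containment_skip(cc, 40, 40, 36))
  cache_record(cc, 0, 0, 100)           # diagonal 0, interval [0, 100)
  expect_true(containment_skip(cc, 40, 40, 36))   # 40 >= 0 and 76 <= 100
  expect_false(containment_skip(cc, 150, 40, 36)) # diagonal 110
  expect_false(containment_skip(cc, 70, 70, 36))  # 70 + 36 > 100
})

test_that("scan finds the full-length self-match and matches the oracle", {
  g <- generate_genome(1, 1000, seed = 61)
  p <- mem_params(50)
  idx <- build_seed_index(g, p)
  tri <- mems_distinct(scan_query(g, g, idx, p)$triples)
  expect_true(any(tri[, 1] == 0 & tri[, 2] == 0 & tri[, 3] == 1000))
  expect_identical(strip_names(tri), strip_names(oracle_mems(g, g, 50)))
})

test_that("a query without unambiguous bases yields nothing", {
  g <- generate_genome(1, 500, seed = 62)
  q <- mem_genome(strrep("N", 500))
  p <- mem_params(50)
  idx <- build_seed_index(g, p)
  sc <- scan_query(g, q, idx, p)
  expect_equal(nrow(sc$triples), 0)
  expect_equal(unname(sc$counters["n_probed"]), 0)
})

test_that("the containment filter is lossless on a similar pair", {
  pr <- make_pair(seq_len = 5000, divergence = 0.01, seed = 42)
  p <- mem_params(50)
  idx <- build_seed_index(pr$ref, p)
  on_ <- scan_query(pr$ref, pr$query, idx, p, containment = TRUE)
  off <- scan_query(pr$ref, pr$query, idx, p, containment = FALSE)
  expect_identical(strip_names(mems_distinct(on_$triples)),
                   strip_names(mems_distinct(off$triples)))
  # the filter prunes work on similar genomes
  expect_lt(on_$counters["n_verified"], off$counters["n_verified"])
})

test_that("distinct output equals the oracle across parameter regimes", {
  pr <- make_pair(seq_len = 4000, divergence = 0.005, seed = 71)
  for (L in c(37, 80)) {
    p <- mem_params(L)
    idx <- build_seed_index(pr$ref, p)
    tri <- mems_distinct(scan_query(pr$ref, pr$query, idx, p)$triples)
    expect_identical(strip_names(tri),
                     strip_names(oracle_mems(pr$ref, pr$query, L)),
                     info = sprintf("L=%d", L))
  }
})

test_that("worker count never changes the distinct result", {
  pr <- make_pair(seq_len = 4000, divergence = 0.01, seed = 81)
  p <- mem_params(50)
  idx <- build_seed_index(pr$ref, p)
  ref <- mems_distinct(scan_query(pr$ref, pr$query, idx, p, workers = 1)$triples)
  for (w in c(2, 4, 7))
    expect_identical(strip_names(mems_distinct(
      scan_query(pr$ref, pr$query, idx, p, workers = w)$triples)),
      strip_names(ref))
})

test_that("parameter mismatch between index and scan is rejected", {
  g <- generate_genome(1, 2000, seed = 91)
  idx <- build_seed_index(g, mem_params(50))
  expect_error(scan_query(g, g, idx, mem_params(80)), "different parameters")
})
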