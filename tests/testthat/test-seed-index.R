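test_that("k-mer hashing is deterministic and respects bucket width", {
  k <- strrep("ACGT", 9)
  expect_identical(hash_kmer(k, 20), hash_kmer(k, 20))
  expect_equal(hash_kmer(k, 0), 0)
  expect_error(hash_kmer("ACGN", 8), "non-ACGT")
  set.seed(5)
  kms <- vapply(1:200, function(i)
    paste(sample(c("A", "C", "G", "T"), 36, replace = TRUE), collapse = ""),
    character(1))
  h <- vapply(kms, hash_kmer, numeric(1), bucket_bits = 20)
  expect_true(all(h >= 0 & h < 2^20))
})

test_that("hash disperses random 36-mers without pathological buckets", {
  set.seed(99)
  n <- 10000L
  kms <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 36, replace = TRUE), collapse = ""),
    character(1))
  h <- vapply(kms, hash_kmer, numeric(1), bucket_bits = 20)
  expect_lte(max(table(h)), 50)
})

test_that("index stores exactly the clean sampled positions", {
  g <- mem_genome("ACGTACGT")
  p <- mem_params(37)
  p$K <- 4L; p$k1 <- 2L
  idx <- build_seed_index(g, p, bucket_bits = 8)
  expect_setequal(idx$pos, c(0, 2, 4))
  hits <- seed_lookup(idx, "ACGT")
  verified <- hits[vapply(hits, function(q)
    substring(g$text, q + 1, q + 4) == "ACGT", logical(1))]
  expect_setequal(verified, c(0, 4))

  # N-containing sampled k-mers are skipped
  g2 <- mem_genome("ACNTACGT")
  idx2 <- build_seed_index(g2, p, bucket_bits = 8)
  expect_equal(as.numeric(idx2$pos), 4)
})

test_that("stored positions equal a brute-force scan on a random genome", {
  g <- generate_genome(3, c(40000, 30000, 30000), seed = 21)
  q <- mutate_genome(g, mutation_model(n_run_rate = 0.001, seed = 22))
  p <- mem_params(50)
  idx <- build_seed_index(q, p)
  chars <- strsplit(q$text, "")[[1]]
  clean <- chars %in% c("A", "C", "G", "T")
  cand <- seq(0, q$total_length - p$K, by = p$k1)
  ok <- vapply(cand, function(s) all(clean[(s + 1):(s + p$K)]), logical(1))
  expect_identical(sort(as.numeric(idx$pos)), as.numeric(cand[ok]))
  # positions within each bucket are increasing
  expect_true(all(tapply(idx$pos, idx$bucket, function(x) !is.unsorted(x))))
})

test_that("no false negatives at sampled positions; absent k-mer returns empty", {
  g <- generate_genome(1, 20000, seed = 33)
  p <- mem_params(50)
  idx <- build_seed_index(g, p)
  set.seed(34)
  for (s in sample(idx$pos, 50)) {
    kmer <- substring(g$text, s + 1, s + p$K)
    expect_true(s %in% seed_lookup(idx, kmer))
  }
  expect_length(seed_lookup(idx, strrep("N", p$K)), 0)
})

test_that("memory-frugal sizing uses two fewer bits with identical scan results", {
  expect_equal(default_bucket_bits(2^10, "default"), 20L)
  expect_equal(default_bucket_bits(2^10, "memory-frugal"), 18L)
  expect_equal(default_bucket_bits(2^20, "default"), 26L)
  pr <- make_pair(seq_len = 3000, divergence = 0.01, seed = 8)
  p <- mem_params(50)
  i1 <- build_seed_index(pr$ref, p)
  i2 <- build_seed_index(pr$ref, p, bucket_bits = i1$bucket_bits - 2L)
  d1 <- mems_distinct(scan_query(pr$ref, pr$query, i1, p)$triples)
  d2 <- mems_distinct(scan_query(pr$ref, pr$query, i2, p)$triples)
  expect_identical(strip_names(d1), strip_names(d2))
})
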