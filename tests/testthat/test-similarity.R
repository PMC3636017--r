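# The k-mer seeded banded alignment engine.

test_that("seed index stores every k-mer posting", {
  idx <- build_index(c(ref1 = "ACGTACGT"), k = 4)
  kmers <- substring("ACGTACGT", 1:5, 4:8)
  postings <- lapply(unique(kmers), index_postings, index = idx)
  expect_identical(sum(vapply(postings, nrow, integer(1))), 5L)
  # postings equal a brute-force substring enumeration on fuzzed references
  set.seed(21)
  refs <- setNames(vapply(1:5, function(i) rand_dna(sample(40:80, 1)), ""),
                   paste0("r", 1:5))
  idx2 <- build_index(refs, k = 6)
  for (si in seq_along(refs)) {
    L <- nchar(refs[si])
    for (p in seq_len(L - 5L)) {
      km <- substr(refs[[si]], p, p + 5L)
      m <- index_postings(idx2, km)
      expect_true(any(m[, "subject"] == si & m[, "pos"] == p))
    }
  }
  expect_error(build_index(refs, k = 3), "at least 4")
  expect_error(build_index(refs, k = 200), "shortest")
})

test_that("every reference self-hits at 100 percent identity", {
  set.seed(22)
  refs <- setNames(vapply(1:8, function(i) rand_dna(150), ""),
                   paste0("ref", 1:8))
  idx <- build_index(refs)
  for (i in seq_along(refs)) {
    h <- best_hit(refs[i], idx)
    expect_identical(h$subject, names(refs)[i])
    expect_equal(h$percent_identity, 100)
  }
})

test_that("pairwise identity handles worked cases and is symmetric", {
  set.seed(23)
  a <- rand_dna(100)
  expect_equal(align_identity(a, a)$percent_identity, 100)
  expect_identical(align_identity(a, a)$alignment_length, 100L)
  b <- a
  substr(b, 50, 50) <- if (substr(a, 50, 50) == "A") "C" else "A"
  expect_equal(align_identity(a, b)$percent_identity, 99)
  for (i in 1:25) {
    x <- rand_dna(sample(50:150, 1))
    y <- parastx:::mutate_sequences(x, 0.05)
    ab <- align_identity(x, y)
    ba <- align_identity(y, x)
    expect_equal(ab$percent_identity, ba$percent_identity)
    expect_gte(ab$percent_identity, 0)
    expect_lte(ab$percent_identity, 100)
  }
})

test_that("banded alignment equals the full-DP oracle on in-band pairs", {
  set.seed(24)
  for (i in 1:100) {
    L <- sample(60:250, 1)
    a <- rand_dna(L)
    b <- parastx:::mutate_sequences(a, runif(1, 0, 0.08))
    if (runif(1) < 0.5) {  # occasional short indel
      p <- sample(nchar(b) - 5L, 1)
      b <- paste0(substr(b, 1, p),
                  substr(b, p + sample(1:3, 1) + 1L, nchar(b)))
    }
    got <- align_identity(a, b)
    want <- oracle_global(a, b)
    expect_equal(got$score, want$score)
    expect_identical(got$alignment_length, want$columns)
    expect_equal(got$percent_identity, 100 * want$matches / want$columns)
  }
})

test_that("best hit is deterministic and ties break to the smaller subject id", {
  set.seed(25)
  s <- rand_dna(120)
  idx <- build_index(c(zebra = s, alpha = s))
  h <- best_hit(c(q = s), idx)
  expect_identical(h$subject, "alpha")
  h2 <- best_hit(c(q = s), idx)
  expect_identical(h, h2)
})

test_that("best hit recovers the true source of error-free queries", {
  cfg <- small_sim(26)
  refs <- simulate_reference_sets(cfg)
  idx <- build_index(refs$sets$parasite_assembly)
  hits <- search_hits(refs$sets$parasite_assembly, idx)
  expect_identical(nrow(hits), length(refs$sets$parasite_assembly))
  expect_gte(mean(hits$subject == hits$query), 0.99)
})

test_that("read mapping applies the coverage and identity rules", {
  set.seed(27)
  tx <- setNames(rand_dna(500), "t1")
  starts <- sample(400, 30)
  reads <- setNames(substring(tx, starts, starts + 79), paste0("r", 1:30))
  res <- map_reads(reads, tx)
  expect_identical(unname(res$counts["t1"]), 30L)
  # a read with only 40 percent alignable stays unmapped at fraction 0.5
  part <- paste0(substr(tx, 101, 140), rand_dna(60))
  res2 <- map_reads(c(bad = part), tx)
  expect_identical(unname(res2$counts["t1"]), 0L)
})

test_that("read assignment equals the exhaustive all-pairs oracle", {
  set.seed(28)
  refs <- setNames(vapply(1:5, function(i) rand_dna(300), ""),
                   paste0("tx", 1:5))
  pol <- mapping_policy()
  reads <- character(0)
  for (i in 1:40) {
    si <- sample(5, 1)
    st <- sample(220, 1)
    r <- substring(refs[[si]], st, st + 79)
    r <- parastx:::mutate_sequences(r, 0.02)
    if (runif(1) < 0.5) r <- parastx:::revcomp(r)
    reads <- c(reads, r)
  }
  names(reads) <- sprintf("read%02d", 1:40)
  got <- map_reads(reads, refs, pol)
  want <- vapply(reads, oracle_read_assign, "", reference = refs,
                 policy = pol)
  got_assign <- setNames(rep(NA_character_, 40), names(reads))
  got_assign[got$assignments$read_id] <- got$assignments$subject
  expect_identical(unname(got_assign), unname(want))
})
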