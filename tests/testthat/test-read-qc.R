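# End trimming, pair repair accounting, and read-level host screening.

test_that("end trimming follows the floor and survival rules on worked cases", {
  # all bases above the floor: untouched
  r <- quality_trim(strrep("A", 83), strrep(intToUtf8(30 + 33), 83))
  expect_true(r$kept)
  expect_identical(nchar(r$seq), 83L)

  # 83 bp with the last 50 bases below the floor: 33 < 41.5 survive -> drop
  qual <- paste0(strrep(intToUtf8(30 + 33), 33), strrep(intToUtf8(10 + 33), 50))
  r2 <- quality_trim(strrep("A", 83), qual)
  expect_false(r2$kept)

  # interior low-quality bases are untouched (end-trimming only)
  qual3 <- paste0(intToUtf8(5 + 33), strrep(intToUtf8(30 + 33), 10),
                  intToUtf8(5 + 33), strrep(intToUtf8(30 + 33), 10))
  r3 <- quality_trim(strrep("C", 22), qual3)
  expect_true(r3$kept)
  expect_identical(nchar(r3$seq), 21L)  # only the leading base stripped
  expect_identical(r3$trim_start, 2L)

  # malformed quality string names the record
  expect_error(quality_trim(c("ACGT", "ACGT"), c("IIII", "III")),
               "record 2")
})

test_that("trimming equals the brute-force oracle on fuzzed reads", {
  set.seed(11)
  n <- 1000
  seqs <- character(n)
  quals <- character(n)
  for (i in seq_len(n)) {
    L <- sample(10:90, 1)
    seqs[i] <- rand_dna(L)
    quals[i] <- intToUtf8(sample(c(2L, 10L, 19L, 20L, 25L, 38L), L,
                                 replace = TRUE,
                                 prob = c(2, 2, 2, 1, 2, 6)) + 33L)
  }
  got <- quality_trim(seqs, quals)
  for (i in seq_len(n)) {
    want <- oracle_trim(seqs[i], quals[i])
    if (is.null(want)) {
      expect_false(got$kept[i])
    } else {
      expect_true(got$kept[i])
      expect_identical(got$seq[i], want$seq)
      expect_identical(got$qual[i], want$qual)
    }
  }
})

test_that("raising the quality floor never lengthens a surviving read", {
  set.seed(12)
  for (i in 1:100) {
    L <- sample(20:80, 1)
    s <- rand_dna(L)
    q <- intToUtf8(sample(2:40, L, replace = TRUE) + 33L)
    lo <- quality_trim(s, q, trim_policy(quality_floor = 15))
    hi <- quality_trim(s, q, trim_policy(quality_floor = 25))
    len <- function(tr) if (tr$kept) nchar(tr$seq) else 0L
    expect_lte(len(hi), len(lo))
  }
})

test_that("pair repair conserves reads exactly on fuzzed pairs", {
  set.seed(13)
  n <- 1000L
  mk <- function() {
    L <- sample(20:60, 1)
    list(seq = rand_dna(L),
         qual = intToUtf8(sample(c(2L, 38L), L, TRUE, prob = c(1, 2)) + 33L))
  }
  m1 <- replicate(n, mk(), simplify = FALSE)
  m2 <- replicate(n, mk(), simplify = FALSE)
  t1 <- quality_trim(vapply(m1, `[[`, "", "seq"),
                     vapply(m1, `[[`, "", "qual"))
  t2 <- quality_trim(vapply(m2, `[[`, "", "seq"),
                     vapply(m2, `[[`, "", "qual"))
  ids <- sprintf("P%04d", seq_len(n))
  rp <- repair_pairs(t1, t2, ids)
  acct <- setNames(rp$accounting$count, rp$accounting$stage)
  expect_identical(unname(acct["input_reads"]), 2L * n)
  expect_identical(unname(acct["surviving_paired_reads"] +
                            acct["orphan_reads"] + acct["discarded_reads"]),
                   2L * n)
  expect_length(intersect(rp$pairs$read_id, rp$orphans$read_id), 0)
  # both survive -> paired; exactly one survives -> orphaned
  expect_identical(sort(rp$pairs$read_id), sort(ids[t1$kept & t2$kept]))
  expect_identical(sort(rp$orphans$read_id), sort(ids[xor(t1$kept, t2$kept)]))
  expect_error(repair_pairs(t1, t2, rep("X", n)), "duplicate")
})

test_that("host screening separates origins on synthetic libraries", {
  # f = 0: nothing is host-assigned
  cfg0 <- small_sim(14, contamination_fraction = 0, base_error_rate = 0,
                    low_quality_tail_prob = 0)
  refs0 <- simulate_reference_sets(cfg0)
  lib0 <- simulate_mixed_library(cfg0, refs0)
  # at read scale the identity modes sit near 100 (true host) and 80
  # (incidental), with ~6-point window noise: 95 separates them
  pol <- mapping_policy(min_similarity = 0.95)
  scr0 <- screen_host_reads(lib0$pairs, NULL, refs0$sets$hostA, pol)
  expect_identical(nrow(scr0$host_pairs), 0L)

  # f = 0.1 with a wide divergence gap, screening quality-trimmed pairs
  # (the pipeline's stage order): read-level sensitivity and specificity
  # against ground truth both at least 0.95
  cfg <- small_sim(15)
  refs <- simulate_reference_sets(cfg)
  lib <- simulate_mixed_library(cfg, refs)
  t1 <- quality_trim(lib$pairs$mate1, lib$pairs$qual1)
  t2 <- quality_trim(lib$pairs$mate2, lib$pairs$qual2)
  rp <- repair_pairs(t1, t2, lib$pairs$read_id)
  scr <- screen_host_reads(rp$pairs, NULL, refs$sets$hostA, pol)
  truth_host <- lib$origins$origin[match(scr$pair_flags$read_id,
                                         lib$origins$read_id)] == "hostA"
  called <- c(scr$pair_flags$mate1_host, scr$pair_flags$mate2_host)
  truth <- c(truth_host, truth_host)
  expect_gte(sum(called & truth) / sum(truth), 0.95)
  expect_gte(sum(!called & !truth) / sum(!truth), 0.95)
  # conservation: host-assigned + retained = input reads
  acct <- setNames(scr$accounting$count, scr$accounting$stage)
  expect_identical(unname(acct["host_assigned_reads"] +
                            acct["retained_reads"]),
                   unname(acct["input_reads"]))
})
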