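# Synthetic-data generators: determinism, divergence targets, contamination
# control and qPCR round-trips.

test_that("reference sets are seed-deterministic down to the written bytes", {
  cfg <- small_sim(5)
  r1 <- simulate_reference_sets(cfg)
  r2 <- simulate_reference_sets(cfg)
  expect_identical(r1$sets, r2$sets)
  expect_identical(r1$families, r2$families)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_reference_sets(r1, d1)
  write_reference_sets(r2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("homolog divergence controls pairwise identity", {
  # zero divergence: host homologs identical to their parasite source
  cfg0 <- small_sim(6, divergence_parasite_host = 0)
  r0 <- simulate_reference_sets(cfg0)
  fams <- attr(r0$sets$hostA, "homolog_family")
  hom <- which(!is.na(fams))
  expect_true(length(hom) > 0)
  expect_identical(unname(r0$sets$hostA[hom]),
                   unname(r0$sets$parasite_assembly[fams[hom]]))

  # d = 0.01 at length 1000: mean identity ~ 99% over >= 100 pairs,
  # measured position-by-position (the analytic substitution-only oracle)
  set.seed(60)
  anc <- replicate(120, rand_dna(1000))
  div <- parastx:::mutate_sequences(anc, 0.01)
  ident <- vapply(seq_along(anc), function(i) {
    mean(strsplit(anc[i], "")[[1]] == strsplit(div[i], "")[[1]])
  }, numeric(1))
  mc_err <- 3 * stats::sd(ident) / sqrt(length(ident))
  expect_lt(abs(mean(ident) - 0.99), mc_err + 1e-4)
})

test_that("mixed library hits the configured contamination fraction", {
  # f = 0: no host-origin reads at all
  r <- simulate_reference_sets(small_sim(7, contamination_fraction = 0))
  lib0 <- simulate_mixed_library(small_sim(7, contamination_fraction = 0), r)
  expect_identical(sum(lib0$origins$origin != "parasite"), 0L)

  # f = 0.1 over 10,000 pairs: host count within 3 * sqrt(n f (1-f)) of nf
  cfg <- sim_config(seed = 8, n_parasite_transcripts = 10,
                    n_host_transcripts = 8,
                    transcript_length_range = c(300L, 400L),
                    n_read_pairs = 10000L, contamination_fraction = 0.1)
  refs <- simulate_reference_sets(cfg)
  lib <- simulate_mixed_library(cfg, refs)
  n_host <- sum(lib$origins$origin == "hostA")
  expect_lt(abs(n_host - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  # origin labels partition the reads
  expect_identical(nrow(lib$origins), 10000L)
  expect_true(all(lib$origins$origin %in% c("parasite", "hostA")))
})

test_that("error-free reads are exact substrings of their source", {
  cfg <- small_sim(9, base_error_rate = 0)
  refs <- simulate_reference_sets(cfg)
  lib <- simulate_mixed_library(cfg, refs)
  src <- c(refs$sets$parasite_assembly, refs$sets$hostA)
  for (i in seq_len(50)) {
    tx <- src[[lib$origins$source_id[i]]]
    expect_true(grepl(lib$pairs$mate1[i], tx, fixed = TRUE))
    expect_true(grepl(parastx:::revcomp(lib$pairs$mate2[i]), tx,
                      fixed = TRUE))
  }
})

test_that("read_length longer than the shortest transcript is rejected", {
  cfg <- small_sim(10, transcript_length_range = c(300L, 400L),
                   read_length = 500L)
  refs <- simulate_reference_sets(cfg)
  expect_error(simulate_mixed_library(cfg, refs), "read_length")
})

test_that("qPCR generator reproduces the configured fold exactly without noise", {
  m1 <- qpcr_model(true_fold = 1, ct_noise_sd = 0, bio_noise_sd = 0)
  tab1 <- simulate_qpcr(m1)
  fc1 <- fold_change_ddct(delta_ct(tab1))
  expect_equal(fc1$per_sample$ddct, rep(0, 6))
  m4 <- qpcr_model(true_fold = 4, ct_noise_sd = 0, bio_noise_sd = 0)
  tab4 <- simulate_qpcr(m4)
  fc4 <- fold_change_ddct(delta_ct(tab4))
  treat <- fc4$per_sample$condition == "treatment"
  expect_equal(fc4$per_sample$ddct[treat], rep(-2, 3))
  expect_equal(fc4$fold, 4)
})

test_that("qPCR estimator recovers a 120-fold effect under realistic noise", {
  folds <- vapply(1:100, function(s) {
    tab <- simulate_qpcr(qpcr_model(true_fold = 120, ct_noise_sd = 0.2),
                         seed = s)
    fold_change_ddct(delta_ct(tab))$fold
  }, numeric(1))
  expect_true(all(folds > 120 / 1.5 & folds < 120 * 1.5))
})
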