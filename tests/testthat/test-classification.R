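# Deduplication, translatability, the classification cascade, and assembly
# statistics.

test_that("deduplication removes identical and contained sequences", {
  r <- deduplicate(c(a = "ACGT", b = "ACGT"))
  expect_length(r$retained, 1)
  r2 <- deduplicate(c(long = "ACGTACGT", short = "GTAC"))
  expect_identical(names(r2$retained), "long")
  expect_identical(r2$removed_reason$unigene_id, "short")
  # reverse-complement containment counts too: GGGA is the reverse
  # complement of the contained substring TCCC
  r3 <- deduplicate(c(big = "TTTTTCCCCCAAAAA", rc = "GGGA"))
  expect_identical(names(r3$retained), "big")
})

test_that("deduplication equals the all-pairs containment oracle on fuzzed sets", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(8:15, 1)
    base <- vapply(seq_len(n), function(i) rand_dna(sample(15:40, 1)), "")
    # plant some exact substrings and duplicates
    extra <- vapply(sample(n, 4, replace = TRUE), function(i) {
      L <- nchar(base[i])
      a <- sample(L - 5L, 1)
      s <- substr(base[i], a, a + sample(4:(L - a), 1))
      if (runif(1) < 0.3) parastx:::revcomp(s) else s
    }, "")
    seqs <- setNames(c(base, extra), sprintf("s%02d", seq_len(n + 4)))
    got <- deduplicate(seqs)
    expect_identical(sort(names(got$retained)), oracle_dedup(seqs))
  }
})

test_that("translatability filter keys on the longest ORF", {
  # single stop-free frame: kept even at fraction 1
  clean <- strrep("GCT", 100)
  expect_true(translatability_filter(c(u1 = clean), 1)$keep)
  # random sequence carries a stop roughly every 21 codons, so a stop-free
  # run spanning half of 400 codons is vanishingly rare: dropped at 0.5
  set.seed(42)
  rand <- setNames(vapply(1:20, function(i) rand_dna(1200), ""),
                   paste0("r", 1:20))
  expect_true(all(!translatability_filter(rand, 0.5)$keep))
  # shorter than a codon: dropped with a reason
  tiny <- translatability_filter(c(t1 = "AC"), 0.1)
  expect_false(tiny$keep)
  expect_match(tiny$reason, "codon")
})

test_that("published count accounting is reproduced by the cascade arithmetic", {
  acct <- cascade_accounting(total = 28126, host = 4967, non_plant = 127,
                             parasite_hits = 17887, other_plant = 2975,
                             no_hits = 2170)
  counts <- setNames(acct$count, acct$stage)
  expect_identical(unname(counts["putative_parasite_pool"]), 23032)
  expect_identical(unname(counts["unigenes_total"]),
                   unname(counts["host_unigenes"] +
                            counts["non_plant_unigenes"] +
                            counts["putative_parasite_pool"]))
  expect_error(cascade_accounting(100, 10, 10, 10, 10, 10), "conserve")
})

test_that("stage order sends dual-threshold unigenes to host", {
  set.seed(43)
  s <- rand_dna(400)
  res <- classify_cascade(c(u1 = s), host_db = c(h1 = s),
                          parasite_db = c(p1 = s))
  expect_identical(res$classified$category, "host")
  expect_identical(res$classified$stage, "host_screen")
  expect_identical(res$ambiguous, "u1")
})

test_that("cascade recovers ground-truth origins on synthetic assemblies", {
  cfg <- small_sim(44)
  refs <- simulate_reference_sets(cfg)
  labeled_db <- c(refs$sets$control, refs$sets$microbial)
  kingdom <- data.frame(
    id = names(labeled_db),
    kingdom = c(rep("plant", length(refs$sets$control)),
                rep("non_plant", length(refs$sets$microbial))))
  res <- classify_cascade(refs$sets$mixed_unigenes, refs$sets$hostA,
                          refs$sets$parasite_ref, labeled_db = labeled_db,
                          labels = kingdom, tau_host = 95, tau_parasite = 95)
  truth <- refs$unigene_truth$origin
  called <- res$classified$category
  map <- c(parasite = "parasite", hostA = "host", microbial = "non_plant")
  expect_gte(mean(called == map[truth]), 0.95)
  # partition: every unigene gets exactly one category
  expect_identical(nrow(res$classified), length(refs$sets$mixed_unigenes))
  counts <- setNames(res$accounting$count, res$accounting$stage)
  expect_identical(unname(counts["unigenes_total"]),
                   length(refs$sets$mixed_unigenes))
})

test_that("raising tau_host never increases the host count", {
  cfg <- small_sim(45)
  refs <- simulate_reference_sets(cfg)
  n_host_at <- vapply(c(80, 90, 99), function(tau) {
    res <- classify_cascade(refs$sets$mixed_unigenes, refs$sets$hostA,
                            refs$sets$parasite_ref, tau_host = tau,
                            tau_parasite = 95)
    sum(res$classified$category == "host")
  }, numeric(1))
  expect_true(all(diff(n_host_at) <= 0))
})

test_that("assembly statistics follow the N50 rule", {
  lens <- c(400L, 300L, 200L, 100L)
  expect_identical(n50(lens), 300L)         # cumulative 400, 700 >= 500
  expect_identical(n50(42L), 42L)
  expect_identical(n50(rep(7L, 5)), 7L)
  seqs <- setNames(vapply(lens, function(L) strrep("A", L), ""),
                   paste0("u", 1:4))
  st <- assembly_stats(seqs)
  expect_identical(st$total_bp, 1000L)
  expect_identical(st$n50, 300L)
  expect_identical(st$min_length, 100L)
  st500 <- assembly_stats(seqs, min_length = 250)
  expect_identical(st500$n, 2L)
  expect_error(assembly_stats(seqs, min_length = 999), "no sequences")
})
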