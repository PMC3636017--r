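# Orthogroup assignment, Venn partitioning, interface fractions, and the
# GO Slim chi-square with residual flags.

test_that("venn partition reproduces the published region counts", {
  fx <- venn_fixture(shared_all = 5947, interface_shared = 1124,
                     A_unique = 677, B_unique = 361, A_above = 1066,
                     B_above = 314, above_unique = 1606)
  vp <- venn_partition(fx$A, fx$B, fx$Ref)
  expect_identical(unname(vp$counts),
                   c(5947L, 1124L, 677L, 361L, 1066L, 314L, 1606L))
  fr <- interface_fractions(vp)
  expect_identical(attr(fr, "interface_only_total"), 2162L)
  expect_identical(fr$region, c("interface_shared", "A_interface_unique",
                                "B_interface_unique"))
  expect_identical(fr$percent, c(52, 31, 17))
})

test_that("venn partition is disjoint and complete on edge cases", {
  # three disjoint sets: only the unique regions populate
  vp <- venn_partition(c("a", "b"), c("c"), c("d", "e", "f"))
  expect_identical(unname(vp$counts),
                   c(0L, 0L, 2L, 1L, 0L, 0L, 3L))
  # identical sets: everything in shared_all
  vp2 <- venn_partition(c("x", "y"), c("x", "y"), c("x", "y"))
  expect_identical(unname(vp2$counts["shared_all"]), 2L)
  expect_identical(sum(vp2$counts), 2L)
  # fuzzed: disjointness and completeness
  set.seed(51)
  for (i in 1:20) {
    u <- sprintf("og%03d", 1:60)
    A <- sample(u, sample(5:40, 1))
    B <- sample(u, sample(5:40, 1))
    R <- sample(u, sample(5:40, 1))
    vp3 <- venn_partition(A, B, R)
    all_ids <- unlist(vp3$regions)
    expect_identical(anyDuplicated(all_ids), 0L)
    expect_setequal(all_ids, union(union(A, B), R))
  }
})

test_that("interface fractions equal exact rational arithmetic", {
  set.seed(52)
  for (i in 1:20) {
    cnts <- sample(1:500, 3)
    fx <- venn_fixture(0, cnts[1], cnts[2], cnts[3], 0, 0, 0)
    fr <- interface_fractions(venn_partition(fx$A, fx$B, fx$Ref))
    expect_identical(fr$percent, unname(round(100 * cnts / sum(cnts))))
    expect_lte(abs(sum(fr$percent) - 100), 1)
  }
  fx3 <- venn_fixture(0, 10, 10, 10, 0, 0, 0)
  fr3 <- interface_fractions(venn_partition(fx3$A, fx3$B, fx3$Ref))
  expect_identical(unname(fr3$percent), c(33, 33, 33))
})

test_that("chi-square matches the closed form and flags follow the 4-rule", {
  # perfectly proportional table: statistic 0, p 1, no flags
  prop <- matrix(c(10, 20, 30, 60), 2, 2,
                 dimnames = list(c("catA", "catB"), c("r1", "r2")))
  g <- goslim_chi_square(prop)
  expect_equal(g$statistic, 0)
  expect_equal(g$p_value, 1)
  expect_true(all(g$flags == ""))

  # hand-computed closed form for [[10, 20], [20, 10]]: all E = 15,
  # X2 = 4 * 25/15 = 20/3
  m <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE,
              dimnames = list(c("catA", "catB"), c("r1", "r2")))
  g2 <- goslim_chi_square(m)
  expect_equal(g2$statistic, 20 / 3)
  expect_equal(g2$df, 1)
  expect_equal(unname(g2$residuals[1, 1]), (10 - 15) / sqrt(15))

  # permutation invariance of the statistic
  set.seed(53)
  big <- matrix(rpois(20, 30) + 1, 4, 5,
                dimnames = list(paste0("c", 1:4), paste0("r", 1:5)))
  gA <- goslim_chi_square(big)
  gB <- goslim_chi_square(big[sample(4), sample(5)])
  expect_equal(gA$statistic, gB$statistic)
  expect_identical(gA$df, gB$df)

  # zero margins are dropped with a message
  withzero <- rbind(big, zeroed = 0)
  expect_message(gz <- goslim_chi_square(withzero), "zero-margin")
  expect_identical(gz$dropped, "zeroed")
  expect_equal(gz$statistic, gA$statistic)
})

test_that("planted GO Slim enrichment is detected and flagged", {
  cfg <- sim_config(seed = 54)
  lab <- simulate_comparative_labels(cfg)
  tab <- goslim_contingency(
    lab$unigenes[lab$unigenes$transcriptome == "intA", ])
  g <- goslim_chi_square(tab)
  expect_lt(g$p_value, 0.0001)
  expect_identical(g$flags["no_category", "interface_shared"], "+")
})

test_that("orthogroup assignment inherits the best hit's label", {
  set.seed(55)
  refs <- setNames(vapply(1:6, function(i) rand_dna(300), ""),
                   paste0("ref", 1:6))
  lab <- data.frame(id = names(refs),
                    orthogroup = paste0("OG", rep(1:3, each = 2)))
  queries <- c(q1 = refs[["ref3"]], q2 = rand_dna(300))
  res <- assign_orthogroups(queries, refs, lab)
  expect_identical(res$orthogroup[res$unigene_id == "q1"], "OG2")
  # random query: overwhelmingly no significant hit -> unassigned
  expect_true(is.na(res$orthogroup[res$unigene_id == "q2"]))
  expect_error(assign_orthogroups(queries, refs, lab[-1, ]), "unlabeled")
})

test_that("assignment accuracy is high at zero divergence and degrades smoothly", {
  cfg <- small_sim(56)
  refs <- simulate_reference_sets(cfg)
  lab <- data.frame(id = names(refs$sets$parasite_assembly),
                    orthogroup = refs$families$orthogroup)
  acc <- vapply(c(0, 0.05), function(d) {
    q <- parastx:::mutate_sequences(refs$sets$parasite_assembly, d)
    names(q) <- paste0("q", seq_along(q))
    res <- assign_orthogroups(q, refs$sets$parasite_assembly, lab)
    mean(res$orthogroup == refs$families$orthogroup, na.rm = TRUE) *
      mean(!is.na(res$orthogroup))
  }, numeric(1))
  expect_gte(acc[1], 0.99)
  expect_gte(acc[2], 0.9)
})
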