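test_that("domain excision slices by stored boundaries", {
  rec <- protein_records("P", "MKVAW")
  expect_equal(excise_domains(rec, domain_calls("P", "D", 2L, 4L))$peptide,
               "KVA")
  expect_equal(excise_domains(rec, domain_calls("P", "D", 1L, 5L))$peptide,
               "MKVAW")
  calls <- domain_calls(rep("P", 2), c("CBM", "Cat"), c(1L, 3L),
                        c(2L, 5L))
  expect_equal(excise_domains(rec, calls, name_filter = "CBM")$peptide,
               "MK")
  expect_equal(nrow(excise_domains(rec, calls, name_filter = "Dockerin")),
               0)
  bad <- domain_calls("P", "D", 2L, 9L)
  expect_error(excise_domains(rec, bad), "exceeds sequence length")
})

test_that("within-group identities enumerate unordered pairs", {
  g <- list(a = c("ACGT", "ACGT", "ACGT"))
  ids <- pairwise_group_identities(g)
  expect_length(ids$a, 3)  # C(3,2)
  expect_equal(ids$a, rep(1, 3))
  g2 <- list(x = c("ACGT", "ACGA"))
  expect_equal(pairwise_group_identities(g2)$x, 0.75)
  expect_error(pairwise_group_identities(list(s = "ACGT")), "fewer than 2")
})

test_that("Kruskal-Wallis matches closed forms and conventions", {
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(kw$H, 12 / 42 * (36 / 3 + 225 / 3) - 21)  # 3.857...
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  # cross-check against the built-in test (tie-corrected)
  tied <- list(a = c(1, 2, 2, 3), b = c(2, 4, 4), c = c(5, 6))
  kt <- kruskal.test(unlist(tied),
                     factor(rep(names(tied), lengths(tied))))
  kw2 <- kruskal_wallis(tied)
  expect_equal(kw2$H, unname(kt$statistic))
  expect_equal(kw2$p, kt$p.value)
  # degenerate all-identical input
  expect_equal(kruskal_wallis(list(a = c(2, 2), b = c(2, 2))),
               list(H = 0, p = 1))
  # invariance under monotone transformation
  g <- list(a = c(0.1, 0.5, 0.9), b = c(0.2, 0.6, 1.4), c = c(2, 3, 0.05))
  expect_equal(kruskal_wallis(g)$H,
               kruskal_wallis(lapply(g, function(x) exp(x)))$H)
})

test_that("Dunn post hoc behaves at the boundaries", {
  # identical groups: mean ranks equal, z = 0, p about 1
  p <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)), "none")
  expect_equal(p["a", "b"], 1)
  expect_equal(p, t(p))
  expect_equal(unname(diag(p)), c(1, 1))
  # one extreme group gets the smallest p on its pairs
  g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 4, 5), c = c(50, 60, 70, 80))
  praw <- dunn_posthoc(g, "none")
  expect_lt(praw["a", "c"], praw["a", "b"])
  # bonferroni multiplies by the number of pairs, capped at 1
  pb <- dunn_posthoc(g, "bonferroni")
  expect_equal(pb["a", "c"], min(1, praw["a", "c"] * 3))
  expect_equal(pb["a", "b"], min(1, praw["a", "b"] * 3))
})

test_that("planted-divergence groups are separated as expected", {
  g <- generate_domain_groups(c(I = 12, II = 10, insect = 10),
                              c(0.05, 0.05, 0.25), length = 250,
                              seed = 23)
  cmp <- compare_groups(g)
  expect_lt(cmp$dunn["I", "insect"], 0.001)
  expect_lt(cmp$dunn["II", "insect"], 0.001)
  expect_gt(cmp$dunn["I", "II"], 0.05)
  expect_lt(cmp$H_pvalue, 0.001)
  # mean identity of a 5% group is far above the 25% group
  s <- cmp$summary
  expect_gt(s$mean_identity_pct[s$group == "I"],
            s$mean_identity_pct[s$group == "insect"] + 15)

  # a duplicated group compares as not significant
  same <- generate_domain_groups(c(x = 8), 0.05, length = 150, seed = 24)
  cmp2 <- compare_groups(list(a = same$x, b = same$x, c = same$x))
  expect_true(all(cmp2$dunn[upper.tri(cmp2$dunn)] > 0.9))

  # unbalanced group sizes are handled
  g3 <- generate_domain_groups(c(big = 36, small = 28),
                               c(0.05, 0.25), length = 120, seed = 25)
  cmp3 <- compare_groups(g3)
  expect_equal(cmp3$summary$n_pairs, c(choose(36, 2), choose(28, 2)))
})
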