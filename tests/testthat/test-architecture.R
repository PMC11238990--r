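test_that("architecture strings join N->C domain names", {
  calls <- domain_calls(rep("P", 3),
                        c("CBM", "Immunoglobulin-like", "Catalytic domain"),
                        c(1L, 120L, 220L), c(100L, 200L, 800L))
  expect_equal(architecture_string(calls),
               "CBM + Immunoglobulin-like + Catalytic domain")
  expect_equal(architecture_string(domain_calls("P", "Catalytic domain",
                                                10L, 600L)),
               "Catalytic domain")
  expect_equal(architecture_string(empty_domain_calls()), "")
  # order comes from coordinates, not input row order
  shuffled <- calls[c(3, 1, 2), ]
  expect_equal(architecture_string(shuffled),
               "CBM + Immunoglobulin-like + Catalytic domain")
  # violated consolidation contract is detected
  bad <- domain_calls(rep("P", 2), c("A", "B"), c(1L, 10L), c(100L, 110L))
  expect_error(architecture_string(bad), "overlap")
})

test_that("assembly enumeration partitions proteins and is order-invariant", {
  set.seed(16)
  fix <- generate_fixture(fixture_spec(seed = 16, n_proteins = 60,
                                       n_sources_per_domain = 2))
  cons <- consolidate_all(fix$records$protein_id, fix$annotations,
                          fix$curation)
  asm <- enumerate_assemblies(cons$calls, fix$records)
  expect_equal(nrow(asm), 35)  # pool coverage plants every architecture
  expect_equal(sum(asm$n_members),
               length(unique(cons$calls$protein_id)))
  # member lists partition the proteins with calls
  all_members <- unlist(asm$protein_ids)
  expect_equal(sort(all_members), sort(unique(cons$calls$protein_id)))
  # sorted by member count desc then architecture
  expect_true(all(diff(asm$n_members) <= 0))

  # permutation invariance over protein input order
  perm <- sample(nrow(cons$calls))
  asm2 <- enumerate_assemblies(cons$calls[perm, , drop = FALSE],
                               fix$records)
  expect_equal(asm2$architecture, asm$architecture)
  expect_equal(asm2$n_members, asm$n_members)

  # A+B and B+A are distinct assemblies
  calls <- rbind(domain_calls(rep("X1", 2), c("A", "B"),
                              c(1L, 200L), c(100L, 300L)),
                 domain_calls(rep("X2", 2), c("B", "A"),
                              c(1L, 200L), c(100L, 300L)))
  class(calls) <- c("domain_calls", "data.frame")
  expect_equal(nrow(enumerate_assemblies(calls)), 2)
})

test_that("attribution recovers planted architecture membership", {
  set.seed(17)
  reps <- protein_records(paste0("R", 1:3), random_protein(3, 200))
  archs <- c("Catalytic domain", "CBM + Catalytic domain",
             "Catalytic domain + Dockerin")
  n_q <- 60
  origin <- sample(1:3, n_q, replace = TRUE)
  queries <- protein_records(
    sprintf("Q%02d", 1:n_q),
    vapply(origin, function(k)
      mutate_sequence(reps$sequence[k], round(0.05 * 200)), ""))
  att <- attribute_sequences(queries, reps, archs)
  expect_equal(att$assignments$architecture, archs[origin])
  expect_true(all(att$assignments$identity >= 0.85))
  # prevalences sum to one including the unassigned remainder
  expect_equal(sum(att$prevalence$prevalence), 1, tolerance = 1e-12)

  # identical query maps with identity 1
  q1 <- protein_records("QQ", reps$sequence[2])
  att1 <- attribute_sequences(q1, reps, archs)
  expect_equal(att1$assignments$identity, 1)
  expect_equal(att1$assignments$architecture, archs[2])

  # distant query stays unassigned
  q2 <- protein_records("QF", random_protein(1, 200))
  att2 <- attribute_sequences(q2, reps, archs)
  expect_true(is.na(att2$assignments$architecture))
  expect_equal(att2$prevalence$architecture, "(unassigned)")
})
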