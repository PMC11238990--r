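test_that("deduplication drops repeated identifiers and sequences", {
  r <- rbind(protein_records("P1", "MKV"),
             protein_records("P2", "MKV"))
  dd <- deduplicate(r)
  expect_equal(dd$kept$protein_id, "P1")
  expect_equal(dd$dropped$reason, "duplicate-sequence")

  r2 <- data.frame(protein_id = c("P1", "P1"),
                   sequence = c("MKV", "AAA"),
                   description = "", taxonomy_group = "Unclassified",
                   characterized = FALSE, stringsAsFactors = FALSE)
  r2$ec_numbers <- list(character(), character())
  dd2 <- deduplicate(r2)
  expect_equal(dd2$kept$sequence, "MKV")
  expect_equal(dd2$dropped$reason, "duplicate-identifier")

  set.seed(8)
  r3 <- protein_records(sprintf("U%03d", 1:100), random_protein(100, 40))
  expect_equal(nrow(deduplicate(r3)$kept), 100)

  # idempotence
  expect_equal(deduplicate(dd$kept)$kept, dd$kept)
})

test_that("partial filtering is token- and case-aware", {
  r <- protein_records(c("A", "B", "C"), c("MKA", "MKC", "MKD"),
                       description = c("endoglucanase, Partial",
                                       "partially characterized", ""))
  fp <- filter_partial(r)
  expect_equal(fp$kept$protein_id, c("B", "C"))
  expect_equal(fp$dropped$protein_id, "A")
  expect_equal(filter_partial(fp$kept)$kept, fp$kept)
})

test_that("presence filtering keeps exactly the listed ids", {
  r <- protein_records(paste0("P", 1:5), random_protein(5, 20))
  pr <- filter_presence(r, c("P1", "P3", "P5"))
  expect_equal(pr$kept$protein_id, c("P1", "P3", "P5"))
  expect_equal(pr$dropped$reason, rep("absent-from-reference", 2))
  expect_equal(filter_presence(r, paste0("P", 1:9))$kept, r)
  expect_warning(filter_presence(r, character()), "empty")

  # a large presence fixture with a known number of absentees
  set.seed(9)
  ids <- sprintf("GEN%04d", 1:1712)
  absent <- sample(ids, 61)
  r2 <- protein_records(ids, random_protein(1712, 10))
  pr2 <- filter_presence(r2, setdiff(ids, absent))
  expect_equal(nrow(pr2$kept), 1651)
  expect_equal(nrow(pr2$dropped), 61)
})

test_that("greedy clustering recovers planted families", {
  r <- protein_records(c("A", "B", "C"), rep("MKVAWLL", 3))
  # identical sequences: deduplicate normally removes these, but the
  # clusterer itself must also handle them
  cl <- cluster_greedy(r)
  expect_equal(nrow(cl$representatives), 1)
  expect_equal(unique(cl$membership$representative_id), "A")

  set.seed(10)
  r2 <- protein_records(paste0("D", 1:6), random_protein(6, 30))
  cl2 <- cluster_greedy(r2, cluster_config(identity_threshold = 1.0))
  expect_equal(nrow(cl2$representatives), 6)

  fam <- generate_family_clusters(k = 5, m = 10, rate = 0.05,
                                  seq_length = 200, seed = 12)
  cl3 <- cluster_greedy(fam$records, cluster_config(0.85))
  expect_equal(nrow(cl3$representatives), 5)
  # membership must match planted families exactly
  pred <- cl3$membership$representative_id[
    match(fam$labels$protein_id, cl3$membership$protein_id)]
  expect_equal(length(unique(paste(pred, fam$labels$family))), 5)
  # every member satisfies the threshold against its representative
  seqs <- setNames(fam$records$sequence, fam$records$protein_id)
  idt <- mapply(function(m, rp)
    global_identity(seqs[[m]], seqs[[rp]], "shorter"),
    cl3$membership$protein_id, cl3$membership$representative_id)
  expect_true(all(idt >= 0.85))
})

test_that("characterized proteins survive clustering or are rescued", {
  set.seed(13)
  base <- random_protein(1, 100)
  r <- protein_records(c("R1", "C1"), c(base, mutate_sequence(base, 5)))
  cl <- cluster_greedy(r)
  expect_equal(nrow(cl$representatives), 1)
  rc <- retain_characterized(cl$representatives, r, "C1")
  expect_true("C1" %in% rc$records$protein_id)
  expect_equal(rc$log$action, "re-added")

  # missing characterized protein with a close pool hit: substituted
  ext <- protein_records("CX", base)
  pool <- protein_records("H1", mutate_sequence(base, 3))  # sim 0.97
  rc2 <- retain_characterized(cl$representatives, r, "CX",
                              rescue_pool = pool,
                              characterized_seqs = ext)
  expect_equal(rc2$log$action, "substituted")
  expect_true("H1" %in% rc2$records$protein_id)

  # best hit below the default 0.95: warning-style unrescued log
  pool2 <- protein_records("H2", mutate_sequence(base, 10))  # sim 0.90
  rc3 <- retain_characterized(cl$representatives, r, "CX",
                              rescue_pool = pool2,
                              characterized_seqs = ext)
  expect_equal(rc3$log$action, "unrescued")
  expect_false("H2" %in% rc3$records$protein_id)
})
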