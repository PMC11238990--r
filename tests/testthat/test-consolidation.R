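cfg <- consolidation_config()

test_that("overlap fraction counts 1-based inclusive positions", {
  expect_equal(overlap_fraction(10, 100, 50, 120), 51 / 71)
  expect_equal(overlap_fraction(10, 50, 60, 100), 0)
  expect_equal(overlap_fraction(10, 50, 10, 50), 1)
  # containment always scores 1 with the shorter-span denominator
  expect_equal(overlap_fraction(1, 500, 100, 150), 1)
  # symmetry
  expect_equal(overlap_fraction(10, 100, 50, 120),
               overlap_fraction(50, 120, 10, 100))
})

test_that("eligibility applies the name, signal and size rules", {
  ann <- raw_annotations(
    protein_id = rep("P", 6),
    source_db = c("Pfam", "Pfam", "PHOBIUS", "CDD", "SMART", "Pfam"),
    accession = paste0("A", 1:6),
    name = c("None", "SIGNAL_PEPTIDE_xxx", "TM_region", "Fine",
             "AlsoFine", "Big"),
    start = c(1, 1, 1, 10, 10, 1),
    end = c(50, 22, 30, 630, 19, 900))
  e <- is_eligible(ann, cfg)
  expect_equal(e$eligible, c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(e$reason[c(1, 2, 3, 6)],
               c("missing-name", "signal-peptide", "signal-peptide",
                 "size-window"))
  # span of 621 AA is eligible (within the 10-800 window); 900 is not
  expect_equal(e$reason[4], "")
  # signal marker is case-sensitive
  ann2 <- raw_annotations("P", "Pfam", "A7", "signal_receiver_domain",
                          10, 100)
  expect_true(is_eligible(ann2, cfg)$eligible)
})

test_that("curation renames and logs every substitution", {
  ann <- raw_annotations(rep("P", 3), rep("Pfam", 3), paste0("A", 1:3),
                         c("Glyco_hydro_48", "Cellulase_48", "Other"),
                         c(1, 10, 400), c(300, 320, 500))
  map <- curation_map(c(Glyco_hydro_48 = "Catalytic domain",
                        Cellulase_48 = "Catalytic domain"))
  out <- apply_curation(ann, map)
  expect_equal(out$annotations$name,
               c("Catalytic domain", "Catalytic domain", "Other"))
  expect_equal(nrow(out$map$applied_log), 2)
  expect_equal(out$map$applied_log$raw_name,
               c("Glyco_hydro_48", "Cellulase_48"))
  # empty map is the identity
  out2 <- apply_curation(ann, curation_map())
  expect_equal(out2$annotations$name, ann$name)
  expect_equal(nrow(out2$map$applied_log), 0)
  # non-functional map is rejected
  expect_error(curation_map(c(a = "X", a = "Y")), "functional")
})

test_that("split same-name calls merge to outermost edges; repeats survive", {
  ann <- raw_annotations(rep("P", 2), c("Pfam", "SUPERFAMILY"),
                         c("A1", "A2"), rep("Catalytic domain", 2),
                         c(5, 150), c(200, 350))
  m <- merge_same_name(ann)
  expect_equal(nrow(m$annotations), 1)
  expect_equal(m$annotations$start, 5L)
  expect_equal(m$annotations$end, 350L)
  expect_equal(m$n_merged_away, 1L)
  expect_equal(m$annotations$source_db, "Pfam;SUPERFAMILY")

  disj <- raw_annotations(rep("P", 2), c("Pfam", "Pfam"), c("B1", "B2"),
                          rep("CBM", 2), c(10, 300), c(60, 350))
  expect_equal(nrow(merge_same_name(disj)$annotations), 2)

  chain <- raw_annotations(rep("P", 3), rep("Pfam", 3), paste0("C", 1:3),
                           rep("X", 3), c(1, 40, 80), c(50, 90, 130))
  mc <- merge_same_name(chain)
  expect_equal(nrow(mc$annotations), 1)
  expect_equal(c(mc$annotations$start, mc$annotations$end), c(1L, 130L))
})

test_that("overlap resolution prefers the configured database order", {
  ann <- raw_annotations(rep("P", 2), c("SUPERFAMILY", "Pfam"),
                         c("S1", "F1"), c("DomA", "DomB"),
                         c(10, 30), c(100, 110))
  res <- resolve_overlaps(ann, cfg)
  expect_equal(nrow(res$calls), 1)
  expect_equal(res$calls$name, "DomB")  # Pfam outranks SUPERFAMILY
  expect_equal(res$dropped$accession, "S1")

  below <- raw_annotations(rep("P", 2), c("Pfam", "CDD"), c("F1", "C1"),
                           c("DomA", "DomB"), c(1, 90), c(100, 200))
  # overlap 11/100 = 0.11 <= 0.31: both kept
  expect_equal(nrow(resolve_overlaps(below, cfg)$calls), 2)
})

test_that("iterative resolution equals the exhaustive-order fixpoint", {
  set.seed(14)
  for (i in 1:120) {
    df <- rand_resolve_instance()
    fx <- oracle_fixpoints(df, cfg)
    expect_length(fx, 1)
    res <- resolve_overlaps(df, cfg)
    expect_equal(sort(unlist(res$calls$accessions)),
                 sort(df$accession[fx[[1]]]))
  }
})

test_that("consolidate runs the full pipeline on a redundant fixture", {
  # one CBM + one Ig-like + one catalytic domain, each reported by three
  # databases, plus a signal peptide: exactly three calls in N->C order
  mk <- function(db, acc, nm, s, e)
    data.frame(protein_id = "P", source_db = db, accession = acc,
               name = nm, start = s, end = e, stringsAsFactors = FALSE)
  ann <- do.call(rbind, list(
    mk("PHOBIUS", "PH1", "SIGNAL_PEPTIDE", 1, 22),
    mk("Pfam", "F1", "CBM_2", 30, 130),
    mk("SMART", "S1", "CBM_smart", 35, 128),
    mk("SUPERFAMILY", "U1", "CBM_sf", 28, 135),
    mk("Pfam", "F2", "Ig_like", 150, 240),
    mk("CDD", "C1", "Ig_cdd", 155, 245),
    mk("SMART", "S2", "Ig_smart", 148, 238),
    mk("Pfam", "F3", "Glyco_hydro_48", 260, 700),
    mk("CDD", "C2", "GH48_cdd", 265, 705),
    mk("SUPERFAMILY", "U2", "GH48_sf", 255, 695)))
  class(ann) <- c("raw_annotations", "data.frame")
  map <- curation_map(c(CBM_2 = "CBM", CBM_smart = "CBM", CBM_sf = "CBM",
                        Ig_like = "Immunoglobulin-like",
                        Ig_cdd = "Immunoglobulin-like",
                        Ig_smart = "Immunoglobulin-like",
                        Glyco_hydro_48 = "Catalytic domain",
                        GH48_cdd = "Catalytic domain",
                        GH48_sf = "Catalytic domain"))
  res <- consolidate("P", ann, map)
  expect_equal(res$calls$name,
               c("CBM", "Immunoglobulin-like", "Catalytic domain"))
  # same-name merge happened first: outermost edges, all sources united
  expect_equal(res$calls$start, c(28L, 148L, 255L))
  expect_equal(res$calls$end, c(135L, 245L, 705L))
  # count conservation: raw = retained + dropped + merged-away
  expect_equal(nrow(ann),
               nrow(res$calls) + nrow(res$dropped) + res$n_merged_away)

  # all-ineligible input flags the protein domainless
  bad <- mk("PHOBIUS", "PH9", "SIGNAL_PEPTIDE", 1, 20)
  class(bad) <- c("raw_annotations", "data.frame")
  res2 <- consolidate("P", bad)
  expect_equal(nrow(res2$calls), 0)

  # single eligible annotation passes through unchanged
  one <- mk("Pfam", "F9", "DomZ", 10, 200)
  class(one) <- c("raw_annotations", "data.frame")
  res3 <- consolidate("P", one)
  expect_equal(res3$calls$name, "DomZ")
  expect_equal(c(res3$calls$start, res3$calls$end), c(10L, 200L))
})

test_that("consolidation is deterministic and size-monotone", {
  set.seed(15)
  fix <- generate_fixture(fixture_spec(
    seed = 15, n_proteins = 20,
    architecture_pool = default_architecture_pool(n_novel = 8)))
  a <- consolidate_all(fix$records$protein_id, fix$annotations,
                       fix$curation)
  b <- consolidate_all(fix$records$protein_id, fix$annotations,
                       fix$curation)
  expect_identical(a$calls, b$calls)

  # raising max_domain_size never decreases the retained count
  pid <- fix$records$protein_id[1]
  sub <- fix$annotations[fix$annotations$protein_id == pid, , drop = FALSE]
  n_small <- nrow(consolidate(pid, sub, fix$curation,
                              consolidation_config(max_domain_size = 150))$calls)
  n_big <- nrow(consolidate(pid, sub, fix$curation,
                            consolidation_config(max_domain_size = 800))$calls)
  expect_gte(n_big, n_small)
})
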