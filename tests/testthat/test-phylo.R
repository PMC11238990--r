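make_tree_fixture <- function(n = 5, n_domainless = 1, seed = 20) {
  set.seed(seed)
  recs <- protein_records(sprintf("T%02d", 1:n), random_protein(n, 300),
                          characterized = c(TRUE, rep(FALSE, n - 1)),
                          ec_numbers = c(list("3.2.1.176"),
                                         rep(list(character()), n - 1)))
  with_domains <- recs$protein_id[seq_len(n - n_domainless)]
  calls <- do.call(rbind, lapply(with_domains, function(pid)
    domain_calls(rep(pid, 2), c("CBM", "Catalytic domain"),
                 c(10L, 150L), c(100L, 290L))))
  class(calls) <- c("domain_calls", "data.frame")
  list(records = recs, calls = calls)
}

test_that("domainless proteins are excluded from tree inputs", {
  fx <- make_tree_fixture(5, 1)
  sel <- select_tree_inputs(fx$records, fx$calls)
  expect_equal(nrow(sel$kept), 4)
  expect_equal(sel$excluded$protein_id, "T05")
  # none domainless: identity
  sel2 <- select_tree_inputs(fx$records[1:4, ], fx$calls)
  expect_equal(sel2$kept, fx$records[1:4, ])
  # all domainless: empty with a warning
  expect_warning(sel3 <- select_tree_inputs(fx$records,
                                            empty_domain_calls()),
                 "no protein")
  expect_equal(nrow(sel3$kept), 0)
})

test_that("stub adapters honour the MSA and tree contracts", {
  recs <- protein_records(c("A", "B"), c("MKVAW", "MKV"))
  aln <- run_msa(recs, stub_msa_adapter())
  expect_equal(unique(nchar(aln)), 5)
  expect_equal(sub("-+$", "", aln[["B"]]), "MKV")
  tb <- run_tree(aln, stub_tree_adapter())
  expect_equal(sort(tb$included_ids), c("A", "B"))
  expect_equal(tb$newick, "(A,B);")
  expect_s3_class(tb$tree, "phylo")

  # leaf-set mismatch is an error
  broken <- function(alignment) "(A,C);"
  expect_error(run_tree(aln, broken), "leaf set")
})

test_that("activity picking uses dotted integer tuple order", {
  expect_equal(pick_activity("3.2.1.4"), list(ec = "3.2.1.4",
                                              warned = FALSE))
  expect_warning(p <- pick_activity(c("3.2.1.176", "3.2.1.4")),
                 "multiple activities")
  expect_equal(p$ec, "3.2.1.4")  # (3,2,1,4) < (3,2,1,176)
  expect_true(p$warned)
  expect_equal(pick_activity(character()),
               list(ec = NA_character_, warned = FALSE))
  expect_warning(p2 <- pick_activity(c("3.2.1.-", "3.2.1.14")))
  expect_equal(p2$ec, "3.2.1.14")  # '-' sorts after any serial
})

test_that("iTOL domain file is valid, in-bounds and byte-deterministic", {
  fx <- make_tree_fixture(6, 0)
  sel <- select_tree_inputs(fx$records, fx$calls)
  aln <- run_msa(sel$kept)
  tb <- run_tree(aln, excluded_ids = character())
  style <- default_style_map(unique(fx$calls$name), "3.2.1.176")
  f1 <- withr::local_tempfile(fileext = ".txt")
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_itol_domains(tb, sel$kept, fx$calls, style, f1)
  expect_length(validate_itol_domains(f1), 0)
  lines <- readLines(f1)
  data_lines <- lines[(match("DATA", lines) + 1):length(lines)]
  expect_length(data_lines, length(tb$included_ids))
  # two shape fields per leaf, in start order
  expect_true(all(grepl("\\|10\\|100\\|.*\\|150\\|290\\|", data_lines)))
  write_itol_domains(tb, sel$kept, fx$calls, style, f2)
  expect_identical(readLines(f1), readLines(f2))

  # a leaf without a record is an error
  expect_error(write_itol_domains(tb, sel$kept[-1, ], fx$calls, style, f2),
               "leaf without")

  # corrupted files are rejected by the validator
  writeLines(sub("^DATASET_DOMAINS$", "DATASET_WRONG", lines), f2)
  expect_gt(length(validate_itol_domains(f2)), 0)
  writeLines(sub("RE\\|", "QQ|", lines), f2)
  expect_gt(length(validate_itol_domains(f2)), 0)
})

test_that("label colours cover exactly the characterized leaves", {
  set.seed(22)
  n <- 30
  char <- c(rep(TRUE, 7), rep(FALSE, n - 7))
  recs <- protein_records(sprintf("L%02d", 1:n), random_protein(n, 100),
                          characterized = char,
                          ec_numbers = lapply(char, function(ch)
                            if (ch) sample(c("3.2.1.4", "3.2.1.14",
                                             "3.2.1.91", "3.2.1.176"), 1)
                            else character()))
  calls <- do.call(rbind, lapply(recs$protein_id, function(pid)
    domain_calls(pid, "Catalytic domain", 5L, 95L)))
  class(calls) <- c("domain_calls", "data.frame")
  tb <- run_tree(run_msa(recs), stub_tree_adapter())
  style <- default_style_map("Catalytic domain",
                             unique(unlist(recs$ec_numbers)))
  f <- withr::local_tempfile(fileext = ".txt")
  write_itol_labelcolors(tb, recs, style, f)
  expect_length(validate_itol_treecolors(f), 0)
  lines <- readLines(f)
  expect_equal(length(lines) - match("DATA", lines), 7)

  # zero characterized: header-only file
  recs2 <- protein_records(c("A", "B"), random_protein(2, 50))
  tb2 <- run_tree(run_msa(recs2), stub_tree_adapter())
  write_itol_labelcolors(tb2, recs2, style, f)
  expect_equal(readLines(f), c("TREE_COLORS", "SEPARATOR SPACE", "DATA"))
})

test_that("style maps are injective and stable", {
  nm <- paste0("D", 1:10)
  s1 <- default_style_map(nm, c("3.2.1.4", "1.1.1.1"))
  s2 <- default_style_map(rev(nm), c("1.1.1.1", "3.2.1.4"))
  expect_identical(s1, s2)  # seeded by sorted name order
  expect_false(anyDuplicated(paste(s1$domains$shape,
                                   s1$domains$color)) > 0)
  expect_false(anyDuplicated(s1$ec_colors) > 0)
  expect_equal(unname(s1$ec_colors["3.2.1.4"]), "#ffcc00")
})
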