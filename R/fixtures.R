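# Seeded synthetic data with known ground truth: proteins carrying planted
# domain architectures, redundant multi-database annotations with bounded
# boundary jitter, signal-peptide / unnamed / off-size decoys, characterized
# tables and presence lists.  Everything every other module needs, offline.

#' Fixture specification
#'
#' Defines the synthetic dataset.  The boundary jitter is bounded
#' analytically: two hits of a region of length `L`, each edge jittered by
#' at most `j * L`, overlap by at least `(1 - 2j) / (1 + 2j)` of the
#' shorter hit, so requiring that bound to exceed `overlap_threshold`
#' guarantees that redundant same-domain hits always conflict and are
#' consolidated into a single call.  For the default threshold 0.31 this
#' requires `j < 0.2634`; the default is 0.10.  Outward jitter is further
#' clamped to less than half the flanking linker, so hits of adjacent
#' distinct domains never touch.
#'
#' @param seed Integer RNG seed.
#' @param n_proteins Number of proteins; must be at least the pool size
#'   when `ensure_coverage` is set.
#' @param architecture_pool List of character vectors (ordered domain
#'   names); default [default_architecture_pool()].
#' @param known Logical vector marking pool entries whose members may be
#'   characterized.
#' @param weights Sampling weights over the pool.
#' @param domain_length_range,linker_length_range Integer ranges in amino
#'   acids.
#' @param n_sources_per_domain Redundant source databases per true domain.
#' @param boundary_jitter Fraction of domain length.
#' @param decoy_rates Named numeric rates in `[0, 1]` for per-protein decoy
#'   annotations: `signal`, `none`, `oversized`, `undersized`.
#' @param overlap_threshold Threshold the jitter bound must beat.
#' @param ensure_coverage Assign each pool architecture to at least one
#'   protein (pool entry `i` to protein `i`) before weighted sampling.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_proteins = 50L,
                         architecture_pool = default_architecture_pool(),
                         known = NULL, weights = NULL,
                         domain_length_range = c(60L, 300L),
                         linker_length_range = c(10L, 30L),
                         n_sources_per_domain = 3L,
                         boundary_jitter = 0.10,
                         decoy_rates = c(signal = 0.3, none = 0.2,
                                         oversized = 0.1, undersized = 0.2),
                         overlap_threshold = 0.31,
                         ensure_coverage = TRUE) {
  pool <- architecture_pool$pool %||% architecture_pool
  if (is.null(known)) known <- architecture_pool$known %||%
      rep(FALSE, length(pool))
  weights <- weights %||% rep(1, length(pool))
  stopifnot(length(known) == length(pool),
            length(weights) == length(pool),
            all(decoy_rates >= 0), all(decoy_rates <= 1),
            n_sources_per_domain >= 1)
  j_max <- (1 - overlap_threshold) / (2 * (1 + overlap_threshold))
  if (boundary_jitter >= j_max)
    stop(sprintf(paste0("boundary_jitter %.3f breaks the recovery ",
                        "guarantee: must be < %.4f for threshold %.2f"),
                 boundary_jitter, j_max, overlap_threshold))
  if (ensure_coverage && n_proteins < length(pool))
    stop("n_proteins must be >= pool size when ensure_coverage is set")
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 pool = pool, known = known, weights = weights,
                 domain_length_range = as.integer(domain_length_range),
                 linker_length_range = as.integer(linker_length_range),
                 n_sources_per_domain = as.integer(n_sources_per_domain),
                 boundary_jitter = boundary_jitter,
                 decoy_rates = decoy_rates,
                 overlap_threshold = overlap_threshold,
                 ensure_coverage = ensure_coverage),
            class = "fixture_spec")
}

#' Default architecture pool
#'
#' Eight "known" multi-domain architectures typical of a glycoside
#' hydrolase family (single catalytic domains, carbohydrate-binding
#' modules, immunoglobulin-like linker domains, dockerins) plus
#' deterministically enumerated novel combinations.
#'
#' @param n_novel Number of additional novel architectures, default 27.
#' @return List with `pool` (list of name vectors) and `known` (logical).
#' @export
default_architecture_pool <- function(n_novel = 27L) {
  known <- list(
    c("Catalytic domain"),
    c("Catalytic domain", "CBM"),
    c("Catalytic domain", "Dockerin"),
    c("Catalytic domain", "Immunoglobulin-like", "CBM"),
    c("CBM", "Immunoglobulin-like", "Catalytic domain"),
    c("Catalytic domain", "Immunoglobulin-like", "Immunoglobulin-like",
      "CBM"),
    c("Catalytic domain", "Immunoglobulin-like", "Immunoglobulin-like",
      "Immunoglobulin-like", "CBM"),
    c("Catalytic domain", "CBM", "CBM", "CBM", "Catalytic domain")
  )
  alphabet <- c("Catalytic domain", "CBM", "Immunoglobulin-like",
                "Dockerin", "Sialidase", "Lectin", "CotH kinase")
  seen <- vapply(known, paste, "", collapse = " + ")
  novel <- list()
  # fixed enumeration order: all length-1, then length-2, ... combinations
  for (len in 1:4) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len),
                      list(stringsAsFactors = FALSE)))
    for (r in seq_len(nrow(grid))) {
      cand <- as.character(unlist(grid[r, ]))
      key <- paste(cand, collapse = " + ")
      if (!(key %in% seen)) {
        novel[[length(novel) + 1L]] <- cand
        seen <- c(seen, key)
      }
      if (length(novel) >= n_novel) break
    }
    if (length(novel) >= n_novel) break
  }
  list(pool = c(known, novel),
       known = c(rep(TRUE, length(known)), rep(FALSE, length(novel))))
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE),
                               collapse = "")

#' Substitute residues at a fixed number of positions
#'
#' Exactly `n_sub` distinct positions are replaced by a different residue,
#' so the mutant differs from the input at exactly `n_sub` positions.
#'
#' @param sequence Amino-acid string.
#' @param n_sub Number of substitutions.
#' @return Mutated sequence.
#' @export
mutate_sequence <- function(sequence, n_sub) {
  ch <- strsplit(sequence, "")[[1]]
  n_sub <- min(n_sub, length(ch))
  if (n_sub == 0) return(sequence)
  pos <- sample(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  paste(ch, collapse = "")
}

#' Generate a synthetic annotated protein family
#'
#' Deterministic for a fixed seed.  Each protein carries an architecture
#' from the pool; every true domain is reported by
#' `n_sources_per_domain` distinct source databases under database-specific
#' raw signature names with bounded boundary jitter; decoy annotations
#' (signal peptides, unnamed hits, off-size spans) are added at the
#' configured rates.  The generated curation map translates every raw name
#' back to its overarching domain name, and the ground truth records each
#' protein's planted architecture and exact boundaries.  By construction
#' (see [fixture_spec()]) consolidation recovers the planted architecture
#' of every protein.
#'
#' @param spec A [fixture_spec()].
#' @return List with `records` (`protein_records`), `annotations`
#'   (`raw_annotations`), `characterized` (named list id -> ECs),
#'   `presence_ids`, `curation` ([curation_map()]), `truth` (list with
#'   `architectures` data frame and `calls` `domain_calls`).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  npool <- length(spec$pool)
  arch_idx <- integer(spec$n_proteins)
  if (spec$ensure_coverage) {
    arch_idx[seq_len(npool)] <- seq_len(npool)
    extra <- spec$n_proteins - npool
    if (extra > 0)
      arch_idx[npool + seq_len(extra)] <-
        sample(npool, extra, replace = TRUE, prob = spec$weights)
  } else {
    arch_idx <- sample(npool, spec$n_proteins, replace = TRUE,
                       prob = spec$weights)
  }

  domain_names <- sort(unique(unlist(spec$pool)))
  dbs <- setdiff(SOURCE_DATABASES, "PHOBIUS")
  raw_name <- function(nm, db)
    paste0(gsub("[^A-Za-z0-9]+", "_", nm), "_",
           gsub("[^A-Za-z0-9]+", "", db))
  map_entries <- character()
  for (nm in domain_names)
    for (db in dbs)
      map_entries[raw_name(nm, db)] <- nm

  ecs_pool <- c("3.2.1.4", "3.2.1.14", "3.2.1.91", "3.2.1.176")
  ids <- sprintf("SYN%04d.1", seq_len(spec$n_proteins))
  sequences <- character(spec$n_proteins)
  characterized <- list()
  char_flag <- logical(spec$n_proteins)
  ec_list <- rep(list(character()), spec$n_proteins)
  ann <- list()
  truth_calls <- list()
  dlr <- spec$domain_length_range
  llr <- spec$linker_length_range
  j <- spec$boundary_jitter
  seen_known <- logical(npool)

  for (p in seq_len(spec$n_proteins)) {
    arch <- spec$pool[[arch_idx[p]]]
    k <- length(arch)
    dlen <- sample(seq(dlr[1], dlr[2]), k, replace = TRUE)
    # linkers: before, between and after the domains
    gaps <- sample(seq(llr[1], llr[2]), k + 1, replace = TRUE)
    starts <- integer(k); ends <- integer(k)
    pos <- gaps[1]
    for (d in seq_len(k)) {
      starts[d] <- pos + 1L
      ends[d] <- pos + dlen[d]
      pos <- ends[d] + gaps[d + 1]
    }
    plen <- pos
    sequences[p] <- random_aa(plen)

    for (d in seq_len(k)) {
      L <- dlen[d]
      jl <- floor(j * L)
      out_left <- min(jl, max((gaps[d] - 1L) %/% 2L, 0L))
      out_right <- min(jl, max((gaps[d + 1] - 1L) %/% 2L, 0L))
      src <- sample(dbs, spec$n_sources_per_domain)
      for (s in src) {
        hs <- starts[d] + sample.int(out_left + jl + 1L, 1L) - out_left - 1L
        he <- ends[d] + sample.int(out_right + jl + 1L, 1L) - jl - 1L
        stopifnot(hs <= he)
        ov <- overlap_fraction(hs, he, starts[d], ends[d])
        stopifnot(ov > spec$overlap_threshold)
        ann[[length(ann) + 1L]] <- data.frame(
          protein_id = ids[p], source_db = s,
          accession = sprintf("%s%05d",
                              toupper(substr(gsub("[^A-Za-z]", "", s), 1, 2)),
                              length(ann) + 1L),
          name = raw_name(arch[d], s),
          start = hs, end = he, stringsAsFactors = FALSE)
      }
    }
    truth_calls[[p]] <- data.frame(protein_id = rep(ids[p], k), name = arch,
                                   start = starts, end = ends,
                                   stringsAsFactors = FALSE)

    # decoys
    dr <- spec$decoy_rates
    if (runif(1) < (dr["signal"] %||% 0)) {
      ann[[length(ann) + 1L]] <- data.frame(
        protein_id = ids[p], source_db = "PHOBIUS",
        accession = sprintf("PH%05d", length(ann) + 1L),
        name = "SIGNAL_PEPTIDE", start = 1L,
        end = min(22L, plen), stringsAsFactors = FALSE)
    }
    if (runif(1) < (dr["none"] %||% 0)) {
      s0 <- sample.int(max(plen - 40L, 1L), 1L)
      ann[[length(ann) + 1L]] <- data.frame(
        protein_id = ids[p], source_db = sample(dbs, 1),
        accession = sprintf("NN%05d", length(ann) + 1L),
        name = MISSING_NAME, start = s0,
        end = min(s0 + 39L, plen), stringsAsFactors = FALSE)
    }
    if (runif(1) < (dr["oversized"] %||% 0)) {
      if (plen > 800L) {
        ann[[length(ann) + 1L]] <- data.frame(
          protein_id = ids[p], source_db = sample(dbs, 1),
          accession = sprintf("OV%05d", length(ann) + 1L),
          name = "Multidomain_span", start = 1L, end = plen,
          stringsAsFactors = FALSE)
      } else {
        ann[[length(ann) + 1L]] <- data.frame(
          protein_id = ids[p], source_db = sample(dbs, 1),
          accession = sprintf("CS%05d", length(ann) + 1L),
          name = "Conserved_site", start = starts[1],
          end = starts[1] + 4L, stringsAsFactors = FALSE)
      }
    }
    if (runif(1) < (dr["undersized"] %||% 0)) {
      s0 <- sample.int(plen - 5L, 1L)
      ann[[length(ann) + 1L]] <- data.frame(
        protein_id = ids[p], source_db = sample(dbs, 1),
        accession = sprintf("US%05d", length(ann) + 1L),
        name = "Active_site_motif", start = s0, end = s0 + 4L,
        stringsAsFactors = FALSE)
    }

    if (spec$known[arch_idx[p]] && !seen_known[arch_idx[p]]) {
      seen_known[arch_idx[p]] <- TRUE
      char_flag[p] <- TRUE
      ec_list[[p]] <- sort(sample(ecs_pool, sample(1:2, 1)))
      characterized[[ids[p]]] <- ec_list[[p]]
    }
  }

  records <- protein_records(ids, sequences,
                             description = "synthetic protein",
                             taxonomy_group = sample(
                               c("Bacteria", "Eukaryota", "Archaea"),
                               spec$n_proteins, replace = TRUE,
                               prob = c(0.8, 0.15, 0.05)),
                             characterized = char_flag,
                             ec_numbers = ec_list)
  annotations <- do.call(rbind, ann)
  class(annotations) <- c("raw_annotations", "data.frame")
  tc <- do.call(rbind, truth_calls)
  truth_arch <- data.frame(
    protein_id = ids,
    architecture = vapply(spec$pool[arch_idx], paste, "", collapse = " + "),
    stringsAsFactors = FALSE)
  list(records = records, annotations = annotations,
       characterized = characterized, presence_ids = ids,
       curation = curation_map(map_entries),
       truth = list(architectures = truth_arch, calls = tc))
}

#' Write a fixture to disk in the package's external dialects
#'
#' Produces `records.fasta`, `annotations.tsv`, `characterized.tsv`,
#' `presence.txt`, `curation.tsv` and `truth.tsv` under `dir`.  Output is
#' byte-deterministic for a fixed spec.
#'
#' @param fixture Output of [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.fasta"),
             annotations = file.path(dir, "annotations.tsv"),
             characterized = file.path(dir, "characterized.tsv"),
             presence = file.path(dir, "presence.txt"),
             curation = file.path(dir, "curation.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(fixture$records, paths["records"])
  write.table(as.data.frame(fixture$annotations), paths["annotations"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  chr <- data.frame(protein_id = names(fixture$characterized),
                    ecs = vapply(fixture$characterized, paste, "",
                                 collapse = ";"))
  write.table(chr, paths["characterized"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(fixture$presence_ids, paths["presence"])
  write.table(data.frame(raw = names(fixture$curation$entries),
                         curated = unname(fixture$curation$entries)),
              paths["curation"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(fixture$truth$architectures, paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths
}

#' Generate mutation families for clustering tests
#'
#' `k` random seed sequences are each expanded into `m` mutants carrying
#' exactly `round(rate * length)` substitutions, so two members of one
#' family differ at no more than twice that many positions (identity at
#' least `1 - 2 * rate`), while unrelated random sequences stay far below
#' usual clustering thresholds.
#'
#' @param k Number of families.
#' @param m Mutants per family (the seed sequence itself is not included).
#' @param rate Substitution fraction.
#' @param seq_length Length of every sequence.
#' @param seed RNG seed.
#' @return List with `records` (`protein_records`) and `labels` (data
#'   frame `protein_id`, `family`).
#' @export
generate_family_clusters <- function(k = 5L, m = 10L, rate = 0.05,
                                     seq_length = 300L, seed = 1L) {
  set.seed(seed)
  ids <- character(); seqs <- character(); fam <- integer()
  for (f in seq_len(k)) {
    seed_seq <- random_aa(seq_length)
    for (j in seq_len(m)) {
      ids <- c(ids, sprintf("FAM%02d_M%02d", f, j))
      seqs <- c(seqs, mutate_sequence(seed_seq,
                                      round(rate * seq_length)))
      fam <- c(fam, f)
    }
  }
  list(records = protein_records(ids, seqs),
       labels = data.frame(protein_id = ids, family = fam,
                           stringsAsFactors = FALSE))
}

#' Generate groups of homologous domain peptides at planted divergence
#'
#' One random ancestor domain per call; each group member carries exactly
#' `round(rate_g * length)` substitutions from the ancestor, planting a
#' known level of within-group divergence for statistical tests.
#'
#' @param sizes Integer vector of group sizes.
#' @param rates Substitution fractions per group (parallel to `sizes`).
#' @param length Domain length.
#' @param seed RNG seed.
#' @return Named list of character vectors of peptides.
#' @export
generate_domain_groups <- function(sizes, rates, length = 300L, seed = 1L) {
  stopifnot(base::length(sizes) == base::length(rates))
  set.seed(seed)
  nm <- names(sizes) %||% paste0("group", seq_along(sizes))
  out <- vector("list", base::length(sizes))
  names(out) <- nm
  for (g in seq_along(sizes)) {
    anc <- random_aa(length)
    out[[g]] <- vapply(seq_len(sizes[g]), function(i)
      mutate_sequence(anc, round(rates[g] * length)), "")
  }
  out
}
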