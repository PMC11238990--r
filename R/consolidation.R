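#' Consolidation configuration
#'
#' Controls the annotation cleanup: eligibility rules (valid name, no signal
#' peptide, size window) and the iterative overlap resolution (threshold and
#' database preference).
#'
#' @param overlap_threshold Two hits are considered the same region when
#'   their overlap exceeds this fraction of the shorter span; default 0.31.
#' @param min_domain_size,max_domain_size Size window in amino acids,
#'   default 10 and 800; spans outside are filtered (conserved sites,
#'   multi-domain super-annotations).
#' @param db_priority Ordered database preference, first = most preferred;
#'   default [DEFAULT_DB_PRIORITY].  Databases absent from the list rank
#'   after all listed ones.
#' @param signal_markers Substrings identifying signal-peptide annotations
#'   by name (case-sensitive); default `"SIGNAL"`.
#' @param signal_sources Source databases whose hits are always treated as
#'   signal-peptide calls; default `"PHOBIUS"`.
#' @return A `consolidation_config` list.
#' @export
consolidation_config <- function(overlap_threshold = 0.31,
                                 min_domain_size = 10L,
                                 max_domain_size = 800L,
                                 db_priority = DEFAULT_DB_PRIORITY,
                                 signal_markers = "SIGNAL",
                                 signal_sources = "PHOBIUS") {
  stopifnot(overlap_threshold >= 0, overlap_threshold <= 1,
            min_domain_size > 0, min_domain_size <= max_domain_size)
  structure(list(overlap_threshold = overlap_threshold,
                 min_domain_size = as.integer(min_domain_size),
                 max_domain_size = as.integer(max_domain_size),
                 db_priority = db_priority,
                 signal_markers = signal_markers,
                 signal_sources = signal_sources),
            class = "consolidation_config")
}

#' Domain-name curation map
#'
#' Maps raw signature names (which differ between source databases for the
#' same biological domain) to user-chosen overarching names.  Substitutions
#' actually applied are accumulated in the `applied_log`.
#'
#' @param entries Named character vector: `names(entries)` are raw names,
#'   values the curated names.
#' @return A `curation_map` object.
#' @export
curation_map <- function(entries = character()) {
  if (length(entries) && anyDuplicated(names(entries)))
    stop("curation map must be functional: duplicate raw name(s): ",
         paste(unique(names(entries)[duplicated(names(entries))]),
               collapse = ", "))
  structure(list(entries = entries,
                 applied_log = data.frame(raw_name = character(),
                                          curated_name = character(),
                                          stringsAsFactors = FALSE)),
            class = "curation_map")
}

#' Overlap fraction of two intervals
#'
#' Intersection length divided by the length of the shorter interval, all
#' counted 1-based inclusive; 0 when disjoint.  The shorter-span denominator
#' is conservative: full containment always scores 1.
#'
#' @param start1,end1,start2,end2 Interval bounds (vectorized).
#' @return Overlap fraction(s) in `[0, 1]`.
#' @examples
#' overlap_fraction(10, 100, 50, 120)  # 51/71
#' @export
overlap_fraction <- function(start1, end1, start2, end2) {
  inter <- pmin(end1, end2) - pmax(start1, start2) + 1
  inter <- pmax(inter, 0)
  shorter <- pmin(end1 - start1 + 1, end2 - start2 + 1)
  inter / shorter
}

#' Annotation eligibility (rules a-c)
#'
#' An annotation is ineligible when (a) its name is missing (`"None"` or
#' empty), (b) it encodes a signal peptide (name contains a signal marker,
#' or its source database is a signal source), or (c) its span length lies
#' outside the configured size window.
#'
#' @param anns A `raw_annotations` data frame.
#' @param config A [consolidation_config()].
#' @return Data frame with columns `eligible` (logical) and `reason`
#'   (`""`, `"missing-name"`, `"signal-peptide"`, `"size-window"`).
#' @export
is_eligible <- function(anns, config = consolidation_config()) {
  n <- nrow(anns)
  reason <- character(n)
  len <- anns$end - anns$start + 1L
  bad_name <- anns$name == MISSING_NAME | !nzchar(anns$name) | is.na(anns$name)
  sig_name <- Reduce(`|`, lapply(config$signal_markers, function(m)
    grepl(m, anns$name, fixed = TRUE)), rep(FALSE, n))
  sig_src <- anns$source_db %in% config$signal_sources
  bad_size <- len < config$min_domain_size | len > config$max_domain_size
  reason[bad_size] <- "size-window"
  reason[sig_name | sig_src] <- "signal-peptide"
  reason[bad_name] <- "missing-name"
  data.frame(eligible = !nzchar(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Apply a curation map to annotation names
#'
#' Names present in the map are replaced by their overarching curated name;
#' every substitution is appended to the map's `applied_log` (which feeds
#' the `DomainCuration` store table).
#'
#' @param anns A `raw_annotations` data frame.
#' @param map A [curation_map()].
#' @return List with `annotations` (renamed) and `map` (with updated log).
#' @export
apply_curation <- function(anns, map = curation_map()) {
  hit <- anns$name %in% names(map$entries)
  if (any(hit)) {
    raw <- anns$name[hit]
    cur <- unname(map$entries[raw])
    map$applied_log <- rbind(map$applied_log,
                             data.frame(raw_name = raw, curated_name = cur,
                                        stringsAsFactors = FALSE))
    anns$name[hit] <- cur
  }
  list(annotations = anns, map = map)
}

#' Merge split same-name annotations
#'
#' Within one protein, annotations sharing a curated name whose spans form
#' an overlapping chain (connected components of the pairwise-overlap graph)
#' are replaced by a single annotation spanning the outermost positions,
#' with source databases and accessions unioned.  Disjoint same-name spans
#' are kept apart: repeat domains are real.
#'
#' @param anns Curated `raw_annotations` for one protein.
#' @return List with `annotations` (merged) and `n_merged_away` (count of
#'   rows absorbed into merged spans).
#' @export
merge_same_name <- function(anns) {
  if (nrow(anns) < 2)
    return(list(annotations = anns, n_merged_away = 0L))
  keep <- list()
  merged_away <- 0L
  for (nm in unique(anns$name)) {
    sub <- anns[anns$name == nm, , drop = FALSE]
    comp <- overlap_components(sub$start, sub$end)
    for (cid in unique(comp)) {
      grp <- sub[comp == cid, , drop = FALSE]
      row <- grp[1, , drop = FALSE]
      if (nrow(grp) > 1) {
        row$start <- min(grp$start)
        row$end <- max(grp$end)
        row$source_db <- paste(sort(unique(grp$source_db)), collapse = ";")
        row$accession <- paste(sort(unique(grp$accession)), collapse = ";")
        merged_away <- merged_away + nrow(grp) - 1L
      }
      keep[[length(keep) + 1L]] <- row
    }
  }
  out <- do.call(rbind, keep)
  out <- out[order(out$start, -out$end), , drop = FALSE]
  rownames(out) <- NULL
  list(annotations = out, n_merged_away = merged_away)
}

# Connected components of the interval-overlap graph (overlap > 0),
# via a sweep over start-sorted intervals.
overlap_components <- function(start, end) {
  n <- length(start)
  ord <- order(start, -end)
  comp <- integer(n)
  cur <- 0L
  max_end <- -Inf
  for (i in ord) {
    if (start[i] > max_end) cur <- cur + 1L
    comp[i] <- cur
    max_end <- max(max_end, end[i])
  }
  comp
}

# Rank of each annotation's best (most preferred) source database.
db_rank <- function(source_db, priority) {
  vapply(strsplit(source_db, ";", fixed = TRUE), function(dbs) {
    r <- match(dbs, priority)
    r[is.na(r)] <- length(priority) + 1L
    min(r)
  }, numeric(1))
}

# TRUE when annotation row a beats row b (strict total order):
# (1) better db priority, (2) longer span, (3) smaller start,
# (4) lexicographically smaller name, (5) smaller original index.
beats <- function(a, b) {
  if (a$rank != b$rank) return(a$rank < b$rank)
  la <- a$end - a$start; lb <- b$end - b$start
  if (la != lb) return(la > lb)
  if (a$start != b$start) return(a$start < b$start)
  if (a$name != b$name) return(a$name < b$name)
  a$.idx < b$.idx
}

#' Iterative overlap resolution
#'
#' Input annotations (eligible, curated, same-name-merged, one protein) are
#' sorted by start (ascending), end (descending), then database priority.
#' Repeatedly, the first adjacent pair in this order whose
#' [overlap_fraction()] exceeds the threshold is resolved by deleting the
#' loser; the winner has (1) the better database priority, (2) the longer
#' span, (3) the smaller start, (4) the lexicographically smaller name.
#' After the adjacent-pair fixpoint, a full pairwise sweep guarantees that
#' no retained pair exceeds the threshold.
#'
#' @param anns Annotations for one protein.
#' @param config A [consolidation_config()].
#' @return List with `calls` (a `domain_calls` data frame sorted by start)
#'   and `dropped` (data frame `accession`, `name`, `reason`).
#' @export
resolve_overlaps <- function(anns, config = consolidation_config()) {
  if (nrow(anns) == 0)
    return(list(calls = empty_domain_calls(), dropped = empty_drop_log()))
  anns$.idx <- seq_len(nrow(anns))
  anns$rank <- db_rank(anns$source_db, config$db_priority)
  dropped <- list()

  repeat {
    anns <- anns[order(anns$start, -anns$end, anns$rank, anns$.idx), ,
                 drop = FALSE]
    n <- nrow(anns)
    conflict <- NULL
    if (n >= 2) {
      # first adjacent pair above threshold
      ov <- overlap_fraction(anns$start[-n], anns$end[-n],
                             anns$start[-1], anns$end[-1])
      hit <- which(ov > config$overlap_threshold)
      if (length(hit)) {
        conflict <- c(hit[1], hit[1] + 1L)
      } else {
        # full sweep: non-adjacent conflicts can remain in rare geometries
        pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
        ov2 <- overlap_fraction(anns$start[pairs[, 1]], anns$end[pairs[, 1]],
                                anns$start[pairs[, 2]], anns$end[pairs[, 2]])
        hit2 <- which(ov2 > config$overlap_threshold)
        if (length(hit2)) conflict <- pairs[hit2[1], ]
      }
    }
    if (is.null(conflict)) break
    i <- conflict[1]; j <- conflict[2]
    loser <- if (beats(anns[i, ], anns[j, ])) j else i
    winner <- if (loser == i) j else i
    dropped[[length(dropped) + 1L]] <- data.frame(
      accession = anns$accession[loser],
      name = anns$name[loser],
      reason = sprintf("overlap-loser vs %s (%s)",
                       anns$name[winner], anns$accession[winner]),
      stringsAsFactors = FALSE)
    anns <- anns[-loser, , drop = FALSE]
  }

  anns <- anns[order(anns$start, -anns$end), , drop = FALSE]
  calls <- domain_calls(
    protein_id = anns$protein_id,
    name = anns$name,
    start = anns$start,
    end = anns$end,
    source_dbs = strsplit(anns$source_db, ";", fixed = TRUE),
    accessions = strsplit(anns$accession, ";", fixed = TRUE)
  )
  list(calls = calls,
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else empty_drop_log())
}

#' Construct a domain call table
#'
#' A retained, curated, possibly merged annotation: the unit of a protein's
#' final architecture.
#'
#' @param protein_id,name Character vectors.
#' @param start,end 1-based inclusive coordinates.
#' @param source_dbs,accessions Lists of character vectors (contributing
#'   databases / signature accessions).
#' @return A `data.frame` with class `domain_calls`.
#' @export
domain_calls <- function(protein_id = character(), name = character(),
                         start = integer(), end = integer(),
                         source_dbs = NULL, accessions = NULL) {
  n <- length(protein_id)
  df <- data.frame(protein_id = as.character(protein_id),
                   name = as.character(name),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  df$source_dbs <- source_dbs %||% rep(list(character()), n)
  df$accessions <- accessions %||% rep(list(character()), n)
  class(df) <- c("domain_calls", "data.frame")
  df
}

empty_domain_calls <- function() domain_calls()

empty_drop_log <- function()
  data.frame(accession = character(), name = character(),
             reason = character(), stringsAsFactors = FALSE)

#' Consolidate the annotations of one protein
#'
#' The full cleanup pipeline: name curation, eligibility filtering (rules
#' a-c), merging of split same-name calls to their outermost edges, then
#' iterative overlap resolution.  The result annotates each region with at
#' most one domain; no retained pair overlaps above the threshold.
#'
#' @param protein_id Protein identifier (all `raw_anns` must belong to it).
#' @param raw_anns A `raw_annotations` data frame.
#' @param map A [curation_map()].
#' @param config A [consolidation_config()].
#' @param protein_length Optional sequence length; when given, annotations
#'   exceeding it raise an error.
#' @return List with `calls` (`domain_calls`, N-to-C order), `dropped`
#'   (drop log with stage and reason), `n_merged_away`, and `map` (curation
#'   map with updated log).
#' @export
consolidate <- function(protein_id, raw_anns, map = curation_map(),
                        config = consolidation_config(),
                        protein_length = NULL) {
  if (nrow(raw_anns) && !all(raw_anns$protein_id == protein_id))
    stop("annotations for foreign protein(s): ",
         paste(setdiff(unique(raw_anns$protein_id), protein_id),
               collapse = ", "))
  if (!is.null(protein_length) && nrow(raw_anns) &&
      any(raw_anns$end > protein_length))
    stop("annotation exceeds sequence length of ", protein_id)

  cur <- apply_curation(raw_anns, map)
  anns <- cur$annotations

  elig <- is_eligible(anns, config)
  drop_elig <- if (any(!elig$eligible))
    data.frame(accession = anns$accession[!elig$eligible],
               name = anns$name[!elig$eligible],
               reason = elig$reason[!elig$eligible],
               stringsAsFactors = FALSE)
  else empty_drop_log()
  anns <- anns[elig$eligible, , drop = FALSE]

  merged <- merge_same_name(anns)
  res <- resolve_overlaps(merged$annotations, config)

  # post-condition: no retained pair above threshold
  cl <- res$calls
  if (nrow(cl) >= 2) {
    pr <- which(upper.tri(matrix(0, nrow(cl), nrow(cl))), arr.ind = TRUE)
    ov <- overlap_fraction(cl$start[pr[, 1]], cl$end[pr[, 1]],
                           cl$start[pr[, 2]], cl$end[pr[, 2]])
    stopifnot(all(ov <= config$overlap_threshold))
  }

  list(calls = res$calls,
       dropped = rbind(drop_elig, res$dropped),
       n_merged_away = merged$n_merged_away,
       map = cur$map)
}

#' Consolidate annotations for many proteins
#'
#' Vectorised driver over [consolidate()]: splits an annotation table by
#' protein and concatenates the per-protein results.  Proteins present in
#' `protein_ids` but lacking any retained call are reported as domainless.
#'
#' @param protein_ids Character vector of proteins to process.
#' @param raw_anns Annotations for all proteins.
#' @param map,config As in [consolidate()].
#' @return List with `calls`, `dropped` (with `protein_id` column),
#'   `domainless` (ids), and `map`.
#' @export
consolidate_all <- function(protein_ids, raw_anns, map = curation_map(),
                            config = consolidation_config()) {
  calls <- list(); dropped <- list()
  for (pid in protein_ids) {
    sub <- raw_anns[raw_anns$protein_id == pid, , drop = FALSE]
    res <- consolidate(pid, sub, map, config)
    map <- res$map
    calls[[pid]] <- res$calls
    if (nrow(res$dropped))
      dropped[[pid]] <- cbind(protein_id = pid, res$dropped)
  }
  all_calls <- do.call(rbind, calls)
  if (is.null(all_calls)) all_calls <- empty_domain_calls()
  rownames(all_calls) <- NULL
  class(all_calls) <- c("domain_calls", "data.frame")
  with_calls <- unique(all_calls$protein_id)
  list(calls = all_calls,
       dropped = if (length(dropped)) do.call(rbind, dropped)
                 else cbind(data.frame(protein_id = character()),
                            empty_drop_log()),
       domainless = setdiff(protein_ids, with_calls),
       map = map)
}
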