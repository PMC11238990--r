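#' Canonical architecture string of one protein
#'
#' Domain names ordered N-to-C (by start) joined with `" + "`.  An empty
#' call list yields the empty string (a domainless protein).
#'
#' @param calls A `domain_calls` data frame, all for one protein.
#' @param overlap_threshold Retained calls overlapping above this fraction
#'   indicate a violated consolidation contract and raise an error.
#' @return Single string.
#' @examples
#' calls <- domain_calls(rep("P", 2), c("CBM", "Catalytic domain"),
#'                       c(1L, 120L), c(100L, 700L))
#' architecture_string(calls)
#' @export
architecture_string <- function(calls, overlap_threshold = 0.31) {
  if (nrow(calls) == 0) return("")
  if (length(unique(calls$protein_id)) > 1)
    stop("calls must belong to a single protein")
  ord <- order(calls$start, -calls$end)
  if (nrow(calls) >= 2) {
    s <- calls$start[ord]; e <- calls$end[ord]
    n <- nrow(calls)
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ov <- overlap_fraction(s[pr[, 1]], e[pr[, 1]], s[pr[, 2]], e[pr[, 2]])
    if (any(ov > overlap_threshold))
      stop("calls of ", calls$protein_id[1],
           " overlap above threshold: consolidation contract violated")
  }
  paste(calls$name[ord], collapse = " + ")
}

#' Enumerate unique domain assemblies
#'
#' One row per distinct architecture string among proteins with at least
#' one domain call; member lists partition those proteins.  Sorted by
#' member count (descending), then architecture.
#'
#' @param calls A `domain_calls` data frame covering many proteins.
#' @param records Optional `protein_records` supplying taxonomy,
#'   characterized flags and EC numbers for the summary columns.
#' @return Data frame with columns `architecture`, `n_members`,
#'   `protein_ids` (list), `example_id`, `taxonomy` (list), `ec_set` (list).
#' @export
enumerate_assemblies <- function(calls, records = NULL) {
  if (nrow(calls) == 0)
    return(data.frame(architecture = character(), n_members = integer(),
                      example_id = character(), stringsAsFactors = FALSE))
  by <- split(calls, calls$protein_id)
  arch <- vapply(by, architecture_string, "")
  pids <- names(arch)
  groups <- split(pids, arch)
  groups <- lapply(groups, sort)
  out <- data.frame(architecture = names(groups),
                    n_members = lengths(groups),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$protein_ids <- unname(groups)
  out$example_id <- vapply(groups, `[[`, "", 1)
  if (!is.null(records)) {
    idx <- match(pids, records$protein_id)
    tax_of <- setNames(records$taxonomy_group[idx], pids)
    char_of <- setNames(records$characterized[idx], pids)
    ec_of <- setNames(records$ec_numbers[idx], pids)
    out$taxonomy <- lapply(out$protein_ids, function(g)
      sort(unique(unname(tax_of[g]))))
    out$ec_set <- lapply(out$protein_ids, function(g)
      sort(unique(unlist(ec_of[g[char_of[g] %in% TRUE]]))))
  } else {
    out$taxonomy <- rep(list(character()), nrow(out))
    out$ec_set <- rep(list(character()), nrow(out))
  }
  out <- out[order(-out$n_members, out$architecture), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribute query sequences to architectures by best-hit identity
#'
#' Each query is assigned the architecture of its best-identity
#' representative (identity = identical matches / query length) provided
#' that identity reaches `min_identity`; otherwise it is unassigned.
#' Prevalence of an architecture is its share of all queries.
#'
#' @param queries A `protein_records` data frame of sequences to attribute.
#' @param representatives A `protein_records` data frame (nonempty).
#' @param rep_architectures Character vector: architecture string of each
#'   representative (parallel to `representatives`).
#' @param min_identity Assignment cutoff, default 0.85 (the clustering
#'   threshold).
#' @return List with `assignments` (data frame `protein_id`,
#'   `architecture`, `best_representative`, `identity`; unassigned rows
#'   have `NA` architecture) and `prevalence` (data frame `architecture`,
#'   `n`, `prevalence` including an `(unassigned)` row when applicable).
#' @export
attribute_sequences <- function(queries, representatives, rep_architectures,
                                min_identity = 0.85) {
  stopifnot(nrow(representatives) >= 1,
            length(rep_architectures) == nrow(representatives))
  n <- nrow(queries)
  arch <- character(n); best_rep <- character(n); best_idt <- numeric(n)
  for (i in seq_len(n)) {
    q <- queries$sequence[i]
    st <- alignment_stats(rep(q, nrow(representatives)),
                          representatives$sequence)
    idt <- st$matches / nchar(q)
    b <- which.max(idt)
    best_rep[i] <- representatives$protein_id[b]
    best_idt[i] <- idt[b]
    arch[i] <- if (idt[b] >= min_identity) rep_architectures[b]
               else NA_character_
  }
  assignments <- data.frame(protein_id = queries$protein_id,
                            architecture = arch,
                            best_representative = best_rep,
                            identity = best_idt,
                            stringsAsFactors = FALSE)
  lab <- ifelse(is.na(arch), "(unassigned)", arch)
  tab <- table(lab)
  prevalence <- data.frame(architecture = names(tab),
                           n = as.integer(tab),
                           prevalence = as.numeric(tab) / n,
                           stringsAsFactors = FALSE)
  prevalence <- prevalence[order(-prevalence$n, prevalence$architecture), ,
                           drop = FALSE]
  rownames(prevalence) <- NULL
  list(assignments = assignments, prevalence = prevalence)
}

#' Export an assembly table as TSV
#'
#' Columns: architecture, prevalence (percent of `total` when given,
#' otherwise of the summed members), taxonomy, example id, known ECs.
#'
#' @param assemblies Output of [enumerate_assemblies()].
#' @param path Output file.
#' @param total Denominator for the prevalence column; defaults to the sum
#'   of member counts.
#' @return `path`, invisibly.
#' @export
write_assemblies_tsv <- function(assemblies, path, total = NULL) {
  total <- total %||% sum(assemblies$n_members)
  out <- data.frame(
    architecture = assemblies$architecture,
    prevalence_pct = round(100 * assemblies$n_members / total, 1),
    taxonomy = vapply(assemblies$taxonomy, paste, "", collapse = ";"),
    example_id = assemblies$example_id,
    known_ecs = vapply(assemblies$ec_set, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
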