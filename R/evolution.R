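#' Excise domain peptides from a protein sequence
#'
#' Cuts each domain call out of the sequence using its stored 1-based
#' inclusive boundaries: the peptide for a call `(s, e)` is
#' `substr(sequence, s, e)` with length `e - s + 1`.
#'
#' @param record One-row `protein_records` (or a list with `protein_id`
#'   and `sequence`).
#' @param calls `domain_calls` of that protein.
#' @param name_filter Optional character vector; only calls whose name is
#'   in the filter are excised.
#' @return Data frame `name`, `start`, `end`, `peptide`, ordered by start.
#' @export
excise_domains <- function(record, calls, name_filter = NULL) {
  pid <- record$protein_id[1]
  seqn <- record$sequence[1]
  pc <- calls[calls$protein_id == pid, , drop = FALSE]
  if (!is.null(name_filter))
    pc <- pc[pc$name %in% name_filter, , drop = FALSE]
  if (nrow(pc) && any(pc$end > nchar(seqn)))
    stop("call exceeds sequence length of ", pid, ": ",
         paste(sprintf("%s(%d,%d)",
                       pc$name[pc$end > nchar(seqn)],
                       pc$start[pc$end > nchar(seqn)],
                       pc$end[pc$end > nchar(seqn)]), collapse = ", "))
  pc <- pc[order(pc$start, -pc$end), , drop = FALSE]
  data.frame(name = pc$name, start = pc$start, end = pc$end,
             peptide = substr(rep(seqn, nrow(pc)), pc$start, pc$end),
             stringsAsFactors = FALSE)
}

#' Within-group pairwise identities
#'
#' All unordered within-group pairs (self-pairs excluded) scored with
#' [global_identity()] in `"longer"` mode: best alignment score divided by
#' the longer of the two sequence lengths.  Each group of size `n` yields
#' `choose(n, 2)` identities.
#'
#' @param groups Named list of character vectors of peptides, each of
#'   length at least 2.
#' @return Named list of numeric identity vectors.
#' @export
pairwise_group_identities <- function(groups) {
  small <- names(groups)[vapply(groups, length, 0L) < 2]
  if (length(small))
    stop("group(s) with fewer than 2 members: ",
         paste(small, collapse = ", "))
  lapply(groups, function(seqs) {
    m <- identity_matrix(setNames(seqs, NULL), mode = "longer")
    m[upper.tri(m)]
  })
}

#' Kruskal-Wallis rank test over groups
#'
#' Mid-rank tie handling with the usual tie correction; the p-value comes
#' from the chi-square distribution with `k - 1` degrees of freedom.  When
#' every pooled value is identical the tie correction degenerates and the
#' convention `H = 0`, `p = 1` applies.
#'
#' @param groups Named list of numeric vectors (at least 2 groups, total
#'   `N >= 3`).
#' @return List with `H` (statistic) and `p`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # H = 3.857
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1),
            sum(lengths(groups)) >= 3)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1)
    return(list(H = 0, p = 1))
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Dunn's post hoc pairwise comparisons
#'
#' For groups `i`, `j` the statistic is
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j))` on mid-ranks of the pooled sample, with two-sided
#' normal p-values adjusted across all pairs.
#'
#' @param groups Named list of numeric vectors.
#' @param adjustment `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return Symmetric matrix of adjusted p-values with unit diagonal.
#' @export
dunn_posthoc <- function(groups, adjustment = c("bonferroni", "holm",
                                                "none")) {
  adjustment <- match.arg(adjustment)
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  k <- length(groups)
  nm <- names(groups) %||% as.character(seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)  # mid-ranks
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  var_term <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  idx <- which(upper.tri(p), arr.ind = TRUE)
  raw <- numeric(nrow(idx))
  for (q in seq_len(nrow(idx))) {
    i <- idx[q, 1]; j <- idx[q, 2]
    se <- sqrt(var_term * (1 / n[i] + 1 / n[j]))
    z <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    raw[q] <- 2 * pnorm(-abs(z))
  }
  adj <- p.adjust(raw, method = adjustment)
  p[idx] <- adj
  p[idx[, c(2, 1), drop = FALSE]] <- adj
  p
}

#' Compare evolution of homologous domain groups
#'
#' The full domain-level comparison: within-group pairwise identities
#' ([pairwise_group_identities()]), a Kruskal-Wallis test across groups,
#' and Dunn's post hoc pairwise p-values, plus a per-group summary of mean
#' and median percent identity.
#'
#' @param peptide_groups Named list of character vectors of domain
#'   peptides (each group at least 2 members).
#' @param adjustment Dunn adjustment, see [dunn_posthoc()].
#' @return A `group_comparison`: list with `identities` (fractions), `H`,
#'   `H_pvalue`, `dunn` (adjusted p matrix), `adjustment` and `summary`
#'   (data frame `group`, `n_sequences`, `n_pairs`, `mean_identity_pct`,
#'   `median_identity_pct`).
#' @export
compare_groups <- function(peptide_groups,
                           adjustment = c("bonferroni", "holm", "none")) {
  adjustment <- match.arg(adjustment)
  ids <- pairwise_group_identities(peptide_groups)
  kw <- kruskal_wallis(ids)
  dunn <- dunn_posthoc(ids, adjustment)
  summary <- data.frame(
    group = names(ids),
    n_sequences = lengths(peptide_groups),
    n_pairs = lengths(ids),
    mean_identity_pct = 100 * vapply(ids, mean, 0),
    median_identity_pct = 100 * vapply(ids, median, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(identities = ids, H = kw$H, H_pvalue = kw$p, dunn = dunn,
                 adjustment = adjustment, summary = summary),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Domain-group identity comparison (Kruskal-Wallis H =",
      format(x$H, digits = 4), ", p =", format(x$H_pvalue, digits = 3),
      ")\n")
  print(x$summary, row.names = FALSE)
  cat("Dunn adjusted p-values (", x$adjustment, "):\n", sep = "")
  print(round(x$dunn, 4))
  invisible(x)
}

#' Export a group comparison as TSV
#'
#' Writes the per-group summary and the Dunn p-value matrix.
#'
#' @param comparison A `group_comparison`.
#' @param summary_path,pvalues_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_comparison_tsv <- function(comparison, summary_path, pvalues_path) {
  write.table(comparison$summary, summary_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(group = rownames(comparison$dunn),
                         comparison$dunn, check.names = FALSE),
              pvalues_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(summary_path, pvalues_path))
}
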