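#' Global percent identity between two sequences
#'
#' Sequences are aligned globally under the scoring scheme match = 1,
#' mismatch = 0, gap = 0 (the classic default of simple pairwise aligners).
#' Under this scheme the best alignment score equals the maximal number of
#' identically aligned residue pairs.  The identity fraction divides that
#' score by a mode-dependent denominator:
#'
#' * `"longer"`  — length of the longer sequence (used for domain-level
#'   identity comparisons);
#' * `"shorter"` — length of the shorter sequence (the clustering
#'   convention; flags containment);
#' * `"query"`   — length of `a` (used for characterized-protein rescue and
#'   sequence attribution).
#'
#' @param a,b Nonempty amino-acid sequences (single strings).
#' @param mode Denominator convention; see above.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' global_identity("ACGT", "ACGA")            # 0.75
#' global_identity("AC", "ACGT", "shorter")   # 1
#' global_identity("AC", "ACGT", "longer")    # 0.5
#' @export
global_identity <- function(a, b, mode = c("longer", "shorter", "query")) {
  mode <- match.arg(mode)
  stopifnot(length(a) == 1, length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  st <- .align_pair_stats(a, b)
  denom <- switch(mode,
                  longer = max(nchar(a), nchar(b)),
                  shorter = min(nchar(a), nchar(b)),
                  query = nchar(a))
  unname(st[1, "matches"]) / denom
}

# Vectorized alignment statistics for pairs (a[i], b[i]).
# Returns data.frame(matches, paired) where `paired` is the number of
# residue-residue columns of one score-optimal alignment (used for
# alignment-coverage checks in clustering).
alignment_stats <- function(a, b) {
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop("sequences must be nonempty")
  st <- .align_pair_stats(as.character(a), as.character(b))
  data.frame(matches = st[, "matches"], paired = st[, "paired"])
}

#' Pairwise identity matrix for a set of sequences
#'
#' Computes [global_identity()] for all unordered pairs; the diagonal is 1.
#'
#' @param seqs Named character vector of sequences.
#' @param mode Denominator convention, see [global_identity()].
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
identity_matrix <- function(seqs, mode = c("longer", "shorter")) {
  mode <- match.arg(mode)
  n <- length(seqs)
  m <- diag(1, n)
  if (n > 1) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    st <- alignment_stats(seqs[idx[, 1]], seqs[idx[, 2]])
    len_a <- nchar(seqs[idx[, 1]])
    len_b <- nchar(seqs[idx[, 2]])
    denom <- if (mode == "longer") pmax(len_a, len_b) else pmin(len_a, len_b)
    m[idx] <- st$matches / denom
    m[idx[, c(2, 1), drop = FALSE]] <- m[idx]
  }
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}
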