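#' Clustering configuration
#'
#' Greedy incremental clustering in the CD-HIT style: sequences sorted by
#' length (descending) join the first representative they match at or above
#' `identity_threshold` (identity over the shorter sequence) with alignment
#' coverage of at least `coverage_short` of the shorter and `coverage_long`
#' of the longer sequence.
#'
#' @param identity_threshold Identity fraction, default 0.85.
#' @param coverage_short,coverage_long Minimum aligned-region coverage of
#'   the shorter/longer sequence, both default 0.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(identity_threshold = 0.85,
                           coverage_short = 0, coverage_long = 0) {
  stopifnot(identity_threshold >= 0, identity_threshold <= 1,
            coverage_short >= 0, coverage_short <= 1,
            coverage_long >= 0, coverage_long <= 1)
  structure(list(identity_threshold = identity_threshold,
                 coverage_short = coverage_short,
                 coverage_long = coverage_long),
            class = "cluster_config")
}

#' Characterized-protein rescue configuration
#'
#' A characterized protein missing from the dataset may be replaced by its
#' best hit in a rescue pool when the similarity — identical matches divided
#' by the query protein length — is at least `min_similarity`.
#'
#' @param min_similarity Fraction, default 0.95.
#' @return A `rescue_config` list.
#' @export
rescue_config <- function(min_similarity = 0.95) {
  stopifnot(min_similarity >= 0, min_similarity <= 1)
  structure(list(min_similarity = min_similarity), class = "rescue_config")
}

#' Remove duplicate identifiers and sequences
#'
#' Keeps the first occurrence (stable input order); a record is a duplicate
#' if its identifier or its exact sequence string was seen before.
#'
#' @param records A `protein_records` data frame.
#' @return List with `kept` (records) and `dropped` (data frame of
#'   `protein_id`, `reason`).
#' @export
deduplicate <- function(records) {
  dup_id <- duplicated(records$protein_id)
  dup_seq <- duplicated(records$sequence) & !dup_id
  drop <- dup_id | dup_seq
  dropped <- data.frame(
    protein_id = records$protein_id[drop],
    reason = ifelse(dup_id[drop], "duplicate-identifier",
                    "duplicate-sequence"),
    stringsAsFactors = FALSE
  )
  list(kept = records[!drop, , drop = FALSE], dropped = dropped)
}

#' Drop partial proteins
#'
#' Records whose description contains the token `partial` (case-insensitive,
#' word-boundary match — `"partially"` does not match) are dropped.
#'
#' @param records A `protein_records` data frame.
#' @return List with `kept` and `dropped` as in [deduplicate()].
#' @export
filter_partial <- function(records) {
  drop <- grepl("\\bpartial\\b", records$description, ignore.case = TRUE)
  list(kept = records[!drop, , drop = FALSE],
       dropped = data.frame(protein_id = records$protein_id[drop],
                            reason = rep("partial", sum(drop)),
                            stringsAsFactors = FALSE))
}

#' Keep only records present in a reference archive
#'
#' The offline stand-in for a presence lookup against a comprehensive
#' sequence archive: records whose id is absent from `presence_ids` are
#' dropped (no domain information would exist for them).
#'
#' @param records A `protein_records` data frame.
#' @param presence_ids Character vector of ids known to the reference.
#' @return List with `kept` and `dropped` (reason `absent-from-reference`).
#' @export
filter_presence <- function(records, presence_ids) {
  if (length(presence_ids) == 0)
    warning("empty presence list: all records dropped")
  drop <- !(records$protein_id %in% presence_ids)
  list(kept = records[!drop, , drop = FALSE],
       dropped = data.frame(protein_id = records$protein_id[drop],
                            reason = rep("absent-from-reference", sum(drop)),
                            stringsAsFactors = FALSE))
}

#' Greedy incremental clustering of protein sequences
#'
#' Sequences are sorted by length descending (ties: input order).  Each
#' sequence joins the first representative it matches at
#' `identity >= identity_threshold` (identity over the shorter sequence)
#' with sufficient aligned-region coverage; otherwise it founds a new
#' cluster.  Every member therefore satisfies the threshold against its
#' representative.
#'
#' @param records A `protein_records` data frame (nonempty).
#' @param config A [cluster_config()].
#' @return List with `representatives` (records subset) and `membership`
#'   (data frame `protein_id`, `representative_id`, `identity`).
#' @export
cluster_greedy <- function(records, config = cluster_config()) {
  stopifnot(nrow(records) >= 1)
  ord <- order(-nchar(records$sequence), seq_len(nrow(records)))
  rep_idx <- integer()
  member_rep <- character(nrow(records))
  member_idt <- numeric(nrow(records))
  for (i in ord) {
    seq_i <- records$sequence[i]
    len_i <- nchar(seq_i)
    assigned <- FALSE
    for (r in rep_idx) {
      seq_r <- records$sequence[r]
      len_r <- nchar(seq_r)
      st <- alignment_stats(seq_i, seq_r)
      sh <- min(len_i, len_r); lo <- max(len_i, len_r)
      idt <- st$matches / sh
      if (idt >= config$identity_threshold &&
          st$paired / sh >= config$coverage_short &&
          st$paired / lo >= config$coverage_long) {
        member_rep[i] <- records$protein_id[r]
        member_idt[i] <- idt
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      member_rep[i] <- records$protein_id[i]
      member_idt[i] <- 1
    }
  }
  rep_idx <- sort(rep_idx)  # back to input order
  list(
    representatives = records[rep_idx, , drop = FALSE],
    membership = data.frame(protein_id = records$protein_id,
                            representative_id = member_rep,
                            identity = member_idt,
                            stringsAsFactors = FALSE)
  )
}

#' Guarantee retention of characterized proteins
#'
#' The final sequence set is the cluster representatives plus every
#' characterized record, even if clustering removed it.  A characterized id
#' absent from `all_records` is replaced by its best hit in `rescue_pool`
#' provided the similarity (identical matches / query length) reaches
#' `config$min_similarity`; otherwise it is logged as unrescued.  Sequences
#' for such external ids are taken from `characterized_seqs` when supplied.
#'
#' @param representatives Records retained by clustering.
#' @param all_records The full pre-clustering record set.
#' @param characterized_ids Ids of characterized proteins.
#' @param rescue_pool Optional records searched for substitutes.
#' @param config A [rescue_config()].
#' @param characterized_seqs Optional `protein_records` providing sequences
#'   for characterized ids absent from `all_records`.
#' @return List with `records` (final set) and `log` (data frame
#'   `protein_id`, `action`, `detail`).
#' @export
retain_characterized <- function(representatives, all_records,
                                 characterized_ids, rescue_pool = NULL,
                                 config = rescue_config(),
                                 characterized_seqs = NULL) {
  out <- representatives
  log <- data.frame(protein_id = character(), action = character(),
                    detail = character(), stringsAsFactors = FALSE)
  note <- function(id, action, detail = "")
    rbind(log, data.frame(protein_id = id, action = action, detail = detail,
                          stringsAsFactors = FALSE))
  for (id in characterized_ids) {
    if (id %in% out$protein_id) next
    hit <- which(all_records$protein_id == id)
    if (length(hit)) {
      out <- rbind(out, all_records[hit[1], , drop = FALSE])
      log <- note(id, "re-added", "present in dataset, removed by clustering")
      next
    }
    qseq <- NULL
    if (!is.null(characterized_seqs)) {
      q <- which(characterized_seqs$protein_id == id)
      if (length(q)) qseq <- characterized_seqs$sequence[q[1]]
    }
    if (is.null(qseq) || is.null(rescue_pool) || nrow(rescue_pool) == 0) {
      log <- note(id, "unrescued", "no sequence or rescue pool available")
      next
    }
    st <- alignment_stats(rep(qseq, nrow(rescue_pool)), rescue_pool$sequence)
    sim <- st$matches / nchar(qseq)
    best <- which.max(sim)
    if (sim[best] >= config$min_similarity) {
      sub <- rescue_pool[best, , drop = FALSE]
      if (!sub$protein_id %in% out$protein_id) out <- rbind(out, sub)
      log <- note(id, "substituted",
                  sprintf("best hit %s, similarity %.3f",
                          sub$protein_id, sim[best]))
    } else {
      log <- note(id, "unrescued",
                  sprintf("best similarity %.3f below %.2f",
                          sim[best], config$min_similarity))
    }
  }
  class(out) <- c("protein_records", "data.frame")
  list(records = out, log = log)
}
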