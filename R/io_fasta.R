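#' Read protein records from a FASTA file
#'
#' Parsing is delegated to [Biostrings::readAAStringSet()]; sequences are
#' uppercased and duplicate identifiers rejected.  The identifier is the
#' first whitespace-delimited token of the header.  The remainder of the
#' header is the description, except for recognised `key=value` metadata
#' tokens:
#'
#' * `tax=<group>` — taxonomy group (one of [TAXONOMY_GROUPS]);
#' * `char=1` — characterized flag;
#' * `ec=<n.n.n.n;...>` — semicolon-separated EC numbers.
#'
#' Headers written by [write_fasta()] use the same convention, so metadata
#' round-trips.
#'
#' @param path Path to a FASTA file.
#' @return A `protein_records` data frame in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty FASTA input: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0)
    stop("empty FASTA input (no header lines): ", path)
  bad <- hdr_idx[!grepl("^>\\S", lines[hdr_idx])]
  if (length(bad))
    stop("malformed FASTA header (no identifier) at line ", bad[1])
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    stop("duplicate identifier(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rest <- trimws(sub("^\\S+\\s*", "", headers))
  meta <- lapply(rest, parse_header_tokens)
  protein_records(
    protein_id = ids,
    sequence = toupper(as.character(set)),
    description = vapply(meta, `[[`, "", "description"),
    taxonomy_group = vapply(meta, `[[`, "", "taxonomy_group"),
    characterized = vapply(meta, `[[`, NA, "characterized"),
    ec_numbers = lapply(meta, `[[`, "ec_numbers")
  )
}

parse_header_tokens <- function(rest) {
  tokens <- if (nzchar(rest)) strsplit(rest, "\\s+")[[1]] else character()
  is_kv <- grepl("^(tax|char|ec)=", tokens)
  kv <- tokens[is_kv]
  get <- function(key) {
    hit <- grep(paste0("^", key, "="), kv, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else NA_character_
  }
  tax <- get("tax")
  ch <- get("char")
  ec <- get("ec")
  list(
    description = paste(tokens[!is_kv], collapse = " "),
    taxonomy_group = if (is.na(tax)) "Unclassified" else tax,
    characterized = (!is.na(ch) && ch %in% c("1", "TRUE", "true")) ||
      (!is.na(ec) && nzchar(ec)),
    ec_numbers = if (is.na(ec) || !nzchar(ec)) character()
                 else strsplit(ec, ";", fixed = TRUE)[[1]]
  )
}

#' Write protein records to a FASTA file
#'
#' Sequences are wrapped at 60 columns.  Non-default metadata (taxonomy,
#' characterized flag, EC numbers) is encoded as `key=value` header tokens
#' understood by [read_fasta()], so `read_fasta(write_fasta(x))` reproduces
#' identifiers, sequences and metadata.
#'
#' @param records A `protein_records` data frame (nonempty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("'records' must be a nonempty protein_records data frame")
  validate_protein_records(records)
  hdr <- records$protein_id
  for (i in seq_len(nrow(records))) {
    parts <- character()
    if (nzchar(records$description[i])) parts <- records$description[i]
    if (records$taxonomy_group[i] != "Unclassified")
      parts <- c(parts, paste0("tax=", records$taxonomy_group[i]))
    if (isTRUE(records$characterized[i]))
      parts <- c(parts, "char=1")
    if (length(records$ec_numbers[[i]]))
      parts <- c(parts,
                 paste0("ec=", paste(records$ec_numbers[[i]], collapse = ";")))
    if (length(parts)) hdr[i] <- paste(hdr[i], paste(parts, collapse = " "))
  }
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
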