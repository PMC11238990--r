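#' Construct a protein record table
#'
#' The central sequence container: one row per protein with its identifier,
#' amino-acid sequence, free-text description, taxonomy group, characterized
#' flag and EC numbers (a list column, empty unless characterized).
#'
#' @param protein_id Character vector of unique, nonempty identifiers
#'   (GenBank-style accessions).
#' @param sequence Character vector of uppercase amino-acid sequences.
#' @param description Free-text descriptions (recycled if scalar).
#' @param taxonomy_group One of `r paste(TAXONOMY_GROUPS, collapse = ", ")`
#'   (recycled if scalar).
#' @param characterized Logical; experimentally characterized proteins.
#' @param ec_numbers List of character vectors of EC numbers; must be empty
#'   for non-characterized records.
#' @return A `data.frame` with class `protein_records`.
#' @examples
#' protein_records("P1", "MKVA")
#' @export
protein_records <- function(protein_id, sequence, description = "",
                            taxonomy_group = "Unclassified",
                            characterized = FALSE,
                            ec_numbers = NULL) {
  n <- length(protein_id)
  if (is.null(ec_numbers)) ec_numbers <- rep(list(character()), n)
  if (!is.list(ec_numbers)) ec_numbers <- list(ec_numbers)
  df <- data.frame(
    protein_id = as.character(protein_id),
    sequence = toupper(as.character(sequence)),
    description = rep_len(as.character(description), n),
    taxonomy_group = rep_len(as.character(taxonomy_group), n),
    characterized = rep_len(as.logical(characterized), n),
    stringsAsFactors = FALSE
  )
  df$ec_numbers <- rep_len(ec_numbers, n)
  class(df) <- c("protein_records", "data.frame")
  validate_protein_records(df)
}

#' Validate a protein record table
#'
#' Checks identifier uniqueness, sequence alphabet and length, taxonomy
#' values, EC number syntax and the characterized/EC consistency rule.
#'
#' @param records A `protein_records` data frame.
#' @return The validated records, invisibly unchanged.
#' @export
validate_protein_records <- function(records) {
  stopifnot(is.data.frame(records))
  ids <- records$protein_id
  if (any(!nzchar(ids)) || anyNA(ids))
    stop("protein_id must be nonempty")
  if (anyDuplicated(ids))
    stop("duplicate protein identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(records$sequence) < 1))
    stop("zero-length sequence for: ",
         paste(ids[nchar(records$sequence) < 1], collapse = ", "))
  ok <- vapply(strsplit(records$sequence, ""), function(ch)
    all(ch %in% AA_ALPHABET), logical(1))
  if (!all(ok))
    stop("non-amino-acid characters in sequence of: ",
         paste(ids[!ok], collapse = ", "))
  if (!all(records$taxonomy_group %in% TAXONOMY_GROUPS))
    stop("taxonomy_group must be one of: ",
         paste(TAXONOMY_GROUPS, collapse = ", "))
  n_ec <- lengths(records$ec_numbers)
  if (any(!records$characterized & n_ec > 0))
    stop("non-characterized records must have empty ec_numbers: ",
         paste(ids[!records$characterized & n_ec > 0], collapse = ", "))
  all_ec <- unlist(records$ec_numbers)
  if (length(all_ec) && !all(is_valid_ec(all_ec)))
    stop("malformed EC number(s): ",
         paste(all_ec[!is_valid_ec(all_ec)], collapse = ", "))
  invisible(records)
}

#' Test EC number syntax
#'
#' An EC number is four dot-separated fields, the first three numeric and
#' the last numeric or `-` (undetermined serial).
#'
#' @param ec Character vector.
#' @return Logical vector.
#' @examples
#' is_valid_ec(c("3.2.1.176", "3.2.1.-", "banana"))
#' @export
is_valid_ec <- function(ec) {
  grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$", ec)
}

#' Construct a raw annotation table
#'
#' One row per domain hit from one source database, with 1-based inclusive
#' coordinates.
#'
#' @param protein_id,source_db,accession,name Character vectors.
#' @param start,end Integer vectors, 1-based inclusive, `start <= end`.
#' @return A `data.frame` with class `raw_annotations`.
#' @export
raw_annotations <- function(protein_id = character(),
                            source_db = character(),
                            accession = character(),
                            name = character(),
                            start = integer(), end = integer()) {
  df <- data.frame(
    protein_id = as.character(protein_id),
    source_db = as.character(source_db),
    accession = as.character(accession),
    name = as.character(name),
    start = as.integer(start),
    end = as.integer(end),
    stringsAsFactors = FALSE
  )
  if (any(df$start < 1L) || any(df$start > df$end))
    stop("annotation coordinates must satisfy 1 <= start <= end")
  class(df) <- c("raw_annotations", "data.frame")
  df
}
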