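# Three-table relational store.  The schema is versioned and fixed:
#   ProteinSequences  - one row per protein: sequence, origin metadata,
#                       architecture string, serialized domain calls
#   DomainAssemblies  - one row per unique architecture with member count
#   DomainCuration    - log of raw -> curated name substitutions
STORE_SCHEMA_VERSION <- 1L

STORE_DDL <- c(
  ProteinSequences = paste(
    "CREATE TABLE ProteinSequences (",
    "  protein_id TEXT PRIMARY KEY,",
    "  sequence TEXT NOT NULL,",
    "  description TEXT,",
    "  taxonomy_group TEXT,",
    "  characterized INTEGER,",
    "  ec_numbers TEXT,",        # JSON array
    "  architecture TEXT,",      # '' when domainless
    "  domain_calls TEXT",       # JSON array of {name,start,end,...}
    ")"),
  DomainAssemblies = paste(
    "CREATE TABLE DomainAssemblies (",
    "  architecture TEXT PRIMARY KEY,",
    "  n_members INTEGER NOT NULL,",
    "  example_id TEXT,",
    "  taxonomy TEXT",           # JSON array of groups observed
    ")"),
  DomainCuration = paste(
    "CREATE TABLE DomainCuration (",
    "  raw_name TEXT NOT NULL,",
    "  curated_name TEXT NOT NULL,",
    "  timestamp TEXT NOT NULL",
    ")")
)

#' Save an analysis to an SQLite store
#'
#' Persists protein records, their consolidated domain calls, the assembly
#' summary and the curation log in three tables (`ProteinSequences`,
#' `DomainAssemblies`, `DomainCuration`).  Before writing, the store
#' invariants are checked: every architecture seen among the proteins must
#' exist in the assemblies table, and assembly member counts must sum to the
#' number of proteins with at least one domain call.  Violations abort the
#' save with a diagnostic naming the offending architecture.
#'
#' @param path Path of the SQLite file (overwritten).
#' @param records A `protein_records` data frame.
#' @param calls A `domain_calls` data frame (all proteins).
#' @param assemblies Assemblies table from [enumerate_assemblies()].
#' @param curation_log Data frame with columns `raw_name`, `curated_name`
#'   (and optionally `timestamp`); may have zero rows.
#' @return `path`, invisibly.
#' @seealso [load_analysis()]
#' @export
save_analysis <- function(path, records, calls, assemblies,
                          curation_log = NULL) {
  validate_protein_records(records)
  if (is.null(curation_log))
    curation_log <- data.frame(raw_name = character(),
                               curated_name = character())
  arch_by_protein <- architecture_by_protein(records$protein_id, calls)
  nonempty <- arch_by_protein[nzchar(arch_by_protein)]
  missing <- setdiff(unique(nonempty), assemblies$architecture)
  if (length(missing))
    stop("store invariant violated: architecture(s) absent from ",
         "DomainAssemblies: ", paste(missing, collapse = " | "))
  if (length(nonempty) != sum(assemblies$n_members))
    stop("store invariant violated: DomainAssemblies member counts (",
         sum(assemblies$n_members), ") do not sum to the number of ",
         "proteins with domain calls (", length(nonempty), ")")

  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  for (ddl in STORE_DDL) DBI::dbExecute(con, ddl)

  json <- function(x) vapply(x, function(v)
    as.character(jsonlite::toJSON(v, auto_unbox = FALSE)), "")
  calls_json <- vapply(records$protein_id, function(pid) {
    pc <- calls[calls$protein_id == pid, , drop = FALSE]
    as.character(jsonlite::toJSON(list(
      name = pc$name, start = pc$start, end = pc$end,
      source_dbs = pc$source_dbs, accessions = pc$accessions
    ), auto_unbox = FALSE))
  }, "")
  DBI::dbWriteTable(con, "ProteinSequences", data.frame(
    protein_id = records$protein_id,
    sequence = records$sequence,
    description = records$description,
    taxonomy_group = records$taxonomy_group,
    characterized = as.integer(records$characterized),
    ec_numbers = json(records$ec_numbers),
    architecture = unname(arch_by_protein),
    domain_calls = unname(calls_json),
    stringsAsFactors = FALSE
  ), append = TRUE)
  DBI::dbWriteTable(con, "DomainAssemblies", data.frame(
    architecture = assemblies$architecture,
    n_members = as.integer(assemblies$n_members),
    example_id = assemblies$example_id,
    taxonomy = json(assemblies$taxonomy),
    stringsAsFactors = FALSE
  ), append = TRUE)
  ts <- curation_log$timestamp %||%
    rep(format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
        nrow(curation_log))
  DBI::dbWriteTable(con, "DomainCuration", data.frame(
    raw_name = curation_log$raw_name,
    curated_name = curation_log$curated_name,
    timestamp = as.character(ts),
    stringsAsFactors = FALSE
  ), append = TRUE)
  invisible(path)
}

#' Load an analysis from an SQLite store
#'
#' @param path Path written by [save_analysis()].
#' @return List with elements `records`, `calls`, `assemblies`,
#'   `curation_log` equal to what was saved.
#' @export
load_analysis <- function(path) {
  if (!file.exists(path)) stop("no such store: ", path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  ps <- DBI::dbReadTable(con, "ProteinSequences")
  da <- DBI::dbReadTable(con, "DomainAssemblies")
  dc <- DBI::dbReadTable(con, "DomainCuration")

  records <- protein_records(
    protein_id = ps$protein_id,
    sequence = ps$sequence,
    description = ps$description,
    taxonomy_group = ps$taxonomy_group,
    characterized = as.logical(ps$characterized),
    ec_numbers = lapply(ps$ec_numbers, function(j)
      as.character(jsonlite::fromJSON(j)))
  )
  call_rows <- lapply(seq_len(nrow(ps)), function(i) {
    x <- jsonlite::fromJSON(ps$domain_calls[i], simplifyVector = FALSE)
    n <- length(x$name)
    if (n == 0) return(NULL)
    df <- data.frame(protein_id = rep(ps$protein_id[i], n),
                     name = unlist(x$name),
                     start = as.integer(unlist(x$start)),
                     end = as.integer(unlist(x$end)),
                     stringsAsFactors = FALSE)
    df$source_dbs <- lapply(x$source_dbs, function(s) unlist(s) %||% character())
    df$accessions <- lapply(x$accessions, function(s) unlist(s) %||% character())
    df
  })
  calls <- do.call(rbind, call_rows)
  if (is.null(calls)) calls <- empty_domain_calls()
  class(calls) <- c("domain_calls", "data.frame")

  assemblies <- data.frame(
    architecture = da$architecture,
    n_members = as.integer(da$n_members),
    example_id = da$example_id,
    stringsAsFactors = FALSE
  )
  assemblies$taxonomy <- lapply(da$taxonomy, function(j)
    as.character(jsonlite::fromJSON(j)))

  list(records = records, calls = calls, assemblies = assemblies,
       curation_log = dc)
}

architecture_by_protein <- function(protein_ids, calls) {
  out <- setNames(rep("", length(protein_ids)), protein_ids)
  if (!is.null(calls) && nrow(calls)) {
    by <- split(calls, calls$protein_id)
    for (pid in names(by)) {
      if (pid %in% names(out))
        out[pid] <- architecture_string(by[[pid]])
    }
  }
  out
}
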