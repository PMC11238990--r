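#' Read domain annotations from local files
#'
#' Two dialects are accepted, mirroring a locally cached multi-database
#' annotation dump:
#'
#' * flat TSV with header
#'   `protein_id  source_db  accession  name  start  end`;
#' * nested JSON keyed by protein id, each value an array of objects with
#'   fields `source_db`, `accession`, `name`, `start`, `end`.
#'
#' A file is treated as JSON when its first non-whitespace character is `{`.
#' Multiple paths are concatenated in the order given (stable by file, then
#' line/record).  Records violating `1 <= start <= end` are skipped with a
#' warning, not an error.  Source databases outside [SOURCE_DATABASES] are
#' preserved verbatim but flagged with a warning.
#'
#' @param paths Character vector of file paths.
#' @return A `raw_annotations` data frame.  Skipped records are reported in
#'   the `"skipped"` attribute.
#' @export
read_annotations <- function(paths) {
  stopifnot(length(paths) >= 1)
  parts <- lapply(paths, read_annotations_one)
  ann <- do.call(rbind, lapply(parts, `[[`, "ann"))
  skipped <- do.call(rbind, lapply(parts, `[[`, "skipped"))
  unknown <- setdiff(unique(ann$source_db), SOURCE_DATABASES)
  if (length(unknown))
    warning("unknown source database(s) preserved verbatim: ",
            paste(unknown, collapse = ", "))
  out <- raw_annotations(ann$protein_id, ann$source_db, ann$accession,
                         ann$name, ann$start, ann$end)
  attr(out, "skipped") <- skipped
  out
}

read_annotations_one <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- substr(trimws(readChar(path, min(file.size(path), 200L))), 1, 1)
  df <- if (identical(first, "{")) {
    nested <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    rows <- lapply(names(nested), function(pid) {
      do.call(rbind, lapply(nested[[pid]], function(r)
        data.frame(protein_id = pid,
                   source_db = as.character(r$source_db),
                   accession = as.character(r$accession),
                   name = as.character(r$name %||% MISSING_NAME),
                   start = as.integer(r$start), end = as.integer(r$end),
                   stringsAsFactors = FALSE)))
    })
    do.call(rbind, rows)
  } else {
    tab <- read.delim(path, sep = "\t", header = TRUE,
                      colClasses = "character", check.names = FALSE)
    need <- c("protein_id", "source_db", "accession", "name", "start", "end")
    if (!all(need %in% names(tab)))
      stop("annotation TSV ", path, " must have columns: ",
           paste(need, collapse = ", "))
    tab$start <- as.integer(tab$start)
    tab$end <- as.integer(tab$end)
    tab[need]
  }
  if (is.null(df))
    df <- data.frame(protein_id = character(), source_db = character(),
                     accession = character(), name = character(),
                     start = integer(), end = integer())
  bad <- is.na(df$start) | is.na(df$end) | df$start < 1L | df$start > df$end
  if (any(bad)) {
    warning(sum(bad), " annotation record(s) skipped in ", path,
            " (invalid coordinates)")
  }
  list(ann = df[!bad, , drop = FALSE],
       skipped = cbind(df[bad, , drop = FALSE],
                       file = rep(path, sum(bad))))
}

#' Read a characterized-protein table
#'
#' Two tab-separated columns: protein id and a semicolon-separated EC list.
#' Every EC number must match the `d.d.d.(d|-)` pattern.
#'
#' @param path Path to the table.
#' @return Named list mapping protein id to a character vector of ECs.
#' @export
read_characterized_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stop("row ", i, ": expected two tab-separated columns")
    ecs <- strsplit(fields[2], ";", fixed = TRUE)[[1]]
    ecs <- trimws(ecs)
    if (!all(is_valid_ec(ecs)))
      stop("row ", i, " (", fields[1], "): malformed EC number: ",
           paste(ecs[!is_valid_ec(ecs)], collapse = ", "))
    out[[fields[1]]] <- ecs
  }
  out
}

#' Read a domain-name curation map
#'
#' Two tab-separated columns: raw signature name, curated overarching name.
#'
#' @param path Path to the TSV (no header).
#' @return A [curation_map()] object.
#' @export
read_curation_map <- function(path) {
  tab <- read.delim(path, sep = "\t", header = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2) stop("curation map needs two columns")
  curation_map(setNames(tab[[2]], tab[[1]]))
}

#' Read a presence list (one protein id per line)
#'
#' The offline stand-in for a reference-archive lookup: only ids present in
#' this list are retained by [filter_presence()].
#'
#' @param path Path to the list.
#' @return Character vector of ids.
#' @export
read_presence_list <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}
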