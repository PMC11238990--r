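#' Run the full domain-architecture workflow
#'
#' Chains the library end to end: read inputs, deduplicate and filter
#' sequences, cluster with guaranteed retention of characterized proteins,
#' consolidate the multi-source annotations of every retained protein,
#' enumerate assemblies, build the co-occurrence network, and persist
#' everything in the three-table SQLite store.
#'
#' @param fasta Path to the protein FASTA file.
#' @param annotations Path(s) to annotation files (TSV or nested JSON).
#' @param characterized Optional path to a characterized-protein table.
#' @param curation Optional path to a curation-map TSV.
#' @param presence Optional path to a presence list; when given, sequences
#'   absent from it are excluded.
#' @param store Optional path for the SQLite store.
#' @param cluster Cluster configuration ([cluster_config()]), or `NULL` to
#'   skip clustering.
#' @param config Consolidation configuration ([consolidation_config()]).
#' @return List with `records` (analyzed set), `calls`, `assemblies`,
#'   `network`, `domainless`, `dropped_sequences`, `dropped_annotations`,
#'   `curation_log`.
#' @export
run_pipeline <- function(fasta, annotations, characterized = NULL,
                         curation = NULL, presence = NULL, store = NULL,
                         cluster = cluster_config(),
                         config = consolidation_config()) {
  records <- read_fasta(fasta)
  anns <- read_annotations(annotations)
  map <- if (!is.null(curation)) read_curation_map(curation)
         else curation_map()
  char_tab <- if (!is.null(characterized))
    read_characterized_table(characterized) else list()

  seq_drops <- list()
  dd <- deduplicate(records); seq_drops$duplicates <- dd$dropped
  fp <- filter_partial(dd$kept); seq_drops$partial <- fp$dropped
  current <- fp$kept
  if (!is.null(presence)) {
    pr <- filter_presence(current, read_presence_list(presence))
    seq_drops$presence <- pr$dropped
    current <- pr$kept
  }
  # annotate characterized flags from the table
  if (length(char_tab)) {
    idx <- match(names(char_tab), current$protein_id)
    ok <- !is.na(idx)
    current$characterized[idx[ok]] <- TRUE
    current$ec_numbers[idx[ok]] <- unname(char_tab[ok])
  }
  analyzed <- current
  if (!is.null(cluster)) {
    cl <- cluster_greedy(current, cluster)
    rc <- retain_characterized(cl$representatives, current,
                               names(char_tab))
    analyzed <- rc$records
  }

  cons <- consolidate_all(analyzed$protein_id, anns, map, config)
  assemblies <- enumerate_assemblies(cons$calls, analyzed)
  arch_by <- architecture_by_protein(analyzed$protein_id, cons$calls)
  net <- build_network(unname(arch_by))
  if (!is.null(store))
    save_analysis(store, analyzed, cons$calls, assemblies,
                  cons$map$applied_log)
  list(records = analyzed, calls = cons$calls, assemblies = assemblies,
       network = net, domainless = cons$domainless,
       dropped_sequences = do.call(rbind, seq_drops),
       dropped_annotations = cons$dropped,
       curation_log = cons$map$applied_log)
}
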