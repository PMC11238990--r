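# iTOL shape vocabulary used for domain glyphs
ITOL_SHAPES <- c("RE", "EL", "DI", "TR", "HH", "HV", "PL", "PR", "PU",
                 "PD", "OC", "GP")

# Fixed colour palette for domains (hex)
DOMAIN_PALETTE <- c(
  "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd", "#8c564b",
  "#e377c2", "#7f7f7f", "#bcbd22", "#17becf", "#aec7e8", "#ffbb78",
  "#98df8a", "#ff9896", "#c5b0d5", "#c49c94"
)

# Default label colours for the four well-known GH48 activities; other ECs
# draw from the remaining palette in sorted order.
EC_BASE_COLORS <- c("3.2.1.14" = "#0000ff",  # chitinase: blue
                    "3.2.1.4"  = "#ffcc00",  # endoglucanase: yellow
                    "3.2.1.91" = "#008000",  # cellobiohydrolase: green
                    "3.2.1.176" = "#ff0000") # reducing-end CBH: red

#' Exclude domainless proteins from tree inputs
#'
#' Proteins without any detected domain carry no architecture to annotate
#' and are excluded from the alignment and tree.
#'
#' @param records A `protein_records` data frame.
#' @param calls Consolidated `domain_calls` for these proteins.
#' @return List with `kept` (records) and `excluded` (data frame
#'   `protein_id`, `reason`).
#' @export
select_tree_inputs <- function(records, calls) {
  has_domain <- records$protein_id %in% unique(calls$protein_id)
  if (!any(has_domain))
    warning("no protein has any detected domain; tree input is empty")
  list(kept = records[has_domain, , drop = FALSE],
       excluded = data.frame(protein_id = records$protein_id[!has_domain],
                             reason = rep("no-domains", sum(!has_domain)),
                             stringsAsFactors = FALSE))
}

#' Multiple sequence alignment through an adapter
#'
#' The adapter contract: a function taking a named character vector of
#' sequences and returning a named character vector of aligned sequences of
#' equal width over the same names.  [mafft_adapter()] wraps the external
#' `mafft` binary; [stub_msa_adapter()] is a dependency-free stand-in for
#' tests (right-pads with gaps).
#'
#' @param records A `protein_records` data frame.
#' @param adapter Adapter function.
#' @return Named character vector of aligned sequences, with the adapter
#'   invocation recorded in attribute `"log"`.
#' @export
run_msa <- function(records, adapter = stub_msa_adapter()) {
  seqs <- setNames(records$sequence, records$protein_id)
  aln <- adapter(seqs)
  if (length(unique(nchar(aln))) != 1)
    stop("adapter returned ragged alignment")
  if (!setequal(names(aln), names(seqs)))
    stop("adapter changed the sequence id set")
  aln <- aln[names(seqs)]
  attr(aln, "log") <- attr(adapter, "log") %||%
    sprintf("msa adapter %s on %d sequences",
            attr(adapter, "name") %||% "custom", length(seqs))
  aln
}

#' Phylogenetic tree inference through an adapter
#'
#' The adapter contract: a function taking a named character vector of
#' aligned sequences and returning Newick text whose leaves are exactly the
#' input names.  [fasttree_adapter()] wraps the external `fasttree` binary
#' (approximate ML, Shimodaira-Hasegawa-like local supports);
#' [stub_tree_adapter()] returns a star tree for tests.
#'
#' @param alignment Named character vector from [run_msa()].
#' @param adapter Adapter function.
#' @param excluded_ids Ids left out upstream (recorded in the bundle).
#' @return A `tree_bundle`: list with `newick`, `tree` (an [ape::read.tree]
#'   phylo), `included_ids`, `excluded_ids`, `log`.
#' @export
run_tree <- function(alignment, adapter = stub_tree_adapter(),
                     excluded_ids = character()) {
  newick <- adapter(alignment)
  tree <- ape::read.tree(text = newick)
  if (is.null(tree)) stop("adapter did not return parseable Newick")
  if (!setequal(tree$tip.label, names(alignment)))
    stop("tree leaf set does not match alignment ids; missing: ",
         paste(setdiff(names(alignment), tree$tip.label), collapse = ", "))
  structure(list(newick = newick, tree = tree,
                 included_ids = tree$tip.label,
                 excluded_ids = excluded_ids,
                 log = attr(adapter, "name") %||% "custom"),
            class = "tree_bundle")
}

#' @rdname run_msa
#' @export
stub_msa_adapter <- function() {
  f <- function(seqs) {
    w <- max(nchar(seqs))
    setNames(vapply(seqs, function(s)
      paste0(s, strrep("-", w - nchar(s))), ""), names(seqs))
  }
  attr(f, "name") <- "stub-msa"
  f
}

#' @rdname run_tree
#' @export
stub_tree_adapter <- function() {
  f <- function(alignment) {
    ids <- names(alignment)
    if (length(ids) < 2) stop("need at least two sequences for a tree")
    paste0("(", paste(ids, collapse = ","), ");")
  }
  attr(f, "name") <- "stub-tree"
  f
}

#' @rdname run_msa
#' @param binary Path or name of the executable.
#' @export
mafft_adapter <- function(binary = "mafft") {
  f <- function(seqs) {
    if (Sys.which(binary) == "")
      stop("external aligner not found on PATH: ", binary,
           " (install it or use stub_msa_adapter())")
    fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(fin, fout)))
    writeLines(paste0(">", names(seqs), "\n", seqs), fin)
    status <- system2(binary, c("--auto", "--quiet", fin),
                      stdout = fout, stderr = FALSE)
    if (status != 0) stop(binary, " exited with status ", status)
    aln <- Biostrings::readAAStringSet(fout)
    setNames(toupper(as.character(aln)), sub("\\s.*", "", names(aln)))
  }
  attr(f, "name") <- paste0("mafft(", binary, ")")
  f
}

#' @rdname run_tree
#' @param binary Path or name of the executable.
#' @export
fasttree_adapter <- function(binary = "fasttree") {
  f <- function(alignment) {
    if (Sys.which(binary) == "")
      stop("external tree builder not found on PATH: ", binary,
           " (install it or use stub_tree_adapter())")
    fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".nwk")
    on.exit(unlink(c(fin, fout)))
    writeLines(paste0(">", names(alignment), "\n", alignment), fin)
    status <- system2(binary, c("-quiet", fin), stdout = fout,
                      stderr = FALSE)
    if (status != 0) stop(binary, " exited with status ", status)
    paste(readLines(fout, warn = FALSE), collapse = "")
  }
  attr(f, "name") <- paste0("fasttree(", binary, ")")
  f
}

#' Choose one activity for tree annotation
#'
#' A protein with several EC numbers is annotated with a single one: the
#' first in lexicographic order of the dotted integer tuples (so
#' `3.2.1.4` precedes `3.2.1.176`); a warning is flagged when a choice was
#' made.
#'
#' @param ec_numbers Character vector of EC numbers (possibly empty).
#' @return List with `ec` (chosen EC or `NA`) and `warned` (logical).
#' @examples
#' pick_activity(c("3.2.1.176", "3.2.1.4"))
#' @export
pick_activity <- function(ec_numbers) {
  ec_numbers <- unique(ec_numbers)
  if (length(ec_numbers) == 0)
    return(list(ec = NA_character_, warned = FALSE))
  if (length(ec_numbers) == 1)
    return(list(ec = ec_numbers, warned = FALSE))
  key <- vapply(strsplit(ec_numbers, ".", fixed = TRUE), function(f) {
    f[f == "-"] <- "999999"
    sprintf("%06d.%06d.%06d.%06d", as.integer(f[1]), as.integer(f[2]),
            as.integer(f[3]), as.integer(f[4]))
  }, "")
  chosen <- ec_numbers[order(key)][1]
  warning("multiple activities (", paste(ec_numbers, collapse = ", "),
          "); only ", chosen, " will be used for tree annotation")
  list(ec = chosen, warned = TRUE)
}

#' Deterministic style map for domains and activities
#'
#' Assigns each domain name a unique (shape, colour) pair by round-robin
#' over the iTOL shape vocabulary and a fixed palette, in sorted-name order
#' (stable across runs).  EC label colours use a fixed base mapping for the
#' common glycoside-hydrolase activities and the palette for the rest;
#' injectivity is enforced.
#'
#' @param domain_names Character vector of domain names to style.
#' @param ec_numbers Character vector of EC numbers to colour.
#' @return A `style_map`: list with `domains` (data frame `name`, `shape`,
#'   `color`) and `ec_colors` (named character vector).
#' @export
default_style_map <- function(domain_names, ec_numbers = character()) {
  domain_names <- sort(unique(domain_names))
  n <- length(domain_names)
  shapes <- rep_len(ITOL_SHAPES, max(n, 1))
  colors <- rep_len(DOMAIN_PALETTE, max(n, 1))
  # offset colour cycle so (shape, colour) pairs stay unique well past
  # length(palette) assignments
  if (n > length(ITOL_SHAPES))
    colors <- DOMAIN_PALETTE[1 + ((seq_len(n) - 1 +
      (seq_len(n) - 1) %/% length(ITOL_SHAPES)) %% length(DOMAIN_PALETTE))]
  domains <- data.frame(name = domain_names,
                        shape = shapes[seq_len(n)],
                        color = colors[seq_len(n)],
                        stringsAsFactors = FALSE)
  if (anyDuplicated(paste(domains$shape, domains$color)))
    stop("style map not injective over domain names")
  ecs <- sort(unique(ec_numbers))
  ec_colors <- setNames(character(length(ecs)), ecs)
  known <- intersect(ecs, names(EC_BASE_COLORS))
  ec_colors[known] <- EC_BASE_COLORS[known]
  rest <- setdiff(ecs, known)
  pool <- setdiff(DOMAIN_PALETTE, ec_colors[known])
  if (length(rest) > length(pool))
    stop("not enough distinct label colours for ", length(ecs),
         " activities")
  ec_colors[rest] <- pool[seq_along(rest)]
  if (anyDuplicated(ec_colors))
    stop("EC colour assignment not injective")
  structure(list(domains = domains, ec_colors = ec_colors),
            class = "style_map")
}

#' Write the iTOL domain-architecture annotation file
#'
#' Emits a `DATASET_DOMAINS` file: a header block, then one DATA line per
#' tree leaf of the form
#' `id,protein_length,SHAPE|start|end|color|label,...` with 1-based
#' inclusive coordinates and shapes from the iTOL vocabulary.  Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param tree A `tree_bundle` from [run_tree()].
#' @param records A `protein_records` covering every leaf.
#' @param calls Consolidated `domain_calls`.
#' @param style A `style_map` from [default_style_map()].
#' @param path Output file.
#' @param label Dataset label shown in the legend.
#' @return `path`, invisibly.
#' @export
write_itol_domains <- function(tree, records, calls, style, path,
                               label = "Domain architectures") {
  leaves <- tree$included_ids
  idx <- match(leaves, records$protein_id)
  if (anyNA(idx))
    stop("leaf without protein record: ",
         paste(leaves[is.na(idx)], collapse = ", "))
  header <- c("DATASET_DOMAINS", "SEPARATOR COMMA",
              paste0("DATASET_LABEL,", label), "COLOR,#7f7f7f",
              "BORDER_WIDTH,1", "SHOW_DOMAIN_LABELS,0", "DATA")
  style_of <- style$domains
  lines <- vapply(seq_along(leaves), function(i) {
    pid <- leaves[i]
    plen <- nchar(records$sequence[idx[i]])
    pc <- calls[calls$protein_id == pid, , drop = FALSE]
    pc <- pc[order(pc$start, -pc$end), , drop = FALSE]
    if (nrow(pc) && (any(pc$start < 1) || any(pc$end > plen)))
      stop("domain call outside [1, protein length] for ", pid)
    srow <- match(pc$name, style_of$name)
    if (anyNA(srow))
      stop("no style for domain(s): ",
           paste(unique(pc$name[is.na(srow)]), collapse = ", "))
    fields <- sprintf("%s|%d|%d|%s|%s", style_of$shape[srow], pc$start,
                      pc$end, style_of$color[srow], pc$name)
    paste(c(pid, plen, fields), collapse = ",")
  }, "")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write the iTOL label-colour annotation file
#'
#' Emits a `TREE_COLORS` file colouring the labels of characterized leaves
#' by their (single, see [pick_activity()]) activity.
#'
#' @param tree A `tree_bundle`.
#' @param records A `protein_records` covering every leaf.
#' @param style A `style_map` providing `ec_colors`.
#' @param path Output file.
#' @return `path`, invisibly.  The chosen EC per leaf is returned in
#'   attribute `"activities"`.
#' @export
write_itol_labelcolors <- function(tree, records, style, path) {
  leaves <- tree$included_ids
  idx <- match(leaves, records$protein_id)
  if (anyNA(idx))
    stop("leaf without protein record: ",
         paste(leaves[is.na(idx)], collapse = ", "))
  header <- c("TREE_COLORS", "SEPARATOR SPACE", "DATA")
  lines <- character(); acts <- character()
  for (i in seq_along(leaves)) {
    if (!isTRUE(records$characterized[idx[i]])) next
    pick <- suppressWarnings(pick_activity(records$ec_numbers[[idx[i]]]))
    if (is.na(pick$ec)) next
    col <- unname(style$ec_colors[pick$ec])
    if (length(col) == 0 || is.na(col))
      stop("no label colour for EC ", pick$ec)
    lines <- c(lines, paste(leaves[i], "label", col, "normal"))
    acts[leaves[i]] <- pick$ec
  }
  writeLines(c(header, lines), path)
  res <- path
  attr(res, "activities") <- acts
  invisible(res)
}

#' Validate an iTOL DATASET_DOMAINS file
#'
#' Structural check against the published format: mandatory header lines,
#' consistent separator, and DATA lines of the form
#' `id,length,SHAPE|start|end|color|label,...` with known shapes, hex
#' colours and `1 <= start <= end <= length`.
#'
#' @param path File to validate.
#' @return Character vector of problems; empty when the file is valid.
#' @export
validate_itol_domains <- function(path) {
  lines <- readLines(path, warn = FALSE)
  problems <- character()
  if (length(lines) == 0 || lines[1] != "DATASET_DOMAINS")
    problems <- c(problems, "first line must be DATASET_DOMAINS")
  sep_line <- grep("^SEPARATOR ", lines, value = TRUE)
  sep <- if (length(sep_line)) {
    switch(sub("^SEPARATOR ", "", sep_line[1]),
           COMMA = ",", TAB = "\t", SPACE = " ", NA)
  } else NA
  if (is.na(sep)) problems <- c(problems, "missing/unknown SEPARATOR")
  if (!any(grepl("^DATASET_LABEL", lines)))
    problems <- c(problems, "missing DATASET_LABEL")
  if (!any(grepl("^COLOR", lines)))
    problems <- c(problems, "missing COLOR")
  data_at <- match("DATA", lines)
  if (is.na(data_at)) {
    problems <- c(problems, "missing DATA section")
    return(problems)
  }
  if (length(problems)) return(problems)
  for (ln in lines[seq_len(length(lines) - data_at) + data_at]) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, sep, fixed = TRUE)[[1]]
    if (length(f) < 2) {
      problems <- c(problems, paste("short DATA line:", ln)); next
    }
    plen <- suppressWarnings(as.integer(f[2]))
    if (!nzchar(f[1])) problems <- c(problems, "empty leaf id")
    if (is.na(plen) || plen < 1)
      problems <- c(problems, paste("bad protein length in:", ln))
    for (dom in f[-(1:2)]) {
      p <- strsplit(dom, "|", fixed = TRUE)[[1]]
      if (length(p) != 5) {
        problems <- c(problems, paste("bad domain field:", dom)); next
      }
      if (!(p[1] %in% ITOL_SHAPES))
        problems <- c(problems, paste("unknown shape:", p[1]))
      s <- suppressWarnings(as.integer(p[2]))
      e <- suppressWarnings(as.integer(p[3]))
      if (is.na(s) || is.na(e) || s < 1 || s > e || e > plen)
        problems <- c(problems, paste("bad coordinates in:", dom))
      if (!grepl("^#[0-9a-fA-F]{6}$", p[4]))
        problems <- c(problems, paste("bad colour:", p[4]))
    }
  }
  problems
}

#' Validate an iTOL TREE_COLORS file
#'
#' @param path File to validate.
#' @return Character vector of problems; empty when valid.
#' @export
validate_itol_treecolors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  problems <- character()
  if (length(lines) == 0 || lines[1] != "TREE_COLORS")
    problems <- c(problems, "first line must be TREE_COLORS")
  data_at <- match("DATA", lines)
  if (is.na(data_at)) return(c(problems, "missing DATA section"))
  for (ln in lines[seq_len(length(lines) - data_at) + data_at]) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, " ", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      problems <- c(problems, paste("short DATA line:", ln)); next
    }
    if (f[2] != "label")
      problems <- c(problems, paste("unsupported type:", f[2]))
    if (!grepl("^#[0-9a-fA-F]{6}$", f[3]))
      problems <- c(problems, paste("bad colour:", f[3]))
  }
  problems
}
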