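# Shared stash so later acceptance checks can reuse the large fixture
.acceptance_cache <- new.env(parent = emptyenv())

# Independent oracles and random-instance generators shared by the tests.
# All are written without touching the code paths they check.

# Brute-force maximum number of identical aligned pairs over all global
# alignments (match=1, mismatch=0, gap=0): plain recursion over the three
# alignment moves, feasible for sequences of length <= 8.
oracle_max_matches <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  rec <- function(i, j) {
    if (i > la || j > lb) return(0L)
    max(rec(i + 1L, j + 1L) + (A[i] == B[j]),
        rec(i + 1L, j),
        rec(i, j + 1L))
  }
  rec(1L, 1L)
}

# Independent reimplementation of the winner rule used in overlap
# resolution: database priority, span length, start, name, original index.
oracle_beats <- function(df, i, j, priority) {
  pr <- function(k) {
    r <- match(strsplit(df$source_db[k], ";", fixed = TRUE)[[1]], priority)
    r[is.na(r)] <- length(priority) + 1L
    min(r)
  }
  a <- pr(i); b <- pr(j)
  if (a != b) return(a < b)
  la <- df$end[i] - df$start[i]; lb <- df$end[j] - df$start[j]
  if (la != lb) return(la > lb)
  if (df$start[i] != df$start[j]) return(df$start[i] < df$start[j])
  if (df$name[i] != df$name[j]) return(df$name[i] < df$name[j])
  i < j
}

# Exhaustive brute-force overlap resolution: explores EVERY deletion order
# (any conflicting pair, in any order), memoized over annotation subsets,
# and returns the list of distinct terminal (conflict-free) sets.
oracle_fixpoints <- function(df, cfg) {
  memo <- new.env(parent = emptyenv())
  results <- new.env(parent = emptyenv())
  explore <- function(idx) {
    key <- paste(idx, collapse = ",")
    if (!is.null(memo[[key]])) return(invisible())
    memo[[key]] <- TRUE
    if (length(idx) >= 2) {
      cb <- utils::combn(idx, 2)
      ov <- overlap_fraction(df$start[cb[1, ]], df$end[cb[1, ]],
                             df$start[cb[2, ]], df$end[cb[2, ]])
      conf <- which(ov > cfg$overlap_threshold)
      if (length(conf)) {
        for (q in conf) {
          i <- cb[1, q]; j <- cb[2, q]
          loser <- if (oracle_beats(df, i, j, cfg$db_priority)) j else i
          explore(setdiff(idx, loser))
        }
        return(invisible())
      }
    }
    results[[key]] <- idx
  }
  explore(seq_len(nrow(df)))
  mget(ls(results), envir = results)
}

# Random region-stacked annotation instance: 1-3 well-separated true
# regions, each reported by 1-4 sources under distinct names with bounded
# boundary jitter -- the input shape overlap resolution is designed for.
# Truncated at 8 annotations so the brute-force oracle stays exhaustive.
rand_resolve_instance <- function() {
  nr <- sample(1:3, 1)
  names_pool <- paste0("Dom", LETTERS[1:10])
  dbs <- setdiff(SOURCE_DATABASES, "PHOBIUS")
  rows <- list()
  pos <- 0
  for (r in seq_len(nr)) {
    L <- sample(60:200, 1)
    s <- pos + 80 + 1
    e <- s + L - 1
    pos <- e
    nh <- sample(1:4, 1)
    nms <- sample(names_pool, nh)
    jl <- floor(0.15 * L)
    for (h in seq_len(nh)) {
      rows[[length(rows) + 1]] <- data.frame(
        protein_id = "P", source_db = sample(dbs, 1),
        accession = sprintf("A%03d", length(rows) + 1),
        name = nms[h],
        start = s + sample(seq(-min(jl, 35), jl), 1),
        end = e + sample(seq(-jl, min(jl, 35)), 1),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (nrow(df) > 8) df <- df[1:8, , drop = FALSE]
  df
}

# Independent tally of node/edge counts from raw architecture strings.
recount_network <- function(arch_strings) {
  nodes <- list(); edges <- list()
  for (a in arch_strings[nzchar(arch_strings)]) {
    nm <- strsplit(a, " + ", fixed = TRUE)[[1]]
    for (x in nm) nodes[[x]] <- (nodes[[x]] %||% 0L) + 1L
    if (length(nm) >= 2)
      for (i in seq_len(length(nm) - 1)) {
        key <- paste(sort(nm[i:(i + 1)]), collapse = "\r")
        edges[[key]] <- (edges[[key]] %||% 0L) + 1L
      }
  }
  list(nodes = unlist(nodes), edges = unlist(edges))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_protein <- function(n = 1, len = 30) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i)
    paste(sample(aa, len, replace = TRUE), collapse = ""), "")
}
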