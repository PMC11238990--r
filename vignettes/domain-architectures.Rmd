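---
title: "Consolidating multi-database domain annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating multi-database domain annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domarch)
```

# The problem and the model

A protein family annotated against several signature databases yields a
redundant stack of domain hits: each true domain is reported by multiple
databases under different signature names, with boundaries that differ by a
modest jitter, alongside nuisance annotations — signal peptides, hits with
no usable name, conserved-site calls far below domain size, and
super-annotations spanning several domains at once. The package's central
object is therefore not a single hit but the *consolidated architecture*:
the ordered N→C list of curated domain names of one protein, written
canonically as `"CBM + Immunoglobulin-like + Catalytic domain"`.

Consolidation proceeds in four stages, in this order:

1. **Curation**: raw signature names are mapped to user-chosen overarching
   names (`curation_map()`); every applied substitution is logged and later
   persisted in the `DomainCuration` table.
2. **Eligibility** (`is_eligible()`): a hit is removed when its name is
   missing (`"None"` or empty), when it encodes a signal peptide (name
   containing a `SIGNAL` marker or source PHOBIUS), or when its span length
   lies outside the size window.
3. **Same-name merging** (`merge_same_name()`): within one protein,
   same-curated-name hits whose spans form an overlapping chain are
   replaced by a single span from the outermost start to the outermost end,
   with sources and accessions unioned. Disjoint same-name spans are *not*
   merged — repeat domains are biologically real.
4. **Overlap resolution** (`resolve_overlaps()`): remaining conflicts
   between different names are resolved iteratively until no retained pair
   overlaps above the threshold.

## Overlap measure

Two spans conflict when `|a ∩ b| / min(|a|, |b|) > t`, all lengths counted
1-based inclusive. The *shorter-span* denominator is a deliberate choice:
the threshold's provenance does not fix a denominator, and dividing by the
shorter span is the conservative reading — a small hit fully contained in a
large one always scores 1 and is guaranteed to be resolved, which is the
behaviour one wants for nested redundant calls. The default threshold is
0.31 and the default size window 10–800 AA; both are exposed in
`consolidation_config()` and can be tightened or relaxed per family.

## Winner rule and order independence

When a conflicting pair must lose one member, the winner is chosen by a
fixed chain: better source-database priority (default order
`r paste(head(DEFAULT_DB_PRIORITY, 4), collapse = ", ")`, …, fully
user-overridable), then longer span, then smaller start, then
lexicographically smaller name, then input order. The chain is a *strict
total order* over annotations, which makes each pairwise decision
deterministic.

The scan itself walks adjacent pairs in (start ↑, end ↓, priority) order
and restarts after each deletion; once no adjacent pair conflicts, a full
pairwise sweep runs so that the post-condition — no retained pair above the
threshold — holds unconditionally and is asserted on every call.

A note on uniqueness: for arbitrary interval configurations, iterative
pair deletion is not confluent — chains in which `a` beats `b`, `b` beats
`c`, but `a` and `c` are disjoint can end differently depending on which
conflict is resolved first. In the regime consolidation is designed for,
however, conflicts are *region-local cliques*: all redundant hits of one
region overlap each other pairwise (the jitter bound below guarantees
this), and hits of different regions do not conflict at all. Within a
clique every deletion order eliminates everything but the top-ranked
element, so the fixpoint is unique. The test suite verifies exactly this:
a brute-force oracle enumerates *all* deletion orders on a thousand random
region-stacked instances and checks that a single common fixpoint exists
and equals the iterative result. Inputs that violate the clique structure
(e.g. a 400-AA span bridging two regions that survives the size filter)
are still resolved deterministically by the fixed scan order — but their
fixpoint is then a property of that order, which is why the scan order is
part of the documented contract rather than an implementation detail.

## Merging before resolving

Whether split same-name calls should be merged before or after overlap
resolution is genuinely open. Merging first was chosen because the split
calls that motivate merging are partial detections of *one* domain by
*different* databases; resolving first would delete one of the fragments
and lose the outermost boundary information that the merge is meant to
recover. Merge-first also keeps the resolution input cleaner: after
merging, every remaining conflict is a genuine cross-name disagreement.

# Sequence preparation

Identity everywhere in the package is the global-alignment score under
match = 1, mismatch = 0, gap = 0 — the default scoring of the classic
simple pairwise aligners, under which the optimal score equals the maximal
number of identically aligned residue pairs. The denominator varies by
purpose and is always stated: the *longer* length for domain-level
comparisons, the *shorter* length for clustering (the CD-HIT convention;
flags containment), the *query* length for characterized-protein rescue
and for attributing sequences to architectures. The aligner is a small
dynamic program in C++ (`src/alignment.cpp`); an independent pure-R
recursion over the alignment recurrence serves as its oracle in the tests
for short sequences.

Clustering is greedy and incremental in the CD-HIT style: sequences sorted
by length descending found clusters in order, each joining the first
representative at identity ≥ 0.85 (default) with sufficient
aligned-region coverage (both coverage knobs default to 0). The exact
word-filter heuristics of the external tool are not reproduced — the
contract is the membership guarantee, asserted in tests: every member
reaches the threshold against its representative. An external `cd-hit`
can be slotted behind the same contract when scale demands it.

Characterized proteins are never lost: after clustering they are re-added,
and a characterized identifier missing from the dataset entirely is
replaced by its best rescue-pool hit if identical-matches / query-length
≥ 0.95 (default), otherwise logged as unrescued. The rescue similarity
needs the query's sequence, so external sequences can be supplied via
`characterized_seqs`; ids absent from both are logged and skipped.

# Architecture analysis and the network

`enumerate_assemblies()` groups proteins by canonical architecture string;
member lists partition the proteins with at least one call, and the table
is sorted by member count. Order matters: `A + B` and `B + A` are distinct
assemblies. `attribute_sequences()` assigns further sequences to the
architecture of their best-identity representative when identity (over the
query length) reaches 0.85 — the same value as the clustering threshold,
chosen because attribution answers the same question as cluster
membership; it is a flag on the CLI.

The co-occurrence network counts each domain instance once per member
protein (node weight) and each *consecutive* pair in an architecture once
per member (edge weight); identical neighbours produce self-loops.
Counting only adjacencies, not all co-membership pairs, is deliberate:
adjacency is what the architecture string encodes and what the edge
widths of the exported graph are meant to show. Both counting universes —
the analyzed (clustered + characterized) set via per-protein strings, or
assemblies weighted by member counts — are available, since either can be
the quantity of interest.

# Tree annotation

External alignment and tree inference run strictly behind adapters with a
fixed contract (named sequences in, equal-width alignment / Newick with
the same leaf set out); `mafft` and `fasttree` adapters are provided, and
dependency-free stubs make every downstream step testable offline.
Domainless proteins are excluded from the alignment — they have nothing to
annotate — and the exclusion is logged. A characterized protein with
several EC numbers is annotated with a single one, the smallest in dotted
integer-tuple order (so `3.2.1.4` precedes `3.2.1.176`), with a warning;
the choice is arbitrary but deterministic. Domain glyphs and activity
colours are assigned round-robin over the iTOL shape vocabulary and a
fixed palette in sorted-name order, so style maps are injective and stable
across runs; both annotation files are byte-deterministic, and an included
validator checks the structural grammar (header block, separator,
shape vocabulary, in-bounds coordinates).

# Domain evolution statistics

Domains are excised by their stored boundaries (`substr(seq, s, e)`,
length `e − s + 1`), and within-group identities are computed over all
unordered pairs, self-pairs excluded. The Kruskal–Wallis test is the
standard tie-corrected rank test (delegated to `stats::kruskal.test`; the
degenerate all-identical case is defined as H = 0, p = 1). Dunn's post hoc
z uses the pooled mid-ranks with tie correction, two-sided normal
p-values, and Bonferroni adjustment by default (Holm and none are
available) — Bonferroni because the number of pairs is small and the cost
of a conservative default is negligible. Percent identities are reported
×100 in summaries and stored as fractions internally.

One caveat is inherent to the design, not the implementation: the
`choose(n, 2)` pairwise identities of a group are not independent
observations, so the rank tests' nominal error rates are approximate. The
tests therefore check the *qualitative* pattern (divergent group separated
at p < 0.001, equal-rate groups not significant), which is robust across
seeds at the scales used.

# The synthetic generator

`generate_fixture()` emulates exactly the input statistics the consolidation
algorithm is designed for: every planted domain is reported by several
distinct databases under database-specific raw names (exercising curation),
with bounded boundary jitter, plus decoys of each nuisance class. Two
quantitative guarantees make recovery provable rather than probabilistic:

* **Jitter bound.** If each edge of a length-`L` region moves by at most
  `j·L`, two hits of that region overlap by at least `(1−2j)/(1+2j)` of
  the shorter. Requiring this to exceed the threshold gives
  `j < (1−t)/(2(1+t))` — 0.2634 for t = 0.31. The default `j = 0.10` is
  asserted against this bound at spec construction, and every generated
  hit's overlap with its truth region is asserted at generation time.
* **Linker clamp.** Outward jitter is additionally clamped to less than
  half the flanking linker, so hits of adjacent distinct domains never
  touch: conflicts are region-local cliques, the regime in which the
  resolution fixpoint is provably unique.

What the generator does *not* emulate: realistic residue composition
(sequences are uniform over the 20 canonical amino acids), HMM-like
emission of domain sequences, database-specific boundary biases, or
annotation coverage gaps (every planted domain is seen by at least one
source). Passing the recovery tests therefore demonstrates the
correctness of the interval algebra, curation, and bookkeeping — not that
real InterPro stacks always satisfy the clique regime; on real data the
size filter and threshold do that job imperfectly, which is why both are
user-tunable and every drop is logged with its reason.

Sampling weights over the architecture pool are honoured after a coverage
pass that assigns pool entry *i* to protein *i*, so "recovers exactly the
planted set of architectures" is a deterministic statement.

# Problem sizes and numerical choices

The shipped test suite runs the full property checks at the scales the
package documents as its reference conditions: 1,000 random instances (≤ 8
annotations) for the resolution oracle; 200 proteins × 35 architectures ×
3 sources with all decoy classes for recovery; 500 random short pairs for
the alignment oracle; 5 families × 10 mutants at 5 % divergence for
clustering; groups of 36/28/20 domains at 5 %/5 %/25 % substitution for
the statistics. These sizes give exact (not asymptotic) guarantees for the
combinatorial checks while keeping the whole suite in well under a minute
of alignment work.

Remaining numerical conventions, in one place: all coordinates are 1-based
inclusive everywhere (file formats, store, memory); the missing-name
marker is the literal string `"None"`, with the empty string treated
identically; the `SIGNAL` marker match is case-sensitive (the upstream
convention writes it in capitals) and overridable; annotation records with
inverted coordinates are skipped with a warning rather than failing the
whole file; and the store refuses to save when the assemblies table does
not exactly account for the proteins' architectures.

# Known limitations

* The greedy clusterer is quadratic in the number of clusters × sequences;
  for families beyond a few thousand representatives the external-tool
  adapter is the intended path.
* Attribution requires no minimum alignment coverage of the hit beyond the
  identity itself; a short query contained in a long representative can
  attribute at high identity. The identity denominator (query length)
  bounds the damage but does not eliminate it.
* Taxonomy metadata is taken as input and never reconciled against an
  external taxonomy; conflicting sources are the caller's problem.
* The rank tests treat pairwise identities as exchangeable observations
  (see above); p-values near the significance boundary should not be
  over-read.
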