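---
title: "Comparing taxonomic profiles on a taxonomy tree"
author: "cladescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing taxonomic profiles on a taxonomy tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladescope)
```

## The problem

Shotgun metagenomic taxonomic profilers estimate, for one sequenced
community, the identity and relative abundance (in percent) of the taxa
present, reported per taxonomic rank. Dozens of profilers exist and their
outputs differ substantially, yet benchmarking practice compresses those
differences into single-valued metrics (L1 norm, F1 score, UniFrac-type
distances) that say *how much* two profiles differ but not *where on the
tree of life* they differ. Two tools can share an identical summary score
while disagreeing wildly about which phyla are present.

`cladescope` addresses the interpretability gap: it merges up to three
profiles — optionally together with the gold-standard composition of a
simulated sample — onto a single taxonomy tree, quantifies agreement clade
by clade, and renders the result as a figure in which each clade is a disc
whose size encodes total relative abundance and whose color encodes either
the per-source abundance split (normal mode) or the clade's classification
against the truth (contrast mode).

## The comparison model

Inputs are taxonomic profiles in the community CAMI/Bioboxes profiling
format (header keys `@SampleID`, `@Ranks`; columns `TAXID`, `RANK`,
`TAXPATH`, `TAXPATHSN`, `PERCENTAGE`) or BIOM 1.0 JSON tables (counts are
converted to percentage shares of the sample total, aggregated along each
observation's lineage). Lineages are placed via the `TAXPATH` column and,
when an NCBI-style taxonomy dump (`nodes.dmp`/`names.dmp`, optionally
`merged.dmp`) is supplied, cross-checked against it: deprecated identifiers
are merged-resolved transitively, and on any rank or name conflict the dump
wins, with a warning naming both values. The precedence rule is a design
choice: the taxonomy dump is the single arbiter of tree structure, so
profiles from tools pinned to slightly different taxonomy versions still
land on one consistent tree. Users may point the loader at any alternate
dump written in the same dmp dialect.

The union of all lineages forms the comparison tree. Each node carries one
abundance per source. Sources that imply an ancestor through a lineage but
never report it directly get that ancestor imputed as the sum of the
source's abundances over the node's children, computed bottom-up and
flagged as imputed. The alternative — zeroing unreported ancestors — would
manufacture spurious false positives at upper ranks for the many profilers
that emit only their deepest rank, which is why imputation is the default
and is not configurable. Rank restriction (`rank_limit`) is applied *after*
imputation for the same reason. A consequence worth knowing when reading
the figures: an imputed ancestor is exactly the sum of its children, while
a reported ancestor may exceed that sum (mass a tool could not place at the
deeper rank); the parent can never fall below the child sum beyond float
noise.

### Classification and error

With a truth profile present, every node is classified by support-set
logic, using an absence cutoff `epsilon` (default `1e-9`, absorbing float
noise in tool outputs):

* **FP** — some tool reports the taxon, the truth does not;
* **FN** — the truth contains the taxon, no tool reports it;
* **TP** — both do; its relative error is `|mean(tool abundances) − truth| / truth`.

The mean over tools is a deliberate choice for the multi-tool case: the
one-tool-versus-truth definition generalizes several ways, and the mean is
the one that is symmetric in the tools and reduces to the familiar
definition for a single tool.

### Highlighting and L1

A clade is highlighted when abundances disagree by more than a threshold,
default 30, read as **percentage points** with **strict** inequality: a
difference of exactly 30 is not highlighted. Percentage points (rather than
a relative ratio) is the interpretation consistent with comparing
quantities that are themselves percentages, and it is user-overridable
(`highlight_threshold` / `--threshold`) precisely because it is a
convention. The per-rank L1 error is the sum of absolute abundance
differences over all nodes at a rank: 0 for identical profiles, 200 for
disjoint per-rank-normalized profiles.

Two optional transformations precede the comparison: `min_abundance`
filtering removes entries *strictly below* the threshold (at-threshold
entries survive, so a filter at a tool's reporting limit keeps borderline
calls), and `normalize` rescales each rank independently to sum to 100.
Normalization is **off** by default: profiles whose ranks do not sum to 100
usually indicate a tool bug or unassigned mass, and silently rescaling
would hide that. Abundances that all lie in `[0, 1]` trigger a
fraction-scale warning at parse time but are stored as given; the warning
fires only when *every* positive value is at most 1, since individual
abundances below 1% are perfectly normal.

## Rendering

Disc radius maps total clade abundance (summed over the sources drawn)
through one of four scalings — with `m` the maximum radius, `a` the
abundance and `A` the figure maximum: linear `m·a/A`, square-root
`m·√(a/A)`, `m·log(1+a)/log(1+A)` (the `1+` admits zero), or power
`m·(a/A)^p`. All are strictly increasing and reach `m` at the maximum.
Discs below `max_radius/50` are drawn at that floor so rare but present
clades stay visible.

In normal mode each disc is split among the sources in proportion to their
abundance share (pie arcs in the `pie`, `circle` and `rectangular`
layouts; stacked bars in `bar`); agreeing tools give equal halves. Default
source colors are green, orange, purple in order, so a single tool versus
truth renders green versus orange. In contrast mode the fill is red for
FP, blue for FN, and for TP a linear RGB interpolation from white toward
green `(0, 128, 0)` with intensity `min(relative error, 1)` — the midpoint
at error 0.5 is `#80C080`. The green endpoint and the clamp at 1 are
configurable decisions: "intensity proportional to the error" needs a
bounded map, and clamping at 100% relative error keeps the gradient
informative in the range where most disagreements live. Highlighted clades
get blue label text.

Layouts are deterministic: leaves are placed in depth-first order with
children sorted by taxid, evenly spaced by `leaf_separation` (rectangular
family) or by angle (circle); internal nodes sit at the mean position of
their children. SVG is the canonical output and is byte-identical across
runs of the same inputs — numbers are printed with fixed precision, fonts
are referenced by family name, and nothing timestamped enters the file —
which is what makes figure output testable by hash. PNG export draws the
same resolved layout directly on an R graphics device at the requested
pixel width; it is a convenience raster, not the reference artifact, and
is skipped with a warning on systems without a PNG device.

## The synthetic-data generator

`generate_taxdump()` and `generate_profile_set()` produce a balanced
three-rank taxonomy (superkingdom/phylum/class) and a ground truth plus
perturbed tool profiles, entirely in memory or as the same dmp/CAMI files
the parsers consume. The truth draws a symmetric Dirichlet over the active
class-level taxa, scales to percentages, and propagates upward by
summation, so every parent equals its children's sum exactly and every
rank sums to 100. Each tool then independently:

1. drops each true taxon with probability `dropout_prob` (intended false
   negatives),
2. injects taxa absent from the truth with probability `spurious_prob`
   each, at uniform (0, 5]% abundance (intended false positives),
3. perturbs surviving abundances with multiplicative lognormal noise of
   coefficient of variation `noise_cv`, then
4. propagates up and renormalizes each rank to 100.

Noise precedes renormalization, and renormalization preserves support, so
the perturbation record — which logs, per tool, the dropped and injected
taxa and their rank-propagated support differences, plus the derived
expected FP set (union of injections) and FN set (intersection of
propagated dropouts) — remains exactly recoverable by the comparison
pipeline. All randomness flows from one seed, with tool `t` drawing from
the derived stream `seed + t`.

Defaults are one fixed choice of study conditions, not tuning knobs: a
community of 8 active taxa under Dirichlet(1) abundances, 30% dropout, 20%
spurious injection, 20% noise — per-taxon error rates in the range
community benchmarks report for shotgun profilers, on a taxonomy small
enough (2 superkingdoms × 3 phyla × 3 classes) that tests and the
acceptance script run in seconds. What the generator does *not* emulate:
real taxonomies are deep, unbalanced and contain unranked nodes beyond the
one at the root; real profiler errors are correlated with abundance and
phylogeny rather than independent per taxon; and real gold standards
contain strain-level structure. Passing tests therefore demonstrate the
correctness of the bookkeeping — parsing, tree building, imputation,
classification, rendering — not robustness to any particular profiler's
error signature.

## A worked example

```{r example}
spec <- synthetic_spec(seed = 7)
td <- generate_taxdump(spec)
gp <- generate_profile_set(spec, td$db, n_tools = 2)
tree <- build_comparison_tree(gp$set, td$db)
tree
assessment <- assess_nodes(tree)
table(assessment$status)
l1_error(tree, "tool1", "truth", "phylum")
head(abundance_summary(tree), 4)
```

Rendering the same tree in contrast mode against the truth:

```{r render, eval = FALSE}
opts <- render_options(mode = "contrast", layout = "rectangular")
spec_r <- layout_tree(tree, opts, assessments = assessment)
render_svg(spec_r, opts, "comparison.svg")
```

The identical pipeline is exposed as a command line (installed under
`exec/`), following the conventional flag set of profile-evaluation tools:

```sh
cladescope -i tool1.profile -i tool2.profile -g truth.profile \
  -s S1 -b comparison -k linear -r 1600 -o results --db taxdump/ --plot-l1
```

## Numerical choices and degenerate inputs

* Absence cutoff `epsilon = 1e-9`; highlight threshold strict, in
  percentage points; at-threshold abundance filtering keeps the entry.
* Duplicate `(taxid, rank)` rows in one sample block are summed with a
  warning (tolerant parsing, mirroring evaluation-platform behavior);
  rows before a `@@` column line, short rows, and non-numeric percentages
  are hard errors naming the line.
* Empty `TAXPATH` placeholder segments are assigned ranks by position
  against the declared `@Ranks` order; an entirely empty `TAXPATH` is an
  error.
* Report rows are ordered by rank, then descending truth abundance, then
  lexicographic taxid — the tie-break makes TSV output reproducible.
* An empty tool profile (total dropout) is legal and yields all-FN
  assessments; an empty union across all sources is an error.
* Profiles may declare any format version tag; it is recorded and not
  interpreted.

## Limitations

Single-machine, in-memory processing aimed at profile-scale data (tens of
ranks, thousands of taxa), not read-level data. BIOM 2.x HDF5 is out of
scope (BIOM 1.0 JSON only), as are benchmark metrics other than per-rank
L1 — precision/recall/F1 and UniFrac belong to dedicated benchmarking
platforms, which this package complements rather than replaces. Figures
are static SVG/PNG; no interactive viewer.
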