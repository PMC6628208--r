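---
title: "Merging screen-derived gene lists into testable network models"
author: "netweaver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging screen-derived gene lists into testable network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netweaver)
```

## The model

A genome-wide screen for a core gene — a DamID or ChIP profile of a
transcription factor, a differential-expression list after a genetic
manipulation, a proteomic interactor list — yields a single list of
targets. netweaver represents each list as a *wheel network*: a star with
the core at the hub and one directed edge `core -> target` per target,
labelled with the screen's technique (`DamID`, `RNAseq`, ...). Merging
wheels is a union: nodes are keyed by primary identifier, edges are unique
on `(source, target, interaction type)`, and a target reported by two
screens becomes a node of in-degree two that interconnects the wheels. The
model is deliberately heuristic: an edge asserts only that a screen
reported the target, not a validated regulatory interaction. The package's
outputs are hypotheses to rank and test, not discoveries.

Two assumptions are built in. First, all merged datasets describe one
organism; the merge refuses mixed organisms rather than attempt orthology
mapping. Second, screen edges point outward from the core, because the
screen only ever observes the core acting on (or binding near) the target.
Curated genetic/physical interactions retrieved through the resolver are
stored as unordered pairs with a recorded query gene and emitted as
`query -> partner`, since the curated data assert no direction; this is
what lets feedback 2-cycles appear when a target is known to act back on
its core.

## Identifier resolution

Screens published years apart use stale identifiers. The resolver contract
(`validateCoreSymbol`, `resolveIdentifiers`, `fetchInteractions`) has two
backends: a live InterMine web-service client, and a local-table backend
driven by two CSV files (submitted id → primary id/symbol/secondary;
pairwise interactions with a `genetic`/`physical` kind). All tests and
examples run against the local backend, which is a pure function of its
tables — identical inputs give byte-identical outputs.

Three policies were genuinely open and are fixed as follows:

* **Symbol case.** Exact symbol match first; if that fails, a
  case-insensitive match is accepted with a warning. Users type symbols in
  lowercase while database symbols vary in case; failing hard on `Esg`
  vs. `esg` helps no one, but silent case-folding could mask a genuine
  typo, hence the warning.
* **Unresolved identifiers.** Kept by default as pass-through nodes whose
  primary identifier is the submitted text, with a warning
  (`passThrough = FALSE` drops them instead). Unresolved inputs are always
  reported; they are never silently dropped. Pass-through keeps network
  sizes stable and keeps the unresolved genes visible in Cytoscape, where
  they are usually recognisable at a glance.
* **Independent switches.** Identifier updating and interaction retrieval
  are independent operations: a session may decline interaction
  integration yet still update identifiers (the attribute builder always
  updates, so attribute rows key onto the same primary identifiers the
  network file uses).

## Output formats

The network CSV has a fixed seven-column header — `Source Symbol`,
`Source Primary Identifier`, `Source Secondary Identifier`,
`Interaction Type`, `Target Symbol`, `Target Primary Identifier`,
`Target Secondary Identifier` — one row per edge, in dataset-registration
order then input row order, so reruns diff cleanly. The attribute CSV has
`Mapping Key` (the node primary identifier) first and one column per
attribute in load order, with exactly one row per network node: nodes
matched by no attribute table still get a row, because the Cytoscape style
for "not in the dataset" is itself informative. Membership (List)
attributes are written as literal `true`/`false` rather than `1`/`0`,
matching how discrete style mappings are usually configured; valued
attributes are passed through as text exactly as read, avoiding
float-round-trip surprises. Writing follows RFC 4180 (fields quoted only
when they contain a comma, quote or line break; quotes doubled; UTF-8
without a byte-order mark, though a BOM is tolerated on read). Within one
attribute table, a duplicated identifier keeps the last value with a
warning; a duplicated attribute *name* across tables is an error.

Tabular ingestion policies: empty cells mean "absent" in identifier and
replicate columns (matching spreadsheet exports); rows shorter than the
header are padded with empty cells, longer rows are rejected; duplicate
header names get `_2`, `_3` suffixes so column addressing stays
unambiguous; `topNByMean` breaks ties by input row order (earlier row
wins), which is deterministic and matches how a spreadsheet sort behaves.

## Filtration and partitioning

`degreeFilter` implements the terminal-node/linear-path pruning used to
isolate feedback-rich cores from interaction-enriched networks: per pass,
degrees are computed on the current network, nodes below the threshold
(default 2) are removed, and the induced subgraph feeds the next pass.
Choices that needed fixing:

* **Degree semantics.** Default `total` (in + out), with parallel edges of
  different interaction types counted once per `(source, target)` pair —
  this reproduces the intuitive "terminal node" reading, where a node
  touched by a single neighbour is terminal regardless of edge
  multiplicity or direction. An `in_or_out` mode (keep when either
  in-degree or out-degree meets the threshold) is exposed because the
  criterion is sometimes read that way; both modes are tested against an
  independent iterative-pruning oracle.
* **Passes.** Two passes by default — the first removes terminal nodes,
  the second removes the linkers that thereby became terminal. Two passes
  do not remove arbitrarily long linear paths, so `fixpoint = TRUE`
  iterates to stability; the fixpoint is idempotent and preserves every
  cycle (each node of a 2-cycle has total degree 2), which is exactly the
  feedback structure the filtration is meant to expose.
* **No core protection.** Cores are filtered like any other node; a core
  whose wheel is all terminal nodes disappears with it, which is the
  honest outcome.

`coTargetPartition` assigns each non-core node with at least one inbound
core edge to the block keyed by the *exact* set of cores targeting it
(mono-, di-, tri-regulated clusters). Blocks are disjoint and exhaustive
over core-targeted nodes by construction, and both properties are asserted
in the class validity.

## The enrichment statistic

The reported quantity is the exact hypergeometric **point mass**
`P(X = x) = C(m, x) C(n, k−x) / C(m+n, k)` — the probability of the
observed count itself, in `dhyper` parameterization — not the Fisher-style
tail `P(X ≥ x)`; the tail and a Bonferroni-adjusted column are available
behind flags (`tail = TRUE`, `bonferroni = TRUE`), and no multiple-testing
correction is applied by default. Per-wheel rows are tested against the
genome background; multi-core blocks default to the whole network as
background, since the interesting question for a co-regulated subset is
enrichment *beyond* the combined wheels.

Numerically, the mass is evaluated in log space. The naive difference of
three log-binomials loses ~4 digits to cancellation at genome scale
(`m + n` around 2 × 10⁴), so the implementation uses the saddle-point
(deviance) form: each log-binomial is decomposed so the large Stirling
terms cancel analytically, leaving only a log-gamma-backed Stirling error
series and a binomial deviance evaluated by a stable series near its
minimum. The result is accurate to better than ten significant digits for
counts up to 10⁶; point masses over a full support sum to 1 within 10⁻¹²,
and the implementation is checked exhaustively against exact big-integer
rational arithmetic for all populations `m + n ≤ 60`. Degenerate inputs
(`m = 0`, `k = 0`, `k = m + n`) fall out of the same code path; arguments
outside the hypergeometric support raise a domain error rather than
returning 0, since an impossible count in an enrichment table is always a
bookkeeping bug upstream.

The acceptance script (`scripts/acceptance.R`) recomputes the four
headline statistics of the intestinal-stem-cell case study from its
published counts. One bookkeeping choice: two of the stated
per-wheel totals are off by one from the counts that reproduce the
published probabilities — 1072 where the corresponding processed target
list holds 1071 genes, and 309 where the high/not-high split sums to
37 + 271 = 308 — evidently because the stated totals include the core
gene itself. The script uses the split-consistent sample sizes (1071 and
308); the remaining counts are consistent as stated (3692 = 550 + 3142;
8 of 23).

## The synthetic-fixture generator

`generateFixtureSuite` is first-class, tested code: it emulates a
multi-screen study with known planted truth so every downstream claim is
checkable offline. Its defaults *are* the study conditions of the
case study and are not tuned per run:

* three cores with target-list sizes **1072, 3692, 309** drawn from a
  universe of **15682** genes, with a three-way overlap block of **23**
  genes; pairwise overlaps are not published, so they were fixed once at
  150/70/60 — DamID-scale overlaps that keep every inclusion–exclusion
  block positive;
* a background high-expression rate of **1251/15682** and a planted rate
  of **8/23** in the three-way block, values uniform on the correct side
  of the RPKM-50 threshold, so threshold classification recovers the
  planted truth exactly;
* **10 %** of submitted identifiers are stale aliases the resolver must
  update, 2 planted feedback edges (target back onto its core, forming
  2-cycles that must survive fixpoint filtration) and 3 leaf edges to
  outsider genes (which the first filtration pass must remove).

Exclusive blocks are constructed by direct assignment, never rejection
sampling, so the planted truth is exact; every generator is a pure
function of spec + seed and reruns byte-identically (the global RNG state
is saved and restored around each call). Identifiers follow a
FlyBase-like fixed-width pattern (`SYN0000001`) so format-sensitive code
paths are exercised.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: realistic DamID signal or RNA-seq count
distributions (only the combinatorial and threshold structure downstream
analyses consume), identifier-mapping ambiguity (one-to-many or merged
gene models; the alias map is a bijection), organism mixtures, and the
coverage biases of curated interaction databases. The end-to-end recovery
tests demonstrate correctness of the bookkeeping, not power on noisy
screens.

## Test problem sizes

The suite exercises: exhaustive oracle comparison over all hypergeometric
instances with `m + n ≤ 60` (~8 × 10⁵ masses against exact rational
arithmetic); 1000 randomized supports with parameters up to 10⁴ for the
normalization bound; 500 random directed graphs of up to 30 nodes against
the independent pruning oracle (plus a hand-worked five-node case checked
edge-for-edge in two-pass mode); and 20 seeded end-to-end runs at full
study scale (universe 15682) recovering every planted block exactly and
the planted enrichment direction in at least 18 of 20 seeds. These sizes
were chosen to cover the regimes the analyses run at while keeping a full
test run around half a minute.

## Known limitations

The live InterMine backend is a thin client over the JSON web service and
is exercised only through its offline twin; service schema drift would
surface at run time, not in the tests. Interaction snapshots change over
time, so networks built with the live backend are dated the day they are
built — exact reproduction of a historical network requires the local
backend with archived tables. Gene Ontology list retrieval, Cytoscape
styling and layout, edge attributes, and non-InterMine services are out of
scope: the package ends at files Cytoscape imports.
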