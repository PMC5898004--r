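---
title: "Structural diffing and evolution statistics for model version histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural diffing and evolution statistics for model version histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modevol)
```

## The problem

Computational biology models published in open repositories are living
documents: species get added, kinetic parameters corrected, annotations
rewritten, whole reaction subtrees restructured. Because SBML and CellML are
XML dialects, every one of those edits is a change to an XML tree, and a
model's public history is a sequence of tree versions. `modevol` computes
what changed between versions — as a typed edit script over the tree, not a
textual diff — classifies each operation with COMODI-style terms, and
aggregates whole histories into the three standard evolution tables
(per-version *filestats*, per-transition *diffstats*, and the repository
time series *repo-evolution*).

Repository-scale headline figures depend on the state of external
repositories at a particular time and are not reproducible from a desk, so
the package carries its own ground truth: a synthetic history generator
that plants known edit scripts. Every claim the test suite makes is checked
against those planted ledgers or against independent oracles
(Zhang–Shasha tree edit distance, a quadratic LCS).

## Canonical form

All comparisons run on a canonicalized tree: attributes sorted by name,
namespace prefixes rewritten to a stable table (the root's namespace
becomes the default, others get `ns2`, `ns3`, … in order of first
appearance), inter-element whitespace dropped, and text trimmed and
whitespace-collapsed — except inside `notes`, `annotation` and
`documentation` subtrees, where text is preserved verbatim. The rationale:
a diff must not report cosmetic serialization differences, but
human-readable description text is semantically meaningful (repository-wide
mass updates have historically been exactly such notes rewrites).
Whitespace-only text nodes are dropped everywhere, including notes;
indentation inside a notes block carries no meaning even though its words
do.

"XML nodes" in all counts means **element nodes only**. Attributes and text
are not counted, which keeps the size figure comparable between SBML and
CellML and independent of annotation verbosity. Entity counts are
format-native: an SBML document always reports zero `variables` and
`components`, a CellML document zero `species`, `reactions`, and so on. All
SBML rule dialects (algebraic/assignment/rate plus the Level 1 variants)
fold into one `rules` figure.

## The diff model

A delta between two versions is a set of operations, each one of
`insert`/`delete`/`update`/`move` applied to an `element`, `attribute`, or
`text` node, addressed by an XPath-like path with 1-based ranks among
same-label siblings. Operations on strict descendants of an inserted or
deleted subtree are flagged *triggered*: they are implied by the subtree
operation. Triggered operations are included in all summary counts (a CLI
flag excludes them from the human-readable listing).

### Matching

The tree matcher is deterministic and runs in passes:

1. **Identity.** Elements whose `(label, id)` key — `id`/`metaid`/`name` —
   is unique in both trees are paired.
2. **Propagation to a fixpoint.** Matched parents pair children that are
   unique by label or by `(label, id)` within that parent; matched children
   pair their parents when labels agree.
3. **Rank alignment.** Residual same-label children of matched parents
   whose sibling ranks coincide exactly are paired by rank. This pins
   elements whose content changed beyond recognition (a notes paragraph
   whose text was replaced) without risking a pairing between a deleted
   element and an unrelated inserted sibling, whose ranks differ.
4. **Similarity.** Remaining same-label elements are paired greedily by
   Jaccard similarity of subtree tokens (labels, attribute names, attribute
   values, text words) at a threshold of 0.7, ties broken by document
   order. Two refinements matter in practice:
   * *containers first* — only the shallowest residual depth is matched per
     round, then propagation pins unique children under the new pairs.
     Without this, content-identical leaves (two equal `map_components`
     elements in different connections) cross-match between unrelated
     parents and manufacture spurious moves out of deleted subtrees;
   * *identity conflicts stay home* — two elements that both carry identity
     attributes with different values are only paired in place (parents
     already matched to each other; the rename case), never across
     parents. A deletion and an unrelated insertion with coincidentally
     similar content must not read as a move-plus-rename.

Passes 3 and 4 alternate with propagation until nothing changes. Roots are
always mapped. Attribute and text nodes are aligned per matched element
pair afterwards (attributes by name; text children by an LCS on values,
leftovers paired positionally).

### Moves

A move is a matched element whose parent changed, or — within a matched
parent — an element off the longest increasing subsequence (LIS) of its
label group's target-side order. The naive definition "rank among
same-label siblings changed" would turn one relocation into a cascade:
moving the first of three species to the end changes every sibling's rank.
The LIS refinement reports exactly the minimal set of moved elements and
keeps move counts symmetric under diff direction. Order changes *across*
different labels under one parent (swapping a `listOfSpecies` with a
`listOfReactions`) are not reported as moves and are a known blind spot;
they do not occur in schema-conforming SBML/CellML nor in the generator.

### Patching

`apply_delta()` is the correctness oracle for the whole engine:
`apply_delta(a, diff_models(a, b))` must equal `b` in canonical form. To
replay losslessly, operations carry three extension fields beyond the core
contract (namespace of the affected element, the global child index of the
insertion point, and — for non-triggered element inserts — the subtree
payload). They are exported in the JSON and XML patch dialects as extension
attributes. Applying a delta to a document that is not its base raises an
`modevol_inconsistent_delta` condition, verified by resolving every old
path and comparing every old value before mutating anything.

### Line diff

Each delta also carries plain insert/delete line counts over the canonical
serializations — the numbers Unix `diff` would report. The production path
is Myers' O(ND) algorithm; the test suite checks it against an independent
quadratic LCS dynamic program.

## Classification

Every operation gets exactly one **Change** term (Insertion / Deletion /
Update / Move), exactly one **XmlEntity** term (Node / Attribute / Text),
and a possibly empty set of **Target** terms derived from the nearest
enclosing recognized container on the operation's path (`listOfSpecies` →
SpeciesSetup, `kineticLaw` → ReactionDefinition, `notes` →
TextualDescription, CellML `component` → ComponentDefinition, …). The table
is a fixed, documented lookup (`comodi_target_table()`), overridable from a
JSON mapping file so term IRIs can track ontology revisions without a code
change. Unrecognized containers yield an empty set rather than a guess:
intention and reason cannot be derived from a structural diff, so the
Intention/Reason branches are out of scope by design.

## The statistics tables

* **filestats** — one row per (model, version): the entity-count feature
  vector plus format, curation status (taken from the ingestion manifest,
  never inferred from content), repository, timestamp and source.
* **diffstats** — one row per consecutive version pair: line diff counts and
  the four op-type counts plus the triggered count. Identical consecutive
  versions produce an all-zero row, not a dropped row — repositories mint a
  new version of every model at each release, and an unchanged re-release
  is still a transition. The op-count columns are named `op_*` (they are
  produced by this package's engine, not by an external tool).
* **repo-evolution** — for each grid date, each model contributes its latest
  version at or before that date; vectors accumulate per repository and for
  the combined set, and the combined vector is by construction the
  elementwise sum (asserted, not assumed, in the tests).

`summarize_evolution()` adds the derived numbers: mean versions per model
within the first five years after its first release (closed interval
anchored on each model's own first timestamp), mean operations per version
transition, mean nodes per model by format, and the release-by-model change
matrix behind the update-heatmap rendering. Whether the per-transition mean
includes zero-op transitions and triggered operations is genuinely
ambiguous in the field, so both toggles are exposed
(`include_zero_transitions`, `include_triggered`), defaulting to inclusive.
Summaries over empty tables are `NA`, never a fabricated zero.

## The synthetic world

The generator is first-class, tested code — the package's oracle factory —
and its defaults are fixed choices, not tuning knobs:

* Seed documents: SBML with 10 species / 5 reactions / 2 compartments /
  4 parameters plus notes, an annotation stub and a unit definition
  (~90 element nodes — the size regime the recovery bar is stated for), or
  CellML with 5 components / 15 variables / 2 units / 3 connections.
* Histories start on 2005-04-11 (the launch date of the older repository)
  and release gaps are uniform 30–365 days. The default of five versions
  per model matches the observed scale of roughly 4–5 versions within a
  model's first years.
* The default op mix is insert/delete-dominated with few moves
  (0.40/0.30/0.25/0.05), matching the observed delta composition;
  `cellml_like = TRUE` raises the move share to 0.25, the regime in which
  CellML documents reorder entities more often. The move-fraction contrast
  between the two regimes is itself an acceptance property.

Planted edits never overlap: each edit claims the subtree it touches, and
each (container, label) group accepts at most one kind of structural edit
per transition — inserts, deletes or one move, never a mixture. Two further
restrictions keep *exact* recovery well-posed rather than merely likely:

* within-container moves have displacement ≥ 2. A displacement-1 move is a
  swap, and "which of the two elements moved" is unanswerable from the
  documents alone;
* text inserts only go into empty elements — adjacent text siblings would
  merge on reparse and break byte-exact replay.

With `id_stability = FALSE` the generator renames identity attributes and
omits them from inserted elements; recovery is then measured as pooled
path-level F1 with an acceptance bar of 0.9 — an artifact-level bar, not a
literature claim.

What a green suite establishes: on id-annotated, schema-shaped documents
with non-overlapping edits, the engine recovers planted scripts exactly and
round-trips every pair. What it does not establish: behaviour on documents
whose edits overlap in one transition, on id-free documents with heavy
reordering, or equivalence with any published tool's op counts on
pathological inputs.

## Numerical and degenerate-input choices

* Similarity threshold 0.7, chosen so a single-attribute change on a
  typical 4-attribute element (token overlap ≈ 0.8) still matches while
  element replacements (overlap ≈ 0.5) do not; it is exposed as
  `sim_threshold` on the diff entry points.
* All ties everywhere break by document order; the diff contains no
  randomness and equal inputs yield byte-equal deltas.
* Empty documents, single-version histories, empty corpora and empty
  filter selections all produce empty-but-well-formed outputs.
* RNG discipline: every generator function seeds locally and restores the
  caller's RNG state, so corpora are regenerable byte-exactly regardless of
  surrounding code.

## Known limitations

* SBML Level 3 package subtrees are treated as opaque XML: they diff and
  count as generic elements, with no package-aware semantics.
* MathML is compared structurally, not semantically: `a*b` and `b*a`
  differ.
* Heterogeneous-sibling reorders under one parent are invisible to the move
  detector (see above).
* The Target vocabulary is a documented superset choice; an external
  classifier populating different terms would produce a different Target
  table, though Change/XmlEntity branches are forced.
* The configuration file for the CLI is JSON, not YAML (no YAML parser in
  the dependency footprint).
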