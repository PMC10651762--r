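---
title: "Transformation-rule library design: models, parameters and design choices"
author: "ChemLibDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transformation-rule library design: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChemLibDesign)
```

ChemLibDesign implements a ligand-based design loop for multi-target
focused libraries: medicinal-chemistry transformation rules, expressed in
SMIRKS, are applied iteratively to seed compounds; the growing library is
standardized, gated on simple physicochemical bounds, scored for
drug-likeness and synthetic accessibility, filtered, and compared to
reference collections in several descriptor spaces. This vignette explains
the models behind each stage, the tunable parameters and their defaults,
the numerical conventions, and what the synthetic test fixtures do and do
not demonstrate.

## The rewrite model

A transformation rule is a SMIRKS string `reactant >> product`. The
reactant side compiles to a substructure query over a deliberately scoped
SMARTS subset — element and aromaticity primitives, `#n`, `D`/`X`/`x`/`H`/
`R`/`r`/`v`, charges, wildcards, negation and conjunction/disjunction, and
recursive environments `$(...)` — which covers published rule compendia
and alert catalogs without pulling in the full SMARTS grammar. The product
side is parsed as a molecular template whose bracket atoms may carry
(ignored) matching decorations.

Application semantics follow the conventions of the widely used
reaction-transform engines, because published rule tables are written
against them:

* the query is matched at **every** site; each match yields one product
  (single-site application). Multi-site modification emerges from
  iteration instead — simultaneous rewriting would explode combinatorially
  and is not what printed one-site transforms describe;
* matched atoms whose map class survives on the product side are kept,
  with element, aromaticity and charge updated from the template; matched
  atoms without a surviving map are deleted with their bonds; product
  atoms with no reactant counterpart are created. A product-side map with
  no reactant-side partner is therefore *not* an error: rules drawn in
  structure sketchers print exactly that pattern, and the deletion +
  re-creation semantics produce their intended products (the benzoyl →
  oxetane linker swap is the canonical example: the carbonyl oxygen must
  leave with the deleted carbonyl carbon);
* hydrogen counts are recomputed from standard valences unless the
  template pins them; products are kekulized (exact matching over each
  aromatic system), valence-checked against a per-element, charge-adjusted
  table, re-aromatized through a canonical round-trip, and dropped — and
  counted — when any step fails;
* product sets are deduplicated on stereo-stripped canonical SMILES and
  emitted in lexicographic key order, so identical inputs always produce
  byte-identical outputs. The input molecule is never its own product.

CXSMILES-style extension blocks (`|s:0:1|`, `|rb:...|`) that sketchers
append to printed SMIRKS encode drawing and stereo hints, not graph
rewriting; they are stripped at parse time and retained as rule metadata.

The whole pipeline is stereo-agnostic: chirality and double-bond
configuration are parsed and discarded, which matches the representation
choice of the curation model (below) and makes canonical keys stable
across spellings.

## Standardization

`standardizeMolecule()` runs a fixed-order cascade: parse; split
components keeping the largest by heavy-atom count (ties by molecular
weight, then element composition — the tie-break is a package convention);
reject on elements outside {H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I} or
on valence/kekulization failure; neutralize charges that a plain
(de)protonation balances, leaving zwitterionic pairs alone; reionize
(normalize hypervalent-spelled nitro groups to the charge-separated form
so both spellings share a key); canonical tautomer; canonical key.

The tautomer canonicalizer is deterministic and deliberately small: it
shifts aliphatic enols to their keto form, lowest-numbered match first, to
a fixpoint. It runs *after* the canonical round-trip has re-aromatized any
Kekulé-written rings, so phenols and aromatic lactams are never touched.
This is a stability convention, not an attempt at full tautomer theory:
the canonical form is documented, versioned and idempotent, which is what
deduplication needs.

## Enumeration

`enumerateLibrary()` expands a frontier: iteration *i* applies every rule
to every molecule first seen at iteration *i − 1*. Defaults are the study
conditions: **two iterations**, and per-iteration gates **MW < 630 Da**
(strict, reading "below" literally) and **40 ≤ TPSA ≤ 150 Å²**
(inclusive). Three behavioural decisions are worth knowing:

* gates are applied after each iteration, and gated-out products do not
  seed the next one — this controls combinatorial growth and makes the
  gate a real constraint on intermediates, not only on the final table;
* only new molecules are expanded, so rewrite cycles (A → B → A) cannot
  loop;
* seeds are excluded from the output by default (`includeSeeds = FALSE`),
  since the object of interest is the generated chemistry.

Each record carries `(seedId, ruleChain, iterationBorn)` with
`length(ruleChain) == iterationBorn`, and `replayProvenance()` re-derives
any record from its seed — the suite asserts this for every record of its
test libraries.

## Drug-likeness and synthetic accessibility

**QED** is the weighted geometric mean of eight desirability functions,
each an asymmetric double sigmoid of one property channel (MW, ALOGP,
HBA, HBD, PSA, ROTB, aromatic rings, structural alerts), using the
published parameterization and mean-weight scheme; 0.67 and 0.49 are the
published cut-points for attractive and unattractive compounds. The
desirability machinery is exact (tested against an independent reference
implementation at 10⁻⁶ given identical property vectors). The property
inputs, however, are this package's: Lipinski-style HBA/HBD counts,
OpenBabel's Wildman–Crippen logP and Ertl TPSA, and the packaged alert
catalogs. Different toolkits count acceptors and alerts differently, so
molecule-level QED values agree with other implementations at the
distribution level (median drift well under 0.1), not at the third
decimal — the same caveat applies between any two QED implementations.

**The SA score** follows the fragment-contribution scheme: the mean
log-frequency score of every atom's circular environments (radius 0–2)
plus complexity penalties — size (n^1.005 − n), stereocenters, spiro
atoms, bridgehead atoms, macrocycles (ring > 8, a log₁₀2 penalty) — and a
symmetry bonus when few distinct fragments cover many atoms, mapped to
[1, 10]. Two resource notes:

* the packaged fragment table is **synthetic**: it is built by
  `buildFragmentScores()` from the package's own calibration collection
  (decorated scaffolds, homologous alkyl/ring/functionalized series, and
  common drug-motif exemplars including the chemotypes the built-in rules
  produce), with scores anchored at the lower-quartile frequency so that
  ordinary environments score positive — emulating the abundance skew of
  the published large-catalog frequency analysis. The table
  (`inst/extdata/sa_fragment_scores_synthetic.tsv`) is regenerable with
  `inst/scripts/regenerate_sa_table.R` and its provenance matters: scores
  near the ≤ 6 filter threshold depend on it, which is why the filter
  report stamps its configuration;
* the macrocycle penalty is a *term*, not a total ordering: for a
  symmetric macrocycle the fewer-distinct-fragments symmetry bonus can
  outweigh the log₁₀2 penalty, so a 20-membered carbocycle may still score
  at the easy end, as it does in reference implementations. The tests
  therefore assert the penalty term directly.

**rsynth-style synthetic feasibility** is *not* reimplemented — the
reference scorer is a proprietary ligand-based method. The cascade exposes
a pluggable `synthScorer` hook (strictly-greater-than-0.5 threshold when
enabled) and skips the stage by default.

## The filter cascade

Stages run in a configurable order (default: SA → synth → QED → alerts,
the conventional attrition-table row order) with exact boundary semantics:
QED 0.67 fails (strict >), SA 6.0 passes (≤), alerts must number at most
`maxAlerts` (default 0). Because the stages are independent predicates the
survivor set is order-invariant even though per-stage attrition is not;
both properties are tested. The packaged alert catalogs are curated,
documented *subsets* of the well-known public collections — a PAINS-family
set (catechols, quinones, rhodanines, azo/hydrazone dyes, Michael
acceptors, …) and a reactive/unwanted-functionality set — shipped as
editable TSV and extensible with user files; every report records which
catalogs were active.

## Chemical-space views

The "chemical multiverse" principle is to view the same libraries through
several descriptor spaces:

* **Property space**: six descriptors (HBD, HBA, logP, MW, RotB, TPSA),
  standardized to zero mean/unit variance over the pooled libraries
  (standardization is recorded in the method metadata). PCA uses a fixed
  sign convention (largest-magnitude loading positive) so embeddings are
  reproducible across runs and row orders; t-SNE is an exact O(n²)
  implementation (per-point precision calibrated by bisection to
  perplexity, default 30; early exaggeration; momentum descent) that is
  deterministic under its mandatory seed and intended for the hundreds-to-
  thousands scale of diversity analyses.
* **Fingerprint space**: ECFP4-style hashed circular fingerprints (radius
  2, 2048 bits, deterministic invariant hashing), Tanimoto distances, a
  k-nearest-neighbour graph (k = 10 default), cheapest bridging edges when
  the kNN graph is disconnected, and the exact minimum spanning tree with
  a seeded force-directed layout. This reproduces the analytical role of
  published tree-map embeddings — a spanning tree over fingerprint
  similarity — with an exactly testable MST; `treeBuilder` lets a
  different tree construction be swapped in.
* **Shape space**: one low-energy conformer per molecule (OpenBabel
  `--gen3d` with force-field minimization, optionally refined by an
  energy-scored conformer search of breadth `nConformers`, default 50),
  mass-weighted inertia tensor, and the normalized ratios npr1 = I1/I3,
  npr2 = I2/I3. npr2 is I2/I3 by the standard construction — this is what
  places the disc at (0.5, 0.5) and makes npr1 + npr2 ≥ 1 a rigid-body
  identity. One honest limitation: the 3-D backend exposes no RNG seed, so
  coordinates of flexible molecules can differ between runs; the requested
  seed is recorded for provenance, and rigid molecules (the rod/disc/
  sphere fixtures) are exactly reproducible because their minimized
  geometry is unique.

## What the synthetic fixtures show — and what they do not

All tests run without any external download. `builtinRules()` ships seven
representative literature rules; `makeSeedSet()` draws curation-stable
molecules from per-motif variant pools; `makeReferenceLibrary()` decorates
ring scaffolds with substituents (greedily selected toward requested
property means when targets are given). Problem sizes are chosen for exact
checkability: rule-application tests compare complete product sets against
an independently computed rewrite oracle on probes of ≤ 20 heavy atoms;
MST tests brute-force instances of ≤ 25 nodes; t-SNE cluster tests use 60
points in two well-separated blobs.

Passing these tests demonstrates the *mechanics* — correct rewriting,
curation idempotence, gate soundness, provenance replay, exact embeddings
— on fixture-scale chemistry. It does not demonstrate reproduction of any
published library's counts or score distributions: those depend on the
full 280-rule compendium, the proprietary rule set of the original
enumeration software, and deposited compound collections that this package
reads (`readRuleCompendium()`, `readCompounds()`) but does not bundle.
The acceptance suite states those checks against the deposit's file
layout and reports them as unavailable when the files are absent.

## Degenerate inputs and numerical conventions

* Unparseable, element-violating or valence-violating records are
  *rejections with a single first-failing reason*, never hard errors, in
  all batch paths; `applyRule()` on an unsanitizable molecule is the one
  hard error (invalid input).
* Zero-match rule applications return the empty set. Empty libraries
  produce all-zero reports. An empty seed set is an error.
* Aromaticity is accepted as written when the system kekulizes (no Hückel
  counting); unkekulizable systems are rejected — the same decision the
  major toolkits make for genuinely invalid aromatic SMILES.
* Ties: duplicate canonical keys keep the first-seen record (input order,
  then compendium order); largest-component ties break by weight then
  composition; product sets sort lexicographically.
* All internal randomness (fixture sampling, t-SNE initialization,
  layouts) is seeded explicitly; fixture generation uses its own
  linear-congruential stream so it neither disturbs nor depends on the
  session RNG.
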