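---
title: "Qualitative attractor analysis of hybrid gene-regulatory models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative attractor analysis of hybrid gene-regulatory models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsmattract)
```

## The model class

A hybrid system model (HSM) of a gene regulatory network couples continuous
and discrete state. Protein concentrations are continuous variables that
change monotonically — growing while the producing gene is on, decaying while
it is off. Binding sites are discrete variables: a site is free or occupied
by one of its ligands. The coupling is hysteretic: a free site is bound when
its ligand's concentration rises to the site's *association threshold*
(`site.as`), and released only when the concentration falls to the strictly
lower *dissociation threshold* (`site.dis`). Discrete *control functions* map
binding-site state tuples to gene expression levels, and one *generator* per
substance turns the level into a growth or decay direction. All fixtures use
two expression levels (on/off); the model schema permits more, but the
analysis rejects multi-level tables with a `NOT_SUPPORTED` diagnostic.

This class sits between Boolean networks (no concentrations at all) and
differential equations (full kinetics): it captures concentration-ordering
effects while requiring only the *relative order* of binding thresholds, not
their values.

## Modes, threshold orderings and the characteristic graph

A *mode* records the state of every binding site. Within a mode every
concentration moves in a fixed direction, so each mode determines a
qualitative behaviour vector (up/down per substance; "flat" is reserved for
substances without a generator — a substance whose gene is off is labelled
"down" even while asymptotically approaching zero, because the qualitative
abstraction cannot witness reaching zero in finite time; the numeric
simulator reports "flat" when a concentration actually sits at zero).

Thresholds of one substance are comparable, thresholds of different
substances are not (concentrations live on separate scales). A *threshold
ordering* is therefore a per-substance total preorder of threshold keys,
with ties allowed only where explicitly declared equal. Given an ordering,
many site-state combinations are impossible: if a substance occupies a site
it must sit above that site's dissociation rank, and below the association
rank of every site it could bind but does not. A mode is *consistent* when
every substance's implied concentration interval is non-empty. For the phage
model this prunes the 11664 raw combinations to roughly a thousand per
ordering.

The *characteristic graph* has the consistent modes as nodes and guarded
transitions as edges. A rising substance can only cross the minimal
uncrossed association rank among its free sites — a monotone concentration
meets lower thresholds first — and a falling one only the maximal
dissociation rank among its occupied sites. Thresholds tied at that rank
fire together as one compound event; events of different substances are
asynchronous. When a release leaves a mode inconsistent (a freed site's
other ligand already sits above its association rank), *cascade closure*
branches into every consistent completion, so release-then-rebind ambiguity
is over- rather than under-approximated. The graph is a safe
over-approximation of the numeric dynamics: every simulation whose
parameters respect the ordering walks inside it, which `conforms()` checks
and the test suite exercises on random runs.

By default the graph seeds on *all* consistent modes (explorable behaviour
from any initial condition); passing explicit seed modes yields the
reachable subgraph instead. Node order is canonical (sites in declared
order, states encoded FREE = 0, k-th ligand = k), so rebuilding a graph is
bit-identical.

## Attractors

Stable behaviours live inside strongly connected components. An SCC is
disqualified by a *progress indicator*: a substance that rises in every
member mode while some bindable site stays free throughout (its association
crossing is then unavoidable and forces an exit), or falls in every mode
while some site stays bound (its dissociation crossing is unavoidable). A
falling substance with nothing bound merely decays towards zero and forces
nothing. Because a uniformly-rising substance can never release a site, its
bound set is constant across an SCC, so "some site free in every mode" and
"one site free throughout" coincide.

`find_attractors()` marks an SCC as an attractor candidate when it has no
progress indicator and can host an infinite behaviour (an internal edge, or
a steady sink). Finality — no edge leaving the SCC — is reported separately
rather than required: the wild-type lysis component of the phage model, for
instance, admits exits whose realization depends on growth-rate ratios, and
treating it as non-stable would discard the biologically central behaviour.

Attractors are compared at two resolutions. The *fingerprint* keeps full
binding-site identities and guard texts; the *signature* relabels modes by
their direction vectors and edges by the guarding substance and threshold
kind, then takes a canonical form of the labelled digraph, so attractors
that differ only in which sites realize the behaviour collapse. The
canonical form encodes each labelled directed edge as a two-node coloured
chain in an undirected graph and applies BLISS canonical labelling
(`igraph::canonical_permutation()`), which is exact — no hash collisions or
refinement heuristics.

## Enumerating orderings under partial constraints

When affinities are only partially known, `enumerate_orderings()` lists
every admissible ordering: backtracking over linear extensions of the
declared chains, with per-site dissociation-before-association implicit,
adjacency blocks forcing a site's two thresholds to be consecutive, and
declared equalities merging keys into tied rank groups. Results are emitted
in lexicographic order of the rendered key sequence, so "the third ordering"
is well defined and matches the published ordering table of the two-gene
network. Permitted interleavings — complete orderings exempted from
adjacency — are validated against the chains and appended. For the phage
constraints the two exceptional interleavings per protein are the
level-aligned ones (the O_R and O_L cascades aligned level by level with the
level-2 blocks interleaved, O_R-first and O_L-first): a local four-key
exception with free placement of the remaining blocks would yield 28
orderings per protein rather than the documented 22 (20 block shuffles,
C(6,3), plus the 2 exceptions), so the count pins the exceptions down to
complete orderings.

## The fixtures

The **two-gene toy network** has `s1` negatively auto-regulated through `b1`,
`s2` negatively auto-regulated through `b3` and activating `s1` through
`b2` (`s1` on iff `b1` free and `b2` bound; `s2` on iff `b3` free). Its six
`s2` orderings give graphs of fewer than ten modes, four distinct
graph/attractor structures (operationalized as distinct multisets of
attractor signatures — the reachable graphs from the all-free mode for the
first two orderings are isomorphic, as are those of the last two), three
distinct attractors overall, and a bistable third ordering.

The **phage lambda switch** model has the six operator sites `bOR1..3`,
`bOL1..3` shared by Cro and repressor with opposite affinity cascades, plus
`bQ`, `bN`, `bCII-1`, `bCII-2`. Its control tables are reconstructions: the
published material fixes the wiring (which sites feed which promoter, which
genes each promoter drives) but not the truth tables, so the tables were
chosen to realize the described regulatory roles and validated against the
published analysis results. Two cells deserve comment:

* `P_ME` (the merged maintenance/establishment promoter of *cI*) is on iff
  `bOR3` is free and (`bOR2` is not repressor-bound or `bCII-1` is
  CII-bound). Repressor's negative loop at `bOR2` produces the lysogeny
  oscillation between `bOR2.dis` and `bOR2.as`; Cro on `bOR3` silences *cI*;
  CII at `bCII-1` overrides the `bOR2` auto-repression (establishment) but
  not Cro's silencing. Leaving the CII trigger ungated by `bOR3` lets
  repressor make zero-net excursions inside lysis (CII peaks switch *cI* on,
  repressor captures `bOR1`, CII decays, repressor releases), which welds the
  lysis component to its surroundings into one large SCC — gating by `bOR3`
  yields the documented twelve-mode lysis component guarded by exactly
  Cro, CII and Q.
* Unreachable table rows (e.g. repressor on `bOR3` combinations excluded by
  the fixture constraints) extend the nearest reachable case.

Under every one of the 500 examined orderings the analysis finds exactly two
attractors: a lysis-type component (Cro cycling at `bOR2`) and a
lysogeny-type component (repressor cycling at `bOR2`). Wild-type lysis
(twelve modes, guards Cro/CII/Q) occurs precisely when both Cro thresholds
for `bOR2` rank below those for `bOL2`; repressor's `bOR3` block below
`bOL1` is sufficient for modified lysogeny (N, CIII and Xis accumulate).
Both conditions are recovered by `mine_conditions()`, which intersects
pairwise rank relations over the orderings producing each signature and also
reports relations holding in none of them; sufficiency claims are then
checked in the other direction (every ordering satisfying the relation
produces the signature).

One classification residual is documented rather than hidden: with the
tied-`bOR2`/`bOL2` variant, the compound binding event switches `P_R` and
`P_L` off together, so N and Q cycle with Cro and the resulting 24-mode
lysis attractor is a genuinely distinct qualitative behaviour under the
formal signature definition. Counting it separately gives 10 fingerprints in
5 signatures rather than the 9-in-4 census obtained when it is lumped with
wild-type lysis by judgment; without the original tool's exact truth tables
the residual cannot be resolved, and the package reports what it computes.

## The numeric simulator

`simulate_hsm()` integrates the piecewise-linear kinetics exactly: within a
mode each concentration is linear, the next event time is the minimum over
closed-form threshold crossings, crossings at equal times fire as one
compound event, and zero-duration cascade re-binds are merged into the
triggering event. Crossing is inclusive (`>=` binds, `<=` releases), decay
is floored at zero, and growth is unbounded by default — matching the
model assumption that a rising concentration eventually crosses any
association threshold ahead of it, which also underpins the
progress-indicator logic. `params_for_ordering()` realizes any ordering
numerically (rank r gets value r, or random rank gaps in [0.5, 1.5] and
rates in [0.5, 2] for generic parameters); `conforms()` then checks that a
run's mode sequence is a guard-matching walk in the ordering's
characteristic graph. Event times are exact rational arithmetic on floats;
simultaneity is detected with a 1e-9 relative tolerance.

The simulator validates the graph semantics (the central over-approximation
property) but is deliberately simple: linear kinetics only, no stochastic
effects, no delays, no parameter fitting.

## What the synthetic generator does and does not emulate

`random_hsm()` draws structurally valid models (random ligand assignments,
random binary tables) for property tests: round-trip identity, consistency
of every built node, hysteresis along walks, SCC correctness against a
transitive-closure oracle. Random models exercise the *algorithms*, not the
biology: they have no affinity cascades, no operon structure and no
interpretable attractors, so passing property tests supports the machinery's
correctness, not the phage model's fidelity — that is what the fixture
census above is for. Problem sizes used in the tests (toy network in full;
phage sweep over all 500 orderings; random digraphs up to 8 nodes for the
SCC oracle; 100 random simulations) were chosen so the whole suite stays
desk-scale.

## Numerical and design choices

* Deterministic everywhere: lexicographic enumeration order, canonical node
  encoding, first-seen fingerprint/signature ids, seeded randomness only in
  test helpers and `random = TRUE` parameter draws.
* Ties: only declared equalities produce tied ranks; tied thresholds fire
  compound events and share values in the simulator.
* Settling: at run start (and instantly after cascades) a free site binds
  the first declared ligand whose concentration reaches its association
  value — the declaration order is the tie-break rule, and it is logged in
  the run's event records.
* Graph export: DOT and GraphML via igraph, with a JSON dump carrying full
  metadata. igraph cannot re-read DOT, so signature round-trip stability is
  guaranteed (and tested) through GraphML.
* Unsatisfiable constraint sets return an empty enumeration with a
  `diagnostic` attribute instead of an error, so sweeps over constraint
  variants can proceed.

## Known limitations

* Expression levels above two are parsed but rejected by the analysis.
* The characteristic graph with cascade-closure branching may contain edges
  no simulation realizes (safe over-approximation; the reverse inclusion is
  what is guaranteed and tested).
* Condition mining reports relations necessary within the examined ordering
  sample; it does not prove necessity beyond it.
* The phage truth tables are validated reconstructions, not the original
  tool's files; the tied-threshold census residual above is the one place
  this shows.
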