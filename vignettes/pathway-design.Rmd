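---
title: "Designing autocatalytic pathways by chemical-space exploration"
author: "crnflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing autocatalytic pathways by chemical-space exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnflow)
```

## The problem

Carbon fixation reduces CO2 or bicarbonate into metabolic building blocks.
The natural chemistries that do this at scale are *autocatalytic cycles*:
one molecule of the cycle (the autocatalyst) must be present for the cycle
to run, and each completed turn regenerates it with a net surplus while
consuming inorganic carbon and cofactors. Designing artificial variants is
a combinatorial search: which known enzymatic reaction classes, applied to
which intermediates, wire into a short, cofactor-cheap, thermodynamically
downhill cycle?

`crnflow` treats this as three separable computations:

1. **Expansion.** Molecules are labeled graphs; enzymatic reaction classes
   are graph-transformation rules. Applying all rules iteratively to a seed
   pool grows a chemical reaction network (CRN), a directed multi-hypergraph
   whose vertices are molecule isomorphism classes and whose hyperedges are
   reactions.
2. **Search.** A pathway is an integer hyperflow on the CRN. An exact ILP
   finds flows that satisfy conservation and an autocatalysis condition
   while minimizing pathway length; no-good cuts enumerate topologically
   distinct alternatives.
3. **Annotation.** Each solution's net reaction is scored for cofactor
   consumption, carbon units fixed, and standard transformed Gibbs reaction
   energy from a formation-energy table.

## Molecules, rules, rewriting

Atoms carry an element label and an integer formal charge; bonds carry an
order (`-`, `=`, `#`, `:`). Hydrogens are explicit vertices because the
rules move them — rewrite correctness needs the bookkeeping. No valence
model is enforced beyond what the rules encode: rule sets are curated, and
a valence checker would silently veto legitimate rule semantics.

Coenzyme A is abstracted to a single reserved pseudo-atom `CoA`. Only its
identity matters for the expansion constraints (its carbons are exempt
from the carbon limit, and molecules may carry at most one CoA), so
carrying its ~48-atom structure would multiply matching cost for no
modeling gain.

A rule is a span *L ← K → R* with shared vertex identities: left-only
elements are deleted, context is preserved, right-only elements are
created, labels and charges may change. Application is double-pushout
rewriting: an embedding that would delete a vertex still holding unmatched
host bonds (dangling condition), or create a bond that already exists, is
not a valid match and is rejected rather than repaired. Matching is
monomorphic — pattern bonds must exist in the host with the exact order,
extra host bonds are allowed — and injective over the whole multi-molecule
pattern; each connected pattern component must land inside one molecule,
and several components may share a molecule instance. Wildcard labels
(e.g. `X`) are declared per rule as finite element sets and bound
independently per matched vertex, which is how one rule expresses a
promiscuous reaction class.

Molecule identity is the canonical key: bond orders are encoded by
subdividing each bond with a vertex colored by order, and the
vertex-colored auxiliary graph is canonically ordered with igraph's BLISS
backend; the serialized canonical form (plus label legend) is the key.
This is exact — key equality is label/charge/bond-preserving isomorphism —
and the test suite certifies it against brute-force permutation
enumeration on all small fixture graphs. We chose the installed exact
canonical-labeling implementation over a hand-written refinement procedure:
it is the same algorithmic family, already validated, and faster.

## Expansion semantics

One expansion step matches every rule against the molecule pool *as it
existed at the step's start*; all admissible derived reactions are added
simultaneously and new products become matchable the following step. This
makes expansion deterministic and independent of rule order, and makes
"number of steps" a meaningful network-size axis. Reactions are identified
by (educt key multiset, product key multiset, rule name) — the rule name is
part of identity because distinct enzymes realizing the same net change
are distinct design choices.

Products with more than `cMax` carbons (default 6) or more than `coaMax`
CoA units (default 1) are inadmissible, and a reaction with any
inadmissible product is dropped *entirely*: the generating event itself is
outside the modeled space, not merely its product. The defaults mirror the
natural carbon-fixation chemistries, whose intermediates stay within six
backbone carbons. Expansion beyond five steps is allowed but warned
against; hypergraph growth is combinatorial and flow queries on such
spaces stop being interactive.

## The hyperflow ILP

Variables per hyperedge: integer flow `x_e` in `[0, flowCap]` and binary
`z_e`, linked by `x_e ≤ flowCap·z_e` and `x_e ≥ z_e`. Conservation holds
at every molecule, with inflow/outflow variables only for the allowed
source/sink species (the autocatalyst, cofactors, inorganic carbon —
supplied as an explicit allow-list, never inferred). Autocatalysis is
`inflow(a) ≥ autocatIn` and `outflow(a) − inflow(a) ≥ autocatGain`
(defaults 1 and 1): the pathway must consume the autocatalyst and return
strictly more. A strict inequality chain with a unit upper gap has no
integer solutions, so the net-gain form is the faithful integer rendering
of "in greater than zero, out greater than in"; a cap on the gain is left
to the user via `autocatGain`.

Objective: `min Σ (w·z_e + x_e)` with `w = 1000`. The dominant term counts
used edges — pathway length in reactions, the comparison axis used across
carbon-fixation cycles — and the flow term breaks ties toward minimal
total flow, so a doubled copy of an optimal flow is feasible but strictly
worse (asserted in the tests). `steps` of a solution is the support size
`Σ z_e`, not `Σ x_e`. "Topologically different" means different support;
flows differing on the same support do not count as new. `flowCap`
defaults to 10: the linking constraint needs a finite bound, and no
credible pathway reuses one reaction more than a handful of times per
turn.

### Solving exactly without a MILP library

The LP relaxations are solved by a two-phase dense tableau simplex written
in the package (Dantzig pricing, switching to Bland's rule after a pivot
budget to guarantee termination; reduced costs maintained incrementally
and refreshed every 200 pivots against drift; pivot tolerance 1e-9).
Branch-and-bound is depth-first, branching on the most fractional variable
with indicator variables preferred and the `z = 1` child explored first —
under an edge-weight-dominated objective this dives to good incumbents
quickly. Because all attainable objectives are integers, nodes are pruned
at `incumbent − 0.99`. A numerically integral LP solution is rounded and
re-verified against every constraint in exact integer arithmetic before it
may become the incumbent; solver breakdowns (node or iteration limits) are
reported as a distinct condition class from genuine infeasibility.
Enumeration adds, after each solution with support *S*, the cut
`Σ_{e∈S}(1−z_e) + Σ_{e∉S} z_e ≥ 1`, so objectives are nondecreasing and
supports pairwise distinct; exhaustion is flagged rather than padded.

`bruteforceFlows()` is the independent certificate: exhaustive enumeration
of all supports up to a size bound and all integer flows up to a per-edge
bound, with a size guard (default 25 edges) because it is exponential by
design. The acceptance tests require solver/oracle agreement on the
planted toy cycle and on batches of random hypernetworks, including
agreement on infeasibility.

## Annotation

The net reaction of a solution is its inflow/outflow. ΔrG′° is the
stoichiometry-weighted sum of formation energies of products minus
reactants, from a TSV of standard transformed formation energies at pH 7
and ionic strength 0.1 M; computing it on the net reaction means the
energy released by cofactor turnover is included, which is the
interpretation used when pathway energies are quoted with cofactors. A
missing table entry is always an error, never a silent zero. ATP units
count the inflow of configured energy carriers regardless of the
discharged form returned (ADP- and AMP-producing steps both count one unit
by default; two-equivalent AMP accounting is a config choice left to the
user). Redox units count the inflow of configured reduced carriers —
NAD(P)H, reduced ferredoxin, ubiquinol in a biological configuration; note
that redox-cofactor lists in the literature sometimes say "ubiquitin"
where the quinol is meant, and the configuration is user-overridable
precisely so such choices are explicit. Carbon units fixed are the total
inflow of the configured inorganic carbon species. Per-carbon and per-step
ratios divide by carbon units and support size; zero-carbon solutions get
`NA` ratios rather than a division error.

## The toy chemistry

`makeToyChemistry()` is a first-class, tested fixture that emulates the
*structure* of a real carbon-fixation space at desk scale: a pool of
intermediates plus helper species, promiscuous rules with tunable
contexts, cofactor couples, and a known shortest autocatalytic cycle.

The autocatalyst ("replicator") is a single carbon bearing a thiol-type
sulfur, an amine nitrogen, and a hydrogen. The planted cycle is
carboxylation (CO2 capture at the C–H bond), carboxyl reduction by a
dithiol/disulfide redox couple, amination by ammonia, and thiolytic
cleavage by a thiyl donor, yielding two replicators — four steps, one
carbon fixed, one redox and one energy-carrier cofactor per turn. The
pathway intermediates sit in the input pool, as real spaces are seeded
with the intermediates of known pathways. Five decoy rules (a reverse
decarboxylation, a wildcard hydrogenation, an amine alkylation whose
context atom varies with the seed, CoA thioesterification, and a
charge-changing carboxyl deprotonation) provide alternative and dead-end
chemistry, exercise wildcards, charges, the CoA cap, and give the
enumerator genuinely distinct supports. Every rule conserves atoms, so
element balance is assertable across the entire derived space. The seed
permutes vertex numbering and selects the decoy context; the planted cycle
and the molecule set are seed-invariant.

What the toy does *not* emulate: realistic valences and reaction
energetics (its energy table is invented, chosen to make the planted cycle
exergonic), rule contexts curated from enzyme databases, and the
hundreds-of-edges scale of a real two-step expansion. Passing tests
certify the machinery — parsing, matching, rewriting, deduplication,
expansion, the ILP, annotation — not the biochemical fidelity of any
particular rule set. Real spaces are loaded from GML directories with
`loadStudySpace()`, and the acceptance suite contains reproduction checks
that run only when such a transcription is present.

`makeRandomHypernetwork()` generates structureless random CRNs (opaque
marker molecules, random educt/product multisets) with an optionally
planted feasible route, for stress-testing the solver against the
exhaustive oracle, including infeasible instances.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at desk scale on one CPU:
the toy space (12 molecules, 9 rules; 28-38 reactions after two steps),
oracle certification on the one-step space and on random networks of 7
molecules and 9 reactions, and enumeration to exhaustion (a handful of
supports). At these sizes a solve takes well under a second and the full
suite a few minutes. The brute-force oracle's guard (25 edges) marks the
boundary of where exhaustive certification is sensible; the ILP itself
handles a few hundred edges, with LP size, not branching, the practical
limit of the pure-R simplex.

## Known limitations

- No stereochemistry, aromatic perception, tautomers, or 3D geometry;
  molecule identity is graph isomorphism on the given labels.
- Rules are directed; reversible steps are modeled as two rules.
- At most three educt molecules per rule (no rule in the modeled space
  exceeds bimolecular plus a cofactor).
- The ILP is purely topological: no kinetic or concentration-dependent
  thermodynamic constraints inside the search; ΔrG′° is a post-annotation
  at standard transformed conditions only.
- Formation energies are consumed as a static table; live lookup from a
  thermodynamics service is deliberately out of the tested path.
- Tie-breaking among equal-objective solutions follows solver order and
  carries no meaning.
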