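# crnflow

Design of autocatalytic (carbon-fixation-style) metabolic pathways by
chemical-space exploration: expand a chemical reaction network (CRN) from
molecular graphs and graph-transformation rules, search it for shortest
autocatalytic pathways with an exact integer-linear-programming (ILP)
hyperflow model, and post-annotate the solutions with cofactor usage,
carbon units fixed, and standard transformed Gibbs reaction energies.

The package is aimed at systems and synthetic biologists who want to
enumerate candidate pathway topologies — which enzymatic reaction classes,
wired how — before committing to thermodynamic or kinetic detail.

## The model

**Molecules** are labeled graphs: atoms with element symbol and formal
charge, bonds of order `-`, `=`, `#` or `:`. Hydrogens are explicit;
Coenzyme A is a single `CoA` pseudo-atom whose carbons are exempt from
size limits. **Reactions** are graph-transformation rules, spans
*L ← K → R* of pattern graphs (bonds/charges before, preserved context,
bonds/charges after) applied by double-pushout rewriting with subgraph
matching; wildcard vertices range over a declared element set, so one rule
covers a whole reaction class (enzyme promiscuity). Both are written in a
GML dialect.

**The CRN** is a directed multi-hypergraph *H = (V, E)*: vertices are
molecule isomorphism classes (deduplicated by exact canonical keys),
hyperedges are reactions with educt and product multisets. Iterative
expansion applies every rule to the current molecule pool each step,
admitting only molecules with at most 6 carbons and at most one CoA.

**A pathway** is an integer hyperflow: flow x_e ≥ 0 on each hyperedge with
usage indicator z_e, conservation at every molecule except designated
source/sink species (the autocatalyst, cofactors, and inorganic carbon),
and the autocatalysis condition — inflow of the autocatalyst ≥ 1 and
outflow strictly greater, so every cycle nets extra copies of the molecule
that seeds it. The objective

```
min Σ_e (w·z_e + x_e),   w = 1000
```

makes the number of used reactions ("steps") the primary criterion and
total flow the tie-breaker, which suppresses uniformly up-scaled copies of
the same route. Topologically distinct alternatives are enumerated by
adding a no-good cut per found support. The ILP is solved exactly by the
package's own branch-and-bound over two-phase simplex relaxations, and
every solution is re-verified in integer arithmetic; an independent
exhaustive oracle (`bruteforceFlows()`) certifies optimality on small
networks.

**Annotation** computes each solution's net reaction (its inflow/outflow),
ΔrG′° = Σ ΔfG′°(products) − Σ ΔfG′°(reactants) from a formation-energy
table (pH 7, ionic strength 0.1 M), ATP-role and reduced-redox cofactor
consumption, carbon units fixed (CO2 + bicarbonate inflow), and the
per-carbon / per-step normalizations used to compare carbon-fixation
cycles.

## Worked example

The built-in toy chemistry ships twelve small molecules (a one-carbon
"replicator" autocatalyst with thiol and amine handles, its pathway
intermediates, CO2, a dithiol/disulfide redox couple, a thiyl donor,
ammonia, water, a proton, and a CoA thiol) and nine rules, four of which
form a planted autocatalytic cycle.

```r
library(crnflow)

toy <- makeToyChemistry(0)
crn <- initCRN(toy$molecules)                       # 12 molecules, 0 reactions
crn <- expandCRN(crn, toy$rules, steps = 2, quiet = FALSE)
#> step 1: 20 molecules, 12 reactions
#> step 2: 33 molecules, 28 reactions

q <- FlowQuery(crn, "replicator", sources = toy$config$sources,
               sinks = toy$config$sinks, flowCap = 4)
sol <- solve(q)
sol
#> FlowSolution (optimal): 4 steps, objective 4004
#>   flows: e0001=1 e0004=1 e0005=1 e0010=1
#>   inflow: replicator:1 CO2:1 dithiol:1 ammonia:1 thiyl:1
#>   outflow: replicator:2 disulfide:1 water:2

energy <- structure(toy$energyTable, pH = 7, ionicStrength = 0.1)
annotateSolution(sol, toy$config, energy)
#> Annotation
#>   net: replicator:1 + CO2:1 + dithiol:1 + ammonia:1 + thiyl:1 -> replicator:2 + disulfide:1 + water:2
#>   steps 4 | ATP 1 | redox 1 | cofactors 2 | carbons 1
#>   ATP/C 1 | cofactors/C 2 | cofactors/step 0.5 | drG' -254 kJ/mol
```

Reading the output: the optimum uses 4 reactions (objective 4·1000 + 4
flow units), consumes one replicator plus one CO2, one reduced dithiol
(the redox cofactor), one thiyl donor (the energy-carrier analog) and one
ammonia, and returns **two** replicators — net gain of one autocatalyst
while fixing one carbon unit, at 2 cofactors per carbon and an exergonic
net reaction of −254 kJ/mol on the toy energy table.

`enumerateDistinct()` lists alternative topologies,
`comparePathways()` merges annotations with the shipped
literature benchmark table (`inst/extdata/benchmark_pathways.tsv`),
`runPipeline()` drives expand → query → annotate → summarize from one
config, and `inst/cli/crnflow.R` exposes the same steps as a command-line
tool. A real rule set is loaded from GML directories with
`loadStudySpace()`.

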