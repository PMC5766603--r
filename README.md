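# moietypath

Moiety-balanced reaction rules and de novo bioconversion pathway design.

`moietypath` is for metabolic engineers and pathway-design researchers who
want to search for bioconversion routes that may include steps *no cataloged
enzyme performs yet* — without giving up mass balance, cofactor accounting,
or thermodynamic feasibility. It does two things:

1. **Rule extraction.** Every metabolite structure (SMILES or MDL molfile,
   hydrogens made explicit, aromatic bonds kept aromatic) is encoded as a
   *molecular signature* $C^{\lambda}_{mi}$: the count of each atom-centered
   moiety $m$ of size $\lambda \in \{1,2,3\}$, where moieties are identified
   by prime numbers assigned to canonical atom-environment labels. The
   *reaction rule* of a reaction $j$ is the net moiety change
   $T^{\lambda}_{mj} = \sum_i S_{ij} C^{\lambda}_{mi}$ — an elementally
   balanced operator capturing the chemistry at the reaction center.
   Deduplicating change maps over a database yields the unique rule set
   $R^{\lambda}$.

2. **Pathway design.** A mixed-integer linear program selects integer
   fluxes through known reactions ($v_j$), through rules ($v_r$), exchange
   fluxes ($v^{EX}_i$), and the linkage fluxes $v^{imb}_i$ between the known
   and the rule network, subject to

   * component balance: $v^{imb}_i = \sum_j S_{ij} v_j$ for every metabolite,
   * moiety balance:
     $\sum_{i \in I_{ex}} C^{\lambda}_{mi} v^{EX}_i =
      \sum_r T^{\lambda}_{mr} v_r + \sum_i C^{\lambda}_{mi} v^{imb}_i$
     for every moiety,
   * thermodynamic feasibility:
     $\sum_i \Delta_f G'^{\circ}_i v^{EX}_i \le -\varepsilon$ (toggleable),
   * design criteria: step/rule caps, banned co-substrates, cofactor-pair
     selection, organism/pathway annotation toggles,

   and enumerates alternative optima with direction-sensitive integer cuts.
   Designed rule steps can afterwards be *instantiated* on concrete
   structures, proposing novel intermediates verified at signature level.

## Worked example

The bundled fixture holds two decarboxylases — 2-hydroxyisophthalate
decarboxylase (`2HIPD`) and salicylate decarboxylase (`SLD`) — over four
metabolites. Extract rules at moiety size 2 and design conversions of
2-hydroxyisophthalate into phenol:

```r
library(moietypath)

toy   <- toy_decarboxylase_db()
reg   <- prime_registry()
rules <- extract_rules(toy$db, toy$mols, 2, reg)
rules
#> <rule set: lambda=2, 2 unique rules from 2 reactions (0 rejected)>

sigs  <- signature_index(toy$mols, 2, reg)
model <- build_design_model(toy_design(), toy$db, rules, sigs, toy$thermo)
paths <- solve_pathways(model, k = 10)
paths
#> <pathway set: 4 solutions (status: ok)>
#> # A tibble: 4 × 4
#>   objective steps       deltaG valid
#>       <dbl> <chr>        <dbl> <lgl>
#> 1         2 2HIPD+ R2+    -103 TRUE
#> 2         2 2HIPD+ SLD+   -103 TRUE
#> 3         2 R1+ R2+       -103 TRUE
#> 4         2 R1+ SLD+      -103 TRUE
```

Four two-step designs convert one mol of 2hipa into phenol: the all-known
route `2HIPD+ SLD+`, the all-novel route `R1+ R2+` (both steps are rule
applications), and the two blends. Every solution is re-validated with
integer arithmetic independently of the solver (`valid`), and each is
exergonic overall (−103 kcal per mol conversion under the fixture's
formation energies). Looking inside the blend that runs the known `2HIPD`
first and finishes with rule `R2`:

```r
sol <- paths$solution[[match("2HIPD+ R2+", paths$steps)]]
sol$vimb
#> 2hipa   co2  phnl   sal
#>    -1     1     0     1
```

The known network consumes one 2hipa (deficit, $v^{imb} = -1$) and hands
one salicylate to the rule network (surplus, $v^{imb} = +1$); the rule then
decarboxylates it. The net conversion, normalized to the target:

```r
net_conversion(sol, model)
#> # A tibble: 3 × 2
#>   metabolite  coef
#>   <chr>      <dbl>
#> 1 co2            2
#> 2 phnl           1
#> 3 2hipa         -1
```

i.e. `2hipa -> phnl + 2 co2`, elementally exact. To realize the novel step
as chemistry, instantiate the size-1 decarboxylation rule on salicylate:

```r
rules1 <- extract_rules(toy$db, toy$mols, 1, reg)
site   <- match_sites(rules1, "R1", toy$mols$sal)
app    <- apply_rule(rules1, "R1", toy$mols$sal, center = site$atoms[[1]])
sapply(app$products[[1]], molecular_formula)
#> [1] "CO2"   "C6H6O"
```

Command-line front ends (`inst/cli/moietypath-extract`,
`moietypath-design`, `moietypath-fixtures`) wrap the same functions for
shell use; see their `--help`-style headers.

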