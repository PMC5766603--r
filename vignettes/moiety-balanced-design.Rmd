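---
title: "Moiety-balanced pathway design: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moiety-balanced pathway design: model, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(moietypath)
library(dplyr)
```

## The problem

Retrosynthetic pathway design asks for a sequence of biochemical steps that
converts a source metabolite into a target. Searching only cataloged
reactions misses conversions that a promiscuous enzyme could plausibly carry
out; searching free-form hypothetical chemistry produces unbalanced,
thermodynamically impossible suggestions. This package takes the middle
road: it compresses cataloged reactions into *reaction rules* — elementally
balanced operators describing what happens to atom-centered fragments
(moieties) at a reaction center — and then searches, with a mixed-integer
linear program, for designs that blend known reactions with rule
applications while conserving every metabolite, every moiety, and free
energy.

## Canonical labels, signatures, and rules

Every metabolite is a labeled graph with explicit hydrogens; aromatic bonds
keep their own bond order (1.5) so resonance-equivalent atoms are
indistinguishable. Each atom receives a canonical label built by $\lambda$
rounds of neighborhood refinement starting from (element, formal charge):

* level 0: the key is `(element, charge)`;
* level $k$: the key combines the atom's level-$(k-1)$ prime with the
  *sorted multiset* of (bond order, neighbor's level-$(k-1)$ prime) pairs.

Each distinct key is mapped, in lexicographic batch order, to the next
unused prime number by a session-wide registry, so a prime is a compact,
cross-molecule identifier for one atom environment. The moiety size
$\lambda \in \{1,2,3\}$ fixes the radius of the encoded environment: at
$\lambda = 1$ a label describes the atom together with its incident bonds,
at $\lambda = 2$ everything within two bonds, and so on.

Why does the $\lambda = 1$ label include the incident bonds rather than the
bare element? Because the rule of a balanced reaction is a *difference* of
signatures: with element-only labels that difference is identically zero for
every elementally balanced reaction, and no chemistry would ever be
captured. One bond shell is the smallest environment whose changes record a
reaction center.

The molecular signature $C^{\lambda}_{mi}$ counts, for metabolite $i$, the
atoms carrying moiety $m$; its total equals the atom count at every
$\lambda$, and it is additive over disconnected components. The reaction
rule of reaction $j$ with stoichiometry $S_{ij}$ is

$$T^{\lambda}_{mj} \;=\; \sum_i S_{ij}\, C^{\lambda}_{mi},$$

with zero entries dropped. Cofactors are signed like any other metabolite,
so rules natively encode cofactor chemistry. Rules are elementally balanced
by construction, and a reaction that fails the element audit is rejected
rather than allowed to contaminate the rule set. Removing duplicate change
maps yields the unique rule set $R^{\lambda}$; rule identifiers are assigned
from the sorted canonical change maps, so shuffling the database cannot
change them. Rule sets of different moiety sizes are never mixed in one
design.

On the bundled two-decarboxylase system the counts behave as the chemistry
suggests — the two decarboxylations share their one-bond-shell chemistry and
separate at radius two:

```{r toy-rules}
toy <- toy_decarboxylase_db()
reg <- prime_registry()
sapply(1:3, function(l) n_rules(extract_rules(toy$db, toy$mols, l, reg)))
```

## The design MILP

A design problem selects integer fluxes: $v_j$ through known reactions,
$v_r$ through rules, exchange fluxes $v^{EX}_i$ (positive = export), and the
linkage fluxes $v^{imb}_i$ that shuttle metabolites between the known
network and the rule network. Two balance families tie them together:

* component balance, per metabolite: $v^{imb}_i = \sum_j S_{ij} v_j$;
* moiety balance, per moiety:
  $\sum_{i \in I_{ex}} C^{\lambda}_{mi} v^{EX}_i =
   \sum_{r} T^{\lambda}_{mr} v_r + \sum_i C^{\lambda}_{mi} v^{imb}_i.$

Thermodynamic feasibility is a single row over exchange fluxes,
$\sum_i \Delta_f G'^{\circ}_i\, v^{EX}_i \le -\varepsilon$, using standard
transformed formation energies (kcal/mol at pH 7.0, ionic strength 0.1 M)
that the package consumes but never computes. The row can be disabled, both
for databases without thermodynamic coverage and deliberately, to surface
and inspect thermodynamically infeasible candidates (they are reported with
their positive overall free-energy change).

Each step has binary direction indicators linked to its split
forward/reverse flux parts by big-M rows in both directions, so an indicator
is on exactly when its flux is nonzero and a step used in either direction
counts once. Design criteria enter as rows or bounds: caps on the number of
rules and total steps, banned exchanges (fixed to zero), organism/pathway
admissibility (a step may carry flux only if it carries an allowed
annotation label; a rule inherits the union of its member reactions'
labels), and cofactor-group selection (binary selectors per declared
cofactor pair, capped). Objectives: fewest total steps, fewest rules, or
maximum profit over priced exchanges.

### Enumeration and reproducibility

Alternatives are enumerated by integer cuts: after each incumbent the exact
active indicator pattern (step set *and* direction pattern) is excluded and
the model re-solved, so the same steps used in a different direction count
as a distinct design, and solutions arrive in non-worsening objective
order. Ties at equal objective are ordered lexicographically by their
sorted active-step lists, so runs are reproducible. Every returned solution
is re-validated with plain integer arithmetic — both balance families, the
free-energy row, the caps, and the elemental balance of the net conversion —
independently of the solver. The MILP itself is solved through the HiGHS
solver (via the scientific Python stack's `scipy.optimize.milp`) behind a
JSON subprocess interface; if no such interpreter is available the package
raises an explicit error naming the missing capability (MILP with integer
variables).

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `lambda` | 2 | bond shells | specificity of moieties/rules; never mixed within a run |
| `epsilon` | 0.5 | kcal | strictness margin of the free-energy row |
| `flux_bound` | 10 | mol/mol conversion | big-M bound on each flux magnitude |
| `max_steps`, `max_rules` | unset | steps | design-criteria caps |
| exchange bounds | per problem | mol/mol conversion | which co-substrates/products may cross the system boundary, and how much |

Guidance on moiety size: larger $\lambda$ yields rules closer to a specific
known reaction (more credible novel steps, fewer of them); smaller
$\lambda$ is more permissive. Start at 3 and relax to 2 or 1 when no design
is found.

### The coarseness of small moiety sizes

Because the rule network operates on moiety counts, metabolite identity is
deliberately lost inside it, and at small $\lambda$ distinct conversions can
become indistinguishable. Two concrete consequences, both visible in this
package's fixtures: in a homologous oligomer family the signature is affine
in chain length beyond the end regions, so at $\lambda = 1$ a single
cleavage step run at flux 2 can stand in for two distinct cleavage steps at
the moiety level; and a carrier molecule's loaded-minus-empty signature can
coincide with the free unit it carries. Both degeneracies disappear one
moiety size up, which is why the bundled toy design runs at $\lambda = 2$
(with the step cap at the known route length, enumeration returns exactly
the four direct blends of known steps and rules) and why the planted-route
optimum is certified at unit flux bounds. This is not an artifact to
engineer away: it is the price of the relaxation that makes novel-step
search linear, and the reason validated designs should be instantiated (see
below) before being taken chemically seriously.

## Rule instantiation

Pathway design never depends on structure generation — the MILP works
entirely on signatures. As post-processing, a designed rule step can be
instantiated on concrete substrates: candidate reaction centers are the
atom sets carrying the rule's consumed moieties (when several assignments
exist, those maximizing internal bonding are kept); around a center, a
bounded search over unit bond-order edits (default at most 4, aromatic
bonds untouched) proposes products, prunes valence violations during the
search, and accepts exactly those candidates whose recomputed signature
difference equals the rule's change map. At $\lambda = 1$ several
residual-zero candidates are expected — the rule underdetermines the
structure — and all are returned, ranked by fewest edits and deduplicated by
their canonical labels at $\lambda = 3$.

```{r roundtrip}
rules1 <- extract_rules(toy$db, toy$mols, 1, reg)
site <- match_sites(rules1, "R1", toy$mols$sal)
app <- apply_rule(rules1, "R1", toy$mols$sal, center = site$atoms[[1]])
sapply(app$products[[1]], molecular_formula)
```

## What the synthetic networks emulate — and what they do not

The planted-network generator builds formaldehyde-unit oligomers and their
aza analogues, plants a source-to-target route of single-unit cleavages,
surrounds it with balanced decoys (condensations, dead-end aza cleavages,
random irreversibilities), and returns two extra cleavages separately as
rule donors. Formation energies are synthetic, ordered so the planted
direction is exergonic (about −5 kcal per step). At generation time the
planted optimum is certified by exhaustive integer enumeration — the same
oracle the test suite compares the MILP against — and decoy draws that
shorten the route are redrawn; the same seed regenerates a network
byte-identically.

These networks exercise every constraint family at realistic
combinatorics, but they do not emulate real metabolism: their chemistry is
two homologous families rather than a heterogeneous reactome, their
thermodynamics is monotone by construction, and their molecules are small
chains without rings, stereochemistry, or charge. Passing the oracle and
balance suites therefore demonstrates the correctness of the machinery —
labeling, balances, enumeration, validation — not predictive performance on
a genome-scale database. Test problem sizes (networks of up to 8
metabolites and 10 reactions with flux magnitudes up to 2; 50 seeded
networks in the equivalence suite) were chosen so exhaustive enumeration
remains an exact, independent referee.

## Numerical and design choices

* **Fluxes are integers.** Designed conversions are small integer
  stoichiometries; integer fluxes make enumeration, integer cuts, and
  zero-residual validation exact. Coefficients of known reactions are kept
  as supplied (rationals are normalized on loading).
* **Sorted-multiset keys instead of prime products.** Composing neighbor
  labels by multiplying primes (with bond-order exponents) is elegant but
  overflows double precision on realistic molecules at $\lambda = 3$,
  risking silent collisions; sorting a string encoding of the multiset
  gives the same order-independence guarantee exactly. The prime remains
  the public moiety identifier.
* **Charge is part of the level-0 key**, so a carboxylate and a carboxylic
  acid never collide; protonation states are taken exactly as drawn, with
  no pH-dependent re-protonation (the formation energies already embed
  pH 7.0).
* **One fixed aromaticity convention.** Structures are used as written —
  lowercase SMILES atoms and molfile bond type 4 are aromatic; nothing is
  kekulized or re-perceived, so identical inputs always label identically.
* **Reversibility.** Known reactions follow their database flags; rules
  default to reversible, with per-step direction pins available as
  configuration.
* **Degenerate inputs.** The identity conversion yields an empty change
  map; an all-zero design with zero exchange validates but is flagged
  "empty design"; a rule whose consumed moieties are absent from the
  substrates matches no centers (empty result, not an error); per-reaction
  extraction failures are collected and reported while the run continues.
* **Registry serialization.** Rule files embed the full key-to-prime
  registry, because level-$\lambda$ keys reference lower-level primes;
  restoring a slice would re-derive different primes and break
  comparability across runs.

## Known limitations

Stereochemistry is not perceived and stereo-descriptors are not part of the
labels; moiety sizes above 3 are not supported; rule instantiation edits
the sigma/pi framework only (it will not rewrite delocalized ring systems)
and is best-effort by design; and the annotation toggles treat
organism/pathway memberships as given data rather than as selection
variables. Formation energies are consumed, never estimated — designs over
metabolites without thermodynamic coverage must disable the free-energy row
explicitly.
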