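---
title: "Retrosynthetic pathway design in an extended metabolic space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrosynthetic pathway design in an extended metabolic space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emspath)
```

# The design problem

Metabolic engineering asks: which set of foreign ("heterologous") enzymatic
steps, imported into a chassis organism such as *Escherichia coli*, converts
metabolites the chassis already makes into a target compound it does not?
`emspath` answers this with a pipeline of five stages, each exposed as plain
functions so every intermediate artifact can be inspected, serialized and
tested:

1. **Molecular signatures** encode compound structure at a tunable resolution.
2. **Reaction rules** — signed signature differences — generalize known
   enzymatic reactions and predict *putative* promiscuous reactions,
   producing an *extended metabolic space*.
3. **Retrosynthetic scope** restricts the network to reactions that can lie
   on some precursor-to-target route.
4. **Elementary flux mode (EFM) enumeration** lists every support-minimal
   steady-state route producing the target.
5. **Ranking** scores each route on gene availability, intermediate
   toxicity, maximum allowable yield (by flux balance analysis) and Gibbs
   free energy, and lists the best gene constructs per route.

This vignette explains the model behind each stage, the main parameters with
their defaults, and the numerical choices. The worked example throughout is
the package's built-in raspberry-ketone problem (`raspberry_network()`).

# Molecular signatures

The signature of an atom at diameter $d$ is a canonical string describing its
bonded neighborhood up to radius $d/2$. Atom labels record element, implicit
hydrogen count and formal charge — `[C;H4;0]` is methane's carbon. The
neighborhood is unfolded as a rooted tree: a branch never immediately
backtracks across the bond it arrived by, and rings re-enter as repeated
atoms. Children are serialized in lexicographic order, which makes the string
canonical: it is invariant under any relabeling of the atoms (this is
property-tested with random permutations). The *molecular* signature of a
compound is the multiset of its heavy atoms' signatures, stored as a named
count vector.

```{r}
mol <- parse_structure("CC(=O)CCc1ccc(O)cc1", "smiles")  # raspberry ketone
molecular_signature(mol, diameter = 2)
```

Parsing is delegated to OpenBabel (via `ChemmineOB`/`ChemmineR`), which
kekulizes aromatic input; signatures therefore encode kekulé bond orders.
Any consistent perception scheme works because substrates and products are
processed identically, so the convention cancels in reaction rules.

Two structures are compared with the multiset Tanimoto similarity
$T(a,b)=\sum_k \min(a_k,b_k) / \sum_k \max(a_k,b_k)$, used by
`search_compound()`.

**Diameter.** $d$ must be even (the radius is $d/2$). Small $d$ means coarse,
general chemistry; large $d$ pins down the exact molecular context. The
package default in examples is $d=4$–$6$, a middle ground; the closure tests
run $d \in \{2, 6, 14\}$ because by $d=14$ even the largest fixture cofactors
are fully resolved.

# Reaction rules and network extension

A reaction's rule at diameter $d$ is the signed sum
$\delta = \sum_i s_i \,\sigma_d(m_i)$ over all participants, where $s_i$ is
the stoichiometric coefficient and $\sigma_d$ the molecular signature. The
rule is *applied* to a substrate multiset by computing
$\tau = \delta + \sum \sigma_d(\text{substrates})$: if $\tau$ has no negative
counts, any multiset of known metabolites whose signatures sum exactly to
$\tau$ is a valid product set, found by a depth-first multiset search over
the universe (products are never invented de novo — extension stays inside
the known compound space, which is what makes it a *space* extension rather
than open-ended generation). Two properties follow from the algebra and are
enforced by tests:

* **Closure**: the rule applied to its own template substrates always
  regenerates the template products, at every diameter.
* **Diameter monotonicity**: truncating signatures commutes with the sums,
  so the putative-reaction set at a smaller $d$ is a superset of that at a
  larger $d$ — lowering $d$ models more enzyme promiscuity.

`extend_network()` sweeps all rules over all substrate combinations (with
repetition, in id order) until a fixpoint; because the metabolite set never
grows, convergence is guaranteed. `max_iterations` (default 50) is a safety
valve only. Putative reactions are tagged `origin = "putative"` with the
generating `rule_id` and inherit the template's reversibility, EC class and
gene candidates — the model assumption being that an enzyme promiscuous
enough to accept the analogous substrate carries its own annotations along.

# Scope and pathway enumeration

Enumerating EFMs of a whole network is exponential; the retrosynthetic scope
makes the problem local to the target. `forward_reachable()` computes the
least fixpoint of the firing relation from the chassis seeds (a reaction
fires when all substrates are reachable; side compounds — the cofactor pool —
are always considered available). `backward_prune()` then walks back from
the target, keeping only reactions (in the direction supported by forward
reachability) that produce some needed metabolite.

The scope's stoichiometric matrix gets explicit boundary columns: an
irreversible uptake `EX_<id>_in` per endogenous precursor, a reversible
exchange `EX_<id>` per participating side compound, and a single sink
`SINK_<target>`. Every EFM of this matrix with positive sink flux is one
candidate pathway; its *support* restricted to non-boundary columns is the
enzymatic step list.

EFMs are enumerated with a Schuster-style tableau on the split
(all-irreversible) matrix. The arithmetic is integral: each combined row is
divided by the gcd of its entries, so entries stay exact (doubles are exact
integers below $2^{53}$; fixture-scale problems stay far below that).
Support-minimality is enforced pairwise at every elimination step, futile
two-cycles from splitting reversible reactions are removed, and
fully-reversible modes are reported once in canonical sign. The
implementation is verified set-for-set against a brute-force oracle that
enumerates candidate supports exhaustively and checks one-dimensional signed
nullspaces — an independent algorithm sharing no code with the tableau.

```{r}
fx <- raspberry_network()
pathways <- enumerate_pathways(fx$network, fx$chassis_seeds, fx$target)
length(pathways)
pathways[[1]]
```

The three routes differ in their entry into 4-coumarate — tyrosine
deamination (TAL), cinnamate hydroxylation (C4H), or reduction/dehydration
of 4-hydroxyphenylpyruvate (HPPR + HPLH) — and share the committed steps
4CL, BAS, BAR.

# Ranking

Each pathway is summarized by:

* **Gene score** — mean over steps of the best candidate-gene score
  (a step without candidates contributes 0).
* **Toxicity** — mean $\log_{10}(\mathrm{IC}_{50})$ over *intermediates*
  (compounds both produced and consumed by the steps, excluding precursors,
  side compounds and the target). Missing values are skipped; an
  all-missing pathway scores `NA` and ranks neutrally.
* **Maximum allowable yield** — for each precursor, the chassis' spare
  production capacity is measured by FBA: a synthetic drain is added and
  maximized subject to the model bounds and biomass $\ge \gamma$ times the
  wild-type optimum (`gamma` defaults to 0, i.e. all flux may be diverted).
  The pathway yield is the minimum over precursors of capacity divided by
  stoichiometric demand per unit target; the minimizing precursor is the
  *bottleneck*.
* **Gibbs metrics** — sum of the steps' $\Delta G$ and the count of
  unfavorable ($\Delta G > 0$) steps.

Criteria are min–max normalized across the pathway set (direction-aware:
higher gene score, higher $\log \mathrm{IC}_{50}$, higher yield, lower Gibbs
sum are better; a degenerate spread collapses to the neutral 0.5) and
combined as a weighted sum with unit default weights (`score_weights()`).
Ties break deterministically: fewer steps first, then lexicographic support.

```{r}
ranked <- rank_pathways(pathways, fx$network, raspberry_chassis_model())
ranked
```

Gene constructs — one gene choice per step, scored by the mean of the chosen
genes' scores — are enumerated lazily: `top_constructs()` runs a best-first
frontier search over the per-step sorted candidate lists, so the $k$ best of
a combinatorially large product are found without materializing it. The
result is verified against exhaustive enumeration in the tests.

# Numerical choices

* **LP solver.** Yields use a small dense two-phase primal simplex written
  for this package (Bland's rule, so no cycling; variable shifts absorb
  lower bounds; infinite lower bounds are clamped at $-10^6$, far beyond
  any fixture flux). It is exact at the intended model scale (tens of
  columns) and is validated against hand-solved programs; it is not meant
  for genome-scale models.
* **Tolerances.** Flux/stoichiometry comparisons use $10^{-9}$; the simplex
  uses $10^{-7}$ for feasibility. EFM arithmetic is integral and needs no
  tolerance beyond classifying exact zeros.
* **Determinism.** All orderings (candidate products, substrate
  combinations, pathway lists, tie-breaks) are lexicographic by id, so every
  run of every stage is reproducible bit-for-bit.

# The built-in fixtures

`raspberry_network()` is a complete, hand-curated design problem: 21
metabolites, all with full SMILES (oxidized nicotinamide cofactors are
written as net-neutral inner salts and reduced ones fully protonated, so all
seven reactions element-balance exactly without a free-proton species), and
synthetic gene scores, toxicities and $\Delta G$ values at realistic
magnitudes — they are inputs to the ranking machinery, not literature
measurements. `random_network()` generates seeded networks with planted
precursor-to-target routes and decoy reactions that provably never produce
the target, so planted routes are always recovered; it drives the
property-based tests. Its parameters (route depth, distractor count, decoy
pool size) are study conditions: tests use them as given rather than tuning
them to outcomes.

# Limitations

* Products of rule application are restricted to known metabolites; truly
  novel compounds require externally supplied structures.
* The EFM tableau targets scope-sized problems (tens of reactions), not
  genome scale, as does the simplex.
* Aromaticity is fixed by OpenBabel's kekulization; signatures at small
  diameters can differ from aromatic-bond-typed schemes, consistently so
  across the package.
* Thermodynamic and toxicity inputs are user-supplied scalars; no
  group-contribution estimation is included.
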