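---
title: "Methods: minimum-cost gap filling, auditing, and benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: minimum-cost gap filling, auditing, and benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapfillr)
```

## The modeling problem

A genome-derived metabolic reconstruction is a set of stoichiometric
reactions plus a growth condition: nutrients the environment supplies (with
maximal uptake rates), metabolites the cell may excrete, and the biomass
metabolites it must synthesize. Because genome annotation misses enzymes,
such networks usually cannot reach all biomass metabolites from the
nutrients; gap filling selects reactions from a reference database whose
addition restores that capability. `gapfillr` implements the
parsimony-based formulation of this problem, together with the quality
control a user of any gap filler needs: an audit for solver-imprecision
artifacts, a minimality check, an exact oracle for validation, accuracy
scoring against reference solutions, and a synthetic benchmark generator.

## Growth as a linear program

Internally every model is compiled to a split stoichiometric matrix
(`build_matrix()`): irreversible reactions contribute one nonnegative flux
column, reversible reactions a forward/backward pair (entrywise negations),
and the condition contributes uptake columns (bounded by the uptake rates),
export columns, and one biomass demand column consuming the biomass
metabolites in their coefficients. `solve_fba()` maximizes the demand flux
subject to steady state `S v = 0` and the bounds; `grows()` compares the
optimum against the activity threshold. Defaults, all configurable:

| parameter | default | meaning |
|---|---|---|
| uptake bound | 10 flux units | maximal uptake per nutrient when unstated |
| biomass threshold | 1e-3 | minimal demand flux counted as growth |
| `B_l` | 1e-3 | minimal flux of a reaction considered active |
| `B_u` | 3000 | maximal flux of a selected candidate |
| mass-balance tolerance | 1e-6 | accepted `max(abs(S v))` of a solution |

Flux units are arbitrary but consistent; only ratios of bounds matter for
the qualitative results. Biomass is modeled two ways on purpose: a single
lumped demand consuming all biomass metabolites jointly (used by `grows()`
and the gap filler, which must enable *all* of them), and per-metabolite
single demands (used by `producible_biomass_subset()` to diagnose *which*
biosynthetic routes are broken). Biomass coefficients default to 1 per
metabolite; a weighted biomass is supported but the package's growth
questions are yes/no, so the weights rarely matter.

The LP engine is a dense two-phase primal simplex with Bland's rule,
written for this package: the LPs are small (tens to a few hundred
variables), exactness and auditability matter more than speed, and keeping
the solver in-package means its tolerances (pivot tolerance 1e-9) are not a
hidden external dependency. Hand-solved LPs in the test suite pin its
behaviour, including infeasible and unbounded cases.

## The gap-filling program and how it is solved

Gap filling minimizes

$$\sum_r c_r\, s_r + w_{\mathrm{rev}} \sum_q \mathit{rev}_q$$

over binary selections, subject to steady state on the union network, the
strict growth constraint (implemented as `>= threshold + 1e-9`, since an LP
cannot express a strict inequality), and the indicator coupling
$B_l s_r \le f_r \le B_u s_r$ per action. Insertion costs encode taxonomic
range (`w_insert_in_taxon = 2` inside, `w_insert_out_taxon = 4` outside);
reversing an existing irreversible reaction costs `w_reverse = 1`. Only the
strict ordering of the three weights is scientifically meaningful; the
numeric values are the package's defaults and any weights respecting the
ordering give the same qualitative preferences. Polymerization reactions
are excluded from the candidate set by default, mirroring the standard
restriction that such reactions cannot be instantiated meaningfully during
automated gap filling.

Reversal actions exist for every irreversible model reaction
(`allow_reversals = TRUE`); a reversal relaxes the reaction to reversible,
it never deletes anything. The candidate's binary gates both directions of
a reversible candidate — one decision per reaction.

### Why not big-M branch-and-bound

The textbook route — solve the LP relaxation of the big-M form, branch on
fractional binaries — fails on this structure in an instructive way. The
relaxation puts $s_r \approx f_r / B_u$; with $B_u = 3000$ and fluxes of
order 10, every binary sits near $3\times10^{-3}$ or below, so (a) the
relaxation bound is essentially zero and the tree degenerates to
enumeration, and (b) a binary can be *below any reasonable integrality
tolerance while its reaction carries load-bearing flux*, so a naive solver
"rounds" it to zero and returns a selection whose fluxes contradict it —
precisely the indicator-violation artifact that `audit_solution()` exists
to detect in third-party solver output. The package's generic
`milp_solve()` guards against (b) by accepting an incumbent only after
re-solving with all binaries fixed at their rounded values (a regression
test constructs the trap), but (a) is inherent to the formulation.

`gapfill()` therefore solves the identical program by exact implicit
enumeration: uniform-cost branch-and-bound over the action binaries where
gating is imposed combinatorially — an unselected action's flux columns are
capped at zero, a selected one's at `B_u`. Each node carries a fixed-in and
a fixed-out set and is pruned by two LPs: a relaxation prune (if even with
every unfixed action available the model cannot grow, no descendant is
feasible) and an acceptance test (if the fixed-in set alone grows, the node
is a feasible selection). Nodes are expanded in increasing cost, so the
first accepted node is a minimum-cost solution; branching follows the
action carrying the most flux in the relaxation LP, which keeps trees small
in practice. Equal-cost ties are resolved by an epsilon cost perturbation
(1e-4 divided by the action count — far below the smallest weight gap) in
lexicographic id order, making results deterministic; `seed` in
`gapfill_config()` switches the perturbation to a seeded random order to
emulate the arbitrary tie selection real solvers exhibit, without ever
affecting the optimal cost. `enumerate_equal_cost_solutions()` makes tie
sets explicit by re-solving under integer cuts until the optimum cost
rises.

Every solution is re-validated independently of the search: a fresh growth
LP on the completed model (`growth_recheck`) and an indicator audit on the
final flux state. Trusting the selection search's own claim of feasibility
is exactly the habit the audit module is designed to break.

## Post-hoc quality control

`audit_solution()` is a pure function of a solver state: it flags
`s_r = 0` with `|f_r| >= B_l` (an unselected reaction carrying active flux
— the typical big-M artifact) and `s_r = 1` with `|f_r| > B_u + 1e-9`.
Property-based tests compare it against its own definition on randomized
states.

`verify_minimality()` re-implements the iterative-removal check: attempt to
drop each solution reaction, in descending cost order with lexicographic
tie-break (the order is a package choice — descending cost biases toward
discarding expensive redundancy; an order effect on *which* minimal set
results is possible and documented, not hidden), keeping the removal when
the model still grows. The result is *a* minimal set — every member
essential — but greedy removal cannot certify it is the *minimum-cost*
completion; the distinction is real and the test suite exercises it with
planted-redundancy benchmarks.

`brute_force_min_gapfill()` enumerates action subsets in increasing cost
and returns the first that grows. It deliberately spans the same action
space as the MILP (insertions plus reversals, under the same
`allow_reversals` switch); an oracle over a smaller action space would not
be a valid equality check. It refuses more than 20 actions and searches
subsets up to `max_size` (default 6) — an exact oracle for small instances,
not a practical solver.

## Synthetic benchmarks

`generate_truth()` builds seeded random networks shaped like biosynthetic
pathway trees: nutrients at the root, one producing backbone reaction per
non-nutrient metabolite (guaranteeing reachability), plus redundant branch
reactions; a configurable fraction of reactions is reversible, and biomass
metabolites are drawn from the downstream half of the network. Stoichiometry
is unit 1-to-1: the generator emulates network *topology* (reachability,
redundancy, directionality), which is what gap filling operates on, not
cofactor coupling, compartments, or realistic stoichiometric ratios — so
passing recovery tests demonstrates correctness of the selection machinery,
not fidelity to any real organism. Default dimensions (20 metabolites, 24
reactions, 2 nutrients, 3 biomass metabolites) keep instances solvable by
the brute-force oracle; test and acceptance runs use 10-metabolite
instances so that hundreds of paired solver/oracle runs complete in
minutes.

`make_benchmark()` deletes seeded-chosen *essential* reactions
(essentiality established by single-deletion FBA, so the gapped variant
provably fails to grow) and assembles a database of the deleted reactions
plus decoys. Decoys are mass-balanced reactions over fresh metabolites
disconnected from the biomass-reachable network — they can never enable
growth, so ground truth remains a feasible completion and the oracle
comparison is clean; a seeded fraction is flagged out-of-taxon to exercise
the cost model. Note the recovered set may legitimately differ from the
deleted set at lower cost (e.g. reversing a surviving branch reaction,
cost 1, instead of re-inserting a deleted reaction, cost 2); benchmarks
therefore compare *costs* against the oracle rather than demanding set
identity. `n_redundant` plants duplicates (fresh ids) of reactions still
present in the gapped model into the solution handed to
`verify_minimality()`, giving a known count of removable reactions. If a
seeded truth network has fewer essential reactions than requested
deletions, the constructor raises a parameter error; benchmark loops in the
tests scan forward deterministically to the next valid seed.

All generator randomness flows through a single seed with save/restore of
the global RNG state, so benchmarks are reproducible across machines and
never perturb a user's session RNG.

## Accuracy scoring and the packaged reference data

`evaluate_solution()` computes tp/fp/fn, recall `tp/(tp+fn)` and precision
`tp/(tp+fp)` over exact id matches; near-equivalent reactions under
different ids (a CoA-specific versus an acyl-carrier-protein variant of
the same transformation, say) score as one fp plus one fn, the strict
convention used in published comparisons. Inputs are sets; empty inputs are
errors naming the empty side.

`load_fixtures()` ships the reference tables of a published gap-filling
comparison on a *Bifidobacterium longum* subsp. *longum* JCM 1217 model:
53 biomass metabolites (15 producible before gap filling), the automated
12-reaction solution with its 2 excess reactions flagged (leaving the
10-reaction minimum set), the manual 13-reaction solution (8 reactions
shared), and 28 direction-curated reactions. These are packaged data for
scoring demonstrations and regression tests; reproducing the underlying
organism-scale computation would require the original reaction database and
reconstruction and is out of scope here.

## Numerical choices and degenerate inputs

- Strict growth inequality as `>= threshold + 1e-9`; LP feasibility
  tolerance 1e-9; mass-balance acceptance 1e-6 (violations raise an error
  rather than returning a silently bad flux state).
- Reactions with unset direction in input files are imported as
  `REVERSIBLE` with a warning — never silently inferred, since direction
  inference is a known source of irreproducibility.
- Exchange and demand reactions are generated from the condition, never
  read from reaction tables; the `EX_`/`SEC_`/`DM_` id namespace is
  reserved and such ids are the only ones allowed to be one-sided.
- Duplicate ids anywhere are hard errors; ids are case-sensitive.
- An already-growing model gap-fills to the empty solution at cost zero; a
  model infeasible even with the full database returns status
  `"infeasible"` plus the list of unproducible biomass metabolites.
- A model with no nutrients produces nothing (conservation); the empty
  model round-trips through both file formats.

## Known limitations

- The simplex/branch-and-bound core targets the package's instance sizes
  (hundreds of variables); it is not a general-purpose solver and makes no
  attempt at sparse factorization or warm starts.
- Single-compartment semantics: compartment suffixes are carried through
  but no transport reactions are inferred.
- Greedy minimality verification is order-dependent by nature; the order is
  fixed and documented, not optimized over.
- The synthetic generator's networks are topological caricatures (see
  above); conclusions about real genome-scale models require real models.
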