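---
title: "Ensemble-objective FBA knockdown screening: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-objective FBA knockdown screening: models, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxscreen)
```

## The question the screen answers

Constraint-based metabolic models describe a cell's metabolism as a
stoichiometric matrix $S$ (metabolites $\times$ reactions) plus flux bounds
$l \le v \le u$ on every reaction. Flux balance analysis (FBA) finds, for a
chosen objective reaction $j$, the largest steady-state flux it can carry:

$$\max_v \; v_j \quad \text{s.t.} \quad S v = 0, \; l \le v \le u .$$

Choosing a single cellular objective (growth, ATP yield) is contentious for
differentiated tissue such as hepatocytes. The ensemble-objective screen
sidesteps that choice: *every* reaction is maximized in turn, under
wild-type bounds and again under gene-knockdown bounds, and the quantity of
interest is how much of each reaction's maximal attainable flux survives
the perturbation,

$$r_j \;=\; 1 - \frac{\max v_j \,|\, \text{knockdown}}
                     {\max v_j \,|\, \text{wild type}} .$$

A reaction with $r_j$ at or above a threshold is *compromised*; compromised
reactions are tallied per curated subsystem label to point at the pathways
a perturbation touches. The screen is a qualitative, system-wide
highlighting device, not a quantitative flux prediction: degenerate optima
are everywhere in genome-scale models, so only the optimal *values* carry
meaning, never the particular flux vectors.

## Knockdown semantics

A fractional knockdown of gene $g$ with scale factor $f \in [0, 1]$
(default 0.5) rescales the bounds of every reaction whose
gene-protein-reaction (GPR) rule mentions $g$ as a leaf:

* $u' = f\,u$ when $u > 0$, otherwise $u$ unchanged;
* $l' = f\,l$ when $l < 0$, otherwise $l$ unchanged.

Both choices pull the feasible flux interval toward zero: an irreversible
reaction keeps its zero lower bound, a reversible reaction shrinks
symmetrically so that "maximum flux" is reduced in both directions (whether
reversible lower bounds should be rescaled is genuinely open; symmetric
shrinking is the direction-agnostic reading and the one we adopt).
Association by leaf membership deliberately ignores AND/OR structure:
scaling bounds wholesale models a dose-like reduction in enzyme capacity,
whereas boolean GPR evaluation answers a different question (can isozymes
rescue a complete knockout?). A strict GPR-aware mode is out of scope.

Because knockdown only shrinks bounds, the knocked feasible region is
contained in the wild-type region, so no objective's maximum can increase.
This containment is the load-bearing property of the screen and is tested
both on constructed fixtures and across hundreds of seeded random networks.

## Classification rules and degenerate cases

* **Blocked objectives** (wild-type maximum $\le$ the solver tolerance,
  $10^{-9}$): reduction is defined as 0 and the record flagged; a reaction
  that cannot carry flux cannot be compromised, and the convention avoids
  0/0.
* **Non-optimal statuses** (infeasible or unbounded subproblems, which open
  exchanges in published models can produce): the record is excluded from
  classification with a warning instead of aborting the screen, and
  unboundedness is reported as such, never silently capped — a capped value
  would corrupt every reduction fraction computed from it.
* **Threshold**: default 0.25. Knockdown at factor 0.5 produces reductions
  of exactly 0.5 on fully coupled reactions and strictly less where bypass
  capacity exists; 0.25 separates genuine propagation from numerical zeros
  while remaining permissive for partially buffered reactions. Comparisons
  use a $10^{-6}$ tolerance so a reduction of $0.25 - 10^{-8}$ still
  counts.
* **Objective set**: all non-boundary reactions by default. Boundary
  exchange pseudo-reactions describe the medium, not cellular capability;
  transport and excretion reactions across internal membranes remain in the
  set. The CLI flag `--objectives all` widens the set.

## The linear-programming backend

The package ships its own dense two-phase primal simplex with Bland's
anti-cycling rule (`solve_lp()`). Box bounds are reduced to standard form
by shifting (finite lower bound), mirroring (only the upper bound finite)
or variable splitting (both infinite), so infeasibility and unboundedness
fall out of the algorithm naturally rather than via big-M surrogates.
Bland's rule guarantees finite termination on the degenerate bases that
metabolic networks produce in abundance; the price is speed, which is
irrelevant at the problem sizes screened here (hundreds of LPs with tens
of variables each run in seconds). Pivot and feasibility tolerances default
to $10^{-9}$; optimal solutions are verified in the test suite to satisfy
$|Sv| \le 10^{-9}\max(1, \lVert v\rVert_\infty)$ and the bounds to
$10^{-9}$.

The solver is validated against an independent brute-force oracle:
exhaustive vertex enumeration of $\{Sv = 0,\; l \le v \le u\}$ (every
linear optimum sits on a vertex, and every vertex fixes at least
$n - \operatorname{rank}(S)$ coordinates on bounds). The oracle is
exponential and used only on fixtures with few reactions; on the larger
valine toy model, whose reactions all convert one metabolite into one
metabolite with unit coefficients, an exact max-flow/min-cut oracle
(igraph) takes its place.

## Synthetic models: what they emulate and what they do not

The generators define the study conditions for every exact-value test.

* `make_linear_chain()` — a source-to-sink pathway with one designated
  strictly-smallest bound. On a chain every internal reaction is
  flux-coupled, so a factor-$f$ knockdown of the bottleneck reduces every
  maximum by exactly $1 - f$.
* `make_bypass_model()` — two parallel branches of capacities $b_1$
  (gene-associated) and $b_2$ rejoining before the sink: the downstream
  maximum falls from $\min(s, b_1 + b_2)$ to $\min(s, f b_1 + b_2)$, giving
  closed-form partial reductions (0.25 at $b_1 = b_2$, $f = 0.5$).
* `make_valine_pathway_model()` — a deterministic 25-metabolite,
  31-reaction caricature of hepatic valine catabolism: valine uptake,
  transamination, the branched-chain ketoacid dehydrogenase complex
  (an AND rule over BCKDHA/BCKDHB/DBT/DLD), the HIBCH hydrolysis step as
  the unique bottleneck (upper bound 10 versus 100 elsewhere),
  3-hydroxyisobutyrate export, the methylmalonate and propionyl-CoA
  branches, a minimal TCA loop, an independent glucose branch with acetate
  export, and a fatty-acid uptake/carnitine-shuttle pair. Cofactors, ATP
  and redox balancing are deliberately omitted: the fixture's job is known
  flux arithmetic, not biochemical completeness. Under a 50% HIBCH
  knockdown, exactly the valine-branch ("BCAA metabolism") and
  propanoate-branch reactions halve their maxima; glucose, TCA-loop and
  fatty-acid reactions are untouched.
* `make_random_network()` — seeded sparse networks built on a guaranteed
  source-to-sink backbone (so fixtures are never vacuously blocked), with
  random extra reactions, reversibility (probability 0.3), bounds and gene
  labels. Used only for property fuzzing: containment, factor-1 identity,
  factor-0 equivalence with outright deletion, determinism. Default size
  is 8 metabolites and 14 reactions; the containment suite runs 200 seeds,
  which the test suite completes in well under a minute.
* `make_medium_table()` — conditioned-medium concentration tables with
  known ground-truth appearance rates: unconditioned baseline (50 µM)
  plus `rate × duration` plus optional Gaussian noise on the conditioned
  measurement.

Passing these tests demonstrates that the screen arithmetic, propagation
and classification are correct under exactly known conditions. It does
*not* demonstrate that a published genome-scale reconstruction will yield
any particular hit list: real models add isozyme redundancy, cofactor
coupling, thermodynamically questionable loops and open exchanges, all of
which move individual reductions away from the clean $1 - f$.

## Net medium appearance rates

For a metabolite measured in culture medium before and after a
conditioning period of `duration_h` hours (default 24), the net appearance
rate is

$$\text{rate} = \frac{C_\text{conditioned} - C_\text{unconditioned}}
                      {\text{duration}} \quad [\mu M/h],$$

positive for net release by the cells and negative for net consumption.
The orientation is chosen so that released metabolites plot positive in
"net medium appearance" summaries; the subtraction is sometimes written in
the opposite order in methods prose, which merely negates the sign.
`summarize_rates()` reports mean, SEM (sample SD/$\sqrt{n}$; `NA` for
$n = 1$) and $n$ per metabolite-group cell; hypothesis testing is left to
standard tools downstream.

## SBML dialect

Models are read and written as SBML Level 3 with the fbc v2 extension.
Bounds resolve in order: fbc parameter references (authoritative;
a dangling reference is a format error naming the reaction), kinetic-law
parameters named `LOWER_BOUND`/`UPPER_BOUND` (legacy COBRA encoding),
then defaults of $(-1000, 1000)$ for reversible and $(0, 1000)$ for
irreversible reactions with a warning. Species flagged
`boundaryCondition="true"` are not mass-balanced and are dropped from all
stoichiometries; a reaction left with no species after the drop constrains
nothing and is removed with a warning. Subsystems travel in COBRA-style
`SUBSYSTEM:` note paragraphs; gene associations as fbc gene-product trees
(with `GENE_ASSOCIATION:` notes as a read fallback). Stoichiometric
coefficients are written at full precision and never rounded.

## Known limitations

* Gene-id namespaces are the caller's responsibility: the perturbed gene is
  matched verbatim against GPR leaves (HGNC symbol, Ensembl id, whatever
  the model uses).
* No parsimonious, loopless or thermodynamic FBA; internal cycles can and
  do carry bound-limited flux, as in any plain FBA.
* The dense simplex targets screen-scale problems; genome-scale models
  with thousands of reactions will work but slowly, and a sparse
  production LP backend would be the natural extension point
  (`solve_lp()` is the single seam).
* Exact reproduction of hit lists from published reconstructions depends
  on that model file and on classification conventions (threshold,
  exclusion of non-optimal objectives) that published analyses rarely
  print; the screen exposes both as explicit parameters instead.
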