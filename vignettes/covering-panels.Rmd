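---
title: "Covering marker panels: model, solver and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covering marker panels: model, solver and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellcover)
```

## The problem

Single-cell RNA-seq suffers pervasive stochastic zero-inflation: a gene that
is biologically active in a cell type is still undetected in many individual
cells of that type. A single "best" marker gene therefore fails to label a
substantial fraction of cells. `cellcover` selects marker *sets* whose
collective binarized expression labels cells despite dropout: a panel covers
a cell when at least `d` of its genes are detected, and the panel is chosen
so that at least a fraction `1 - alpha` of the class's cells are covered,
at minimal total gene weight.

## The model

Counts are binarized: gene $g$ is *expressed* in cell $c$ iff its count
exceeds a threshold $\theta$ (default 0, i.e. raw count $\ge 1$; the
comparison is strictly greater, so normalized non-integer matrices also
behave sensibly). Write $u_g(c) \in \{0, 1\}$ for the indicator and $S_k$
for the cells of class $k$.

For a target class $k$, panel selection is the integer program

$$
\min_{z, s} \sum_{g \in G_k} w_{g,k}\, z_g
\quad\text{s.t.}\quad
\sum_{g} z_g u_g(c) \ge d\, s(c) \;\; \forall c \in S_k,
\qquad
\sum_{c \in S_k} s(c) \ge \lceil (1-\alpha)\,|S_k| \rceil ,
$$

with $z_g = 1$ when gene $g$ enters the panel and $s(c) = 1$ when cell $c$
counts as covered — a weighted *partial set multi-cover*: each covered cell
needs coverage multiplicity $d$, and an $\alpha$ fraction of hardest cells
may be left uncovered. The ceiling is the tightest integer reading of the
rate constraint.

### Weights

A gene's weight measures how poorly it separates class $k$ from the rest;
the solver prefers small weights. Per-class expression probabilities
$m_{g,k}$ are empirical frequencies (no shrinkage). Schemes:

* `mean_ratio` (default): $\big(\sum_{l \ne k} m_{g,l}/(K-1)\big) / m_{g,k}$;
* `max_ratio`: $\max_{l \ne k} m_{g,l} / m_{g,k}$ — more conservative, equal
  to `mean_ratio` when $K = 2$;
* `lognorm_ratio`: the `mean_ratio` formula applied to per-class means of
  log-normalized expression (see below); covering constraints stay binary;
* `bonferroni`: the pooled off-class expression probability
  $P(U_g = 1 \mid Y \ne k)$, an additive (Bonferroni) upper bound on the
  probability that any panel gene fires off-class;
* `log_complement`: $-\log(1 - P(U_g = 1 \mid Y \ne k))$, the additive form
  of the off-class silence probability under conditional independence.

Candidate genes must be discriminative ($w_{g,k} \le 1$) and detectable
($m_{g,k} \ge$ `min_expr`, default 0.1). A zero denominator yields weight
$+\infty$ (never a candidate); a perfectly specific gene (off-class
probability 0, in-class positive) has weight 0 and sorts first.

Two points the formulas leave open were fixed as follows:

* *Log-normalization* is not defined by the weighting scheme's description;
  we use the field's convention — per-cell depth scaling to a target sum of
  10,000 followed by $\log(1 + x)$ — and expose the target sum. Only the
  weight *ordering* matters to the optimizer, so the exact convention is not
  critical.
* The pooled off-class probability is computed *cell-weighted* (pool all
  non-$k$ cells), not as an average of class-wise rates; the two differ
  under class imbalance, and the class-averaged quantity is already
  available as `mean_ratio`'s numerator.
* Only one-vs-all weighting is implemented. A one-vs-nearest-neighbor
  variant is sometimes mentioned in this literature but has no agreed
  definition of "nearest"; we leave it out rather than invent one.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `depth` (d) | 1 | genes a cell must express to be covered (dimensionless count) |
| `alpha` | 0 | tolerated uncovered fraction of the class |
| `theta` | 0 | binarization threshold, count units (strict `>`) |
| `scheme` | `mean_ratio` | weight scheme |
| `min_expr` | 0.1 | minimum in-class detection probability for candidates |
| `max_weight` | 1 | candidate weight cutoff |
| `time_limit` / `node_limit` | 600 s / 5e7 | solver budget before `gap_reported` |

Raising `d` buys redundancy against dropout at the cost of larger panels;
raising `alpha` shrinks panels by abandoning the hardest cells. Both
monotonicities are asserted by tests.

## The solver

No MILP library is assumed. The `ilp` back-end is a specialized exact
branch-and-bound written in C++ for this one problem class:

* genes are presented to the search sorted by ascending weight (ties broken
  by gene id), which both fixes determinism and makes the include-first dive
  produce a good initial leaf;
* a greedy solution (see below) provides the initial incumbent;
* nodes are pruned with the maximum of two lower bounds: a
  fractional-knapsack bound on the *coverage units* still needed by the
  `n_required` easiest-to-finish coverable cells, and a cardinality bound
  (any covered cell expresses $\ge d$ selected genes, so every feasible
  panel has at least $d$ genes);
* cells that cannot reach depth $d$ even with all remaining genes are
  excluded from the demand calculation but still consume the `alpha` budget
  — dropping them would change `n_required` and be wrong;
* forced genes (nested expansion) are committed before the search, so the
  superset constraint is exact, not heuristic.

The search is complete: within budget the returned solution is a proven
optimum (`optimal`). On exhausting `node_limit`/`time_limit` the best
incumbent is returned as `gap_reported`. The achieved covering rate is
always recomputed in R from the returned panel rather than trusted from the
solver. Equal-objective optima are genuinely non-unique in this problem;
tests therefore assert on objective values, never on gene identity, except
in planted-marker simulations constructed to have unique optima.

Two independent routes check the solver. `brute_force_cover` enumerates all
gene subsets (capped at 20 genes) in pure R and is the test oracle: on
hundreds of random instances the branch-and-bound matches its objective
exactly, and during development both were additionally cross-checked against
an external MILP solver. `greedy_cover` iteratively adds the gene with the
best newly-satisfied-demand-per-weight ratio over the `n_required`
easiest-to-cover cells; it is the warm start, the fallback for instances too
hard to solve exactly, and by construction an upper bound on the optimum.

Infeasibility is never silent: when even the full candidate set cannot cover
`n_required` cells at depth `d`, the result carries status `infeasible` with
the maximum feasible covering rate, so the caller can raise `alpha` or lower
`d` deliberately.

### Nested expansion

Growing a panel to a larger depth re-solves the program with $z_g \ge
z^{(0)}_g$ for the initial panel — the result is a superset, its objective
at least the unconstrained optimum at the new depth. Whether `alpha` may
change between the initial fit and an expansion is left open in the
literature; both are accepted here and recorded in the panel's config.

## Panel transfer, mapping and metrics

Transferring a panel to another dataset uses exact gene-id matching only
(orthologs must be pre-mapped). Panel genes missing from the target are
dropped from numerator *and* denominator, and `panel_genes_found` is always
reported — this is the only convention that keeps proportions in $[0,1]$
without inventing values. Covering rates per target class use $\ge d$ by
default with a strict-greater flag, since published figures sometimes count
"more than d" genes. Bulk samples are scored by summed panel expression
normalized by the maximum sum; whatever scale the caller supplies (raw or
normalized) is used as given.

Cell-type mapping computes raw covering rates of each source panel against
every target class (default depth 5), 0–1 normalizes them within each
source class, and maps pairs whose normalized rate strictly exceeds 0.8.
When a panel has fewer genes in the target than the requested depth, the
depth is lowered to the panel size and logged. When a source class's raw
rates are constant the normalization is undefined; the class is reported
unmapped with a warning rather than given an invented value.

Quality metrics: panel-set *redundancy* (fraction of the global panel's
genes claimed by two or more classes), *intersection* with a reference
global panel (normalized by reference size), and *balanced accuracy* (mean
per-class recall, zero-support classes excluded and flagged). As a
transparent size-matched baseline, `frequency_rank_reference` ranks genes by
$m_{g,k} - \max_{l \ne k} m_{g,l}$ — a per-gene criterion blind to overlap
between classes, which is exactly the weakness the covering objective
addresses.

## The synthetic world

`simulate_counts()` generates what the covering model assumes: per-class
Bernoulli expression with planted markers (`p_in = 0.9` in class,
`p_out = 0.05` outside, 10 markers per class, 3 classes of 200 cells, 200
background genes at `p_bg = 0.3`), optional extra dropout, and positive
counts drawn as $1 + \text{Poisson}(\lambda)$ so binarization at
$\theta = 0$ recovers the Bernoulli layer exactly. The marker parameters are
the stated conditions of the parameter-recovery test; `p_bg`, and
$\lambda$ of 2 (markers) vs 1 (background), were chosen once as values a
practitioner would call realistic for moderately expressed genes and are
not tuned. Each gene has its own deterministic RNG substream derived from
the seed, so enlarging the gene set never perturbs existing genes and
identical configs are bit-identical.

The sibling scenario plants a class pair sharing a fraction `rho` of their
markers at full `p_in` in both — a controlled redundancy trap: a per-gene
ranking happily selects shared markers for both siblings, while the
covering objective, seeing their high off-class probability, prefers each
sibling's cheap unshared markers. On this world the covering panels'
redundancy is never above the size-matched frequency-difference baseline
(in the default regime both are typically zero, because five unshared
markers already cover at depth 3 — the test asserts the inequality, not a
gap).

What the generator does *not* emulate: real droplet chemistry, ambient RNA,
doublets, gene–gene correlation within a class beyond the class structure
itself, or realistic library-size variation. A green planted-marker test
establishes that the estimator and solver do what they claim on data
satisfying the model's assumptions — not that panels on real tissue will be
as clean.

## Degenerate inputs and numerical choices

* `n_required` is computed as $\lceil (1-\alpha) n - 10^{-9} \rceil$; the
  epsilon guards against floating fuzz like $0.75 \times 4$ evaluating just
  above 3.
* Objective comparisons in the solver use a $10^{-9}$ pruning tolerance;
  weights are user-scale quantities of magnitude $\le$ ~1.5 in practice.
* Empty candidate sets, classes whose cells express nothing, and
  generatively identical class pairs all yield reported
  infeasible/degenerate results, never crashes; `fit_all_classes` isolates
  per-class failures.
* Readers never guess matrix orientation; `cells_by_genes` must be stated
  explicitly.

## Known limitations

* The exact solver's worst case is exponential; pathological instances fall
  back to `gap_reported` incumbents. Candidate filtering (`w <= 1`,
  `min_expr`) is what keeps realistic instances small, as intended by the
  formulation.
* Gene-id aliasing and ortholog mapping are out of scope by design.
* The frequency-difference baseline is a stand-in for external
  differential-expression rankings; plugging in a real DE ranking is a
  one-liner (any ordered gene list can be wrapped with `marker_panel()`).
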