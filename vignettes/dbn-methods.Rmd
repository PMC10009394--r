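---
title: "Learning symptom dynamics: two-slice DBNs and posterior intervention effects"
author: "dbncausal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning symptom dynamics: two-slice DBNs and posterior intervention effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbncausal)
```

## The problem

Longitudinal symptom panels in psychiatry — here the motivating shape is a
cohort of people with long-standing schizophrenia rated on nine PANSS items
(delusions, hallucinations, excitement, grandiosity, persecution, hostility,
anxiety, poor attention, poor impulse control) and three CDSS items
(depressed mood, hopelessness, self-depreciation) at five waves six months
apart — raise a causal question that cross-sectional networks cannot answer:
which symptoms *drive* which others over time?  `dbncausal` addresses it
with a first-order stationary **dynamic Bayesian network (DBN)** over binary
symptom indicators, learned in a fully Bayesian way, followed by posterior
distributions of **do-calculus intervention effects** between adjacent
time-slices.

## The model

Each wave is a time-slice over the same $n$ binary variables.  The DBN has
two parts, both assumed stationary (identical across slices):

* a within-slice DAG $W$ describing contemporaneous dependence, shared by
  every slice;
* a between-slice matrix $B$ whose edges run from a variable at time $T$ to
  a variable at time $T+1$; any such edge is admissible — time already
  orients it — including the diagonal "momentum" edge of a variable on its
  own next-slice copy.

Unrolling $(W, B)$ over two slices gives a $2n$-node DAG: $W$ on each slice
and $B$ across.  Acyclicity of $W$ makes the unrolled graph acyclic
automatically, and no edge can run backwards in time by construction.

Data enter as a **transition table**: one row per (participant, adjacent
wave pair) with complete data on all $2n$ values.  Participants with
several complete pairs contribute one row per pair, treated as independent
observations — the pooling that stationarity licenses.  Completeness is
judged per pair, never per participant, and no imputation is done.

### Dichotomization

PANSS items (scored 1–7) are coded present at the conventional
moderate-severity cutoff, a rating of 4 or above.  CDSS items are scored
0–3 and have no comparable convention; we default to $\ge 2$ ("moderate")
and expose the cutpoint in `dichotomize()` — analyses sensitive to this
choice should vary it.

## Scoring

Every child node is scored by the BDeu marginal likelihood: with $q = 2^k$
parent configurations and per-cell prior weight $\alpha = \mathrm{ess}/(2q)$,

$$\log \prod_j \frac{B(\alpha + k_j,\ \alpha + m_j)}{B(\alpha, \alpha)},$$

computed in the log domain via `lbeta`.  A slice-2 node is scored on the
transition rows given its $W$-parents (slice-2 columns) and $B$-parents
(slice-1 columns); a slice-1 node is scored on the slice-1 columns given
its $W$-parents, so the prior time-point's data also inform the
within-slice structure (switch off with `score_first_slice = FALSE` for
sensitivity analysis).  The score is decomposable per child node, which is
what both the score-table precomputation and the sampler exploit.

Defaults that the data cannot identify and must therefore be declared:
equivalent sample size `ess = 1` (weakly informative BDeu), a uniform
structure prior (optional per-edge penalty `edge_penalty`, applied once per
edge so the prior is $e^{-\gamma(|W|+|B|)}$), and a parent-set cap
`max_parents = 4`, which keeps the exhaustive parent-set tables tractable
($\sum_{k \le 4}\binom{2n-1}{k}$ sets per node, about $10^4$ at $n = 12$).

## Sampling structures: partition MCMC

Maximising the score would pick one network; instead we sample networks in
proportion to $\exp(\mathrm{score})$ so that better-fitting graphs appear
more often, and propagate the structure uncertainty downstream.  The
primary sampler is a **partition MCMC**: a within-slice DAG maps uniquely
to an ordered partition (layering) of the nodes — layer 1 the parentless
nodes, a node in layer $m \ge 2$ having all parents in earlier layers and
at least one in layer $m-1$.  The chain walks over layerings; the score of
a layering sums, per child, over all parent sets consistent with it, with
between-slice parents (always admissible) marginalised analytically inside
each child's sum.  Moves are: relocate a node (probability 0.5), split a
layer (0.2), merge adjacent layers (0.2), and swap a node between adjacent
layers (0.1); relocation and swap are symmetric proposals, split/merge
carry the usual Hastings correction.  At each thinning point a concrete
$(W, B)$ is drawn conditional on the layering in proportion to its score.
Sampling over layerings rather than single edges is what lets the chain
cross between score-equivalent arrangements that single-edge moves cannot
connect.

A **structure MCMC** baseline (single-edge toggle and edge-reversal
Metropolis moves) is retained for cross-validation.  On its own such a
chain gets trapped: with an informative posterior and a parent-set cap,
escaping a local mode requires passing through states tens of log-units
worse.  The baseline therefore mixes in, at 15% of proposals, a Gibbs move
that resamples the whole parent set of two children jointly from its exact
full conditional (the admissible region factorises into three blocks after
classifying candidate sets by which cycles they could close, so the draw
is exact and costs one pass over each child's score table).  With that
move the two samplers agree with each other and with exhaustive
enumeration to well under one percentage point of edge posterior on
problems small enough to enumerate.

`exhaustive_posterior()` is that enumeration: every admissible $(W, B)$ up
to the cap, feasible to about four variables per slice, used throughout
the tests as the independent reference.

Chain defaults follow the scale of the motivating analysis — $10^6$
proposals, 20% burn-in, thinned to 10\,000 draws — but every verification
in this package runs shorter chains ($3 \times 10^4$ to $10^5$ proposals,
500–2000 draws), which the enumeration comparisons show are already
well-mixed at these problem sizes.  No formal convergence diagnostics are
computed beyond the score trace, the reported acceptance rate and two-seed
agreement; that is a stated non-goal.

## Intervention effects

For each sampled structure we draw one set of conditional probability
tables from their conjugate posterior — each parent-configuration success
probability independently from $\mathrm{Beta}(\alpha + \text{ones},\
\alpha + \text{zeros})$, the same $\alpha$ as in scoring — so the effect
distribution reflects parameter as well as structure uncertainty.  One
parameter draw per structure draw is the default; the nesting is
configurable in principle but the structure sample is already large.

The effect of variable $s$ at time $T$ on variable $t$ at $T+1$ is the
total causal effect

$$P(t = 1 \mid \mathrm{do}(s = 1)) - P(t = 1 \mid \mathrm{do}(s = 0)),$$

computed **exactly** on the unrolled network: delete $s$'s incoming edges,
clamp its value, and marginalise the remaining variables by variable
elimination restricted to the ancestral set of the target (greedy smallest-
union elimination order; a hard guard refuses factors beyond 24 variables,
far above anything the parent cap admits).  No Monte-Carlo inference is
used anywhere; a target that is not a descendant of the clamped source
yields exactly zero.  Effects include mediation through slice-2
within-slice edges — e.g. a path $s_T \to s_{T+1} \to t_{T+1}$ counts —
which is also what makes mixtures over structures with and without such a
mediating edge produce visibly bimodal effect distributions whose modes
sit at the per-structure exact effects.

Per source–target pair (the full $n \times n$ grid including the diagonal
"momentum" effects) we report the posterior mean and an equal-tailed
credible interval from the empirical quantiles of the draws; a pair is
flagged significant when the 95% interval excludes zero.  Highest-density
intervals and within-slice contemporaneous effects are out of the default
report (the latter available via `contemporaneous = TRUE`).  The grid of
cross-slice effects — sources on rows, targets on columns — is the primary
output; `plot_effect_grid()` truncates the display to $[-0.1, 0.5]$ by
default purely as a plotting choice.

The identifying assumptions are the usual ones and are not testable here:
a causal DAG generates the data and all common causes are measured.  The
consensus graph (below) marks directions the data cannot resolve rather
than pretending to resolve them.

## The consensus graph

`build_consensus()` thresholds posterior edge frequencies: a within-slice
pair appears when $p(i \to j) + p(j \to i) \ge 0.5$, drawn single-headed
when the dominant direction carries $\ge 80\%$ of that mass and
double-headed otherwise; between-slice edges appear at $p \ge 0.5$ and
always point forward in time.  Both thresholds are declared display
defaults, not estimated quantities; raising the inclusion threshold can
only remove connections.  Line width grows with the connection's posterior
strength, within-slice edges are solid and between-slice edges dashed.

## The synthetic cohort generator

No real cohort ships with the package; `generate_true_dbn()` and
`simulate_cohort()` create study-shaped data from a *known* DBN so that
every downstream stage is testable:

* `generate_true_dbn()` draws $W$ (each ordered pair under a random
  topological order with probability `within_density`, default 0.2 — about
  13 edges at $n = 12$), $B$ (diagonal momentum edges with probability
  `self_edge_prob`, default 0.9, mirroring the empirical regularity that
  almost all symptoms self-predict; off-diagonal edges at
  `between_density`, default 0.05), and CPTs in which every parent moves
  the child's probability by at least `effect_floor` (default 0.3, chosen
  so planted effects are detectable at a few hundred transition rows).
  The floor is geometrically infeasible once a child has more than
  $\lfloor 0.9/\text{floor}\rfloor$ parents; contrasts are then spread
  evenly, or in-degree can be capped with `max_in_degree`.
* `simulate_cohort()` draws wave 1 from the within-slice model (the
  stationarity idealisation: the same $W$ with its own CPTs) and each
  later wave from the transition CPTs, then applies monotone wave-level
  dropout, missing completely at random.  The default five-wave schedule
  retains 90.5% per follow-up wave so a cohort of 1208 declines to about
  810 by wave 5 — the shape of the motivating study.  Item-level
  missingness and informative dropout are deliberately not modelled.

What passing tests on these data do **not** show: robustness to ordinal
(rather than binary) measurement, to informative attrition, to
non-stationary dynamics, or to unmeasured confounding.  The generator
satisfies the analysis model's assumptions by construction; the tests
verify the machinery, not the clinical assumptions.

## Numerical and design notes

* All scores live in the log domain; Beta functions via `lgamma`.  Score
  tables are reproducible bit-for-bit for identical inputs.
* Ties in every categorical draw are broken by the seeded RNG stream,
  never by index order; a seed is mandatory for sampling and for the
  pipeline, and identical seeds give byte-identical samples and
  (non-figure) pipeline outputs.
* Zero-row transition tables score zero everywhere (the vacuous product),
  which the no-data sampling tests use to recover the prior exactly.
* Degenerate inputs fail loudly: unknown items, out-of-range ratings,
  duplicated cells, no complete adjacent pair (with a per-pair
  completeness report), infeasible `effect_floor`, parent-set budgets.
* Problem sizes used in the shipped verification runs: 3-variable
  enumeration comparisons (500 rows), a 12-variable recovery run with 1000
  transition rows and $10^5$ proposals, and effect grids over 500–1000
  draws — sizes at which the full suite completes in a couple of minutes
  on one core while still exercising the study-scale code paths.

## Limitations

Stationarity is an assumption, not a finding; four transition pairs cannot
distinguish slow drift from stability.  Rows from the same participant are
treated as independent.  The BDeu score ties direction identification to
v-structures and between-slice anchoring — some within-slice directions
remain unidentified and are honestly reported as double-headed.  Effects
are averaged over the cohort; effect modification is out of scope.
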