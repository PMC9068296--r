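---
title: "Module detection and integrated-centrality target ranking for multi-component pharmacology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module detection and integrated-centrality target ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

A medicinal plant extract is not one drug: hundreds of metabolites each
interact weakly with dozens of protein targets. The practical questions are
(i) which metabolites are even plausible oral drugs, (ii) which *groups* of
targets act together on the same biology, (iii) which disease categories each
group contributes to, and (iv) which single targets inside the important
groups deserve experimental follow-up. `netpharm` answers these with a fixed,
seeded pipeline over five tabular inputs: compounds with per-tissue
abundances, predicted ADMET properties, predicted compound–target
interactions, enrichment-filtered target–pathway annotations, and a
pathway–disease mapping.

This vignette explains the model behind each stage, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
numerical choices the implementation makes.

## Stage models and assumptions

### ADMET screening

The screen is a conjunction of per-property rules; a compound passes iff it
satisfies **all** enabled rules. The default thresholds follow the ADMETlab
"excellent" bands (e.g. QED ≥ 0.67, risk scores ≤ 0.3, PPB ≤ 90%, PAINS
alerts = 0). Two consequences of the conjunction design are worth knowing:

* the passing set equals the intersection of the per-rule passing sets, so
  relaxing any single threshold can only grow it (a property the tests check
  on 1,000 random profiles);
* a missing value for an enabled rule fails that compound with reason
  `"missing"` — silence would bias the screen toward incompletely annotated
  compounds.

Printed ADMET criteria lists in the literature are often ambiguous about
which bands are joint requirements. The rule set is therefore data: a tibble
of `(field, op, value, enabled)` rows, overridable from YAML/JSON
(`read_screen_criteria()`), and the package makes no claim that the default
conjunction reproduces any particular published compound count.

### Target filtering

Predicted interactions are kept when `probability > threshold` (default 0.1,
strict). Strictness matters at the boundary: a pair at exactly 0.1 is
dropped. The retained target set is the union over retained pairs; the
supporting (compound, target) map is preserved for traceability.

### The T-P-D network and its projection

The tripartite graph exists to make one relation explicit: a target matters
for a disease only through pathways that are themselves disease-linked.
Retention is therefore mutual — a pathway needs both a target edge and a
disease edge; targets and diseases need at least one retained pathway. The
edge count always equals retained target–pathway pairs plus retained
pathway–disease pairs, and the tests recount both sides independently.

The one-mode projection connects two targets iff they share at least one
pathway. The edge weight is the *number* of shared pathways and the shared
set itself is stored on the edge; flattening to an unweighted graph would
discard the strength of functional association, and the projection is
validated against a brute-force all-pairs set-intersection oracle.

### Module detection

Louvain modularity optimization runs on the projected graph, by default using
the shared-pathway weights (the weights express evidence strength; whether a
GUI analysis used them is usually unknowable, so an unweighted mode is one
flag away). The resolution parameter defaults to 1.0 — classical modularity.
The algorithm is seeded: tie-breaking inside Louvain follows the seeded
order, results are bit-reproducible for a fixed seed, and the seed is
reported alongside the partition. Modules are renumbered 1..k by decreasing
size (ties by earliest vertex position, so numbering depends on the
partition, not on the target symbols). Targets isolated after projection
have no shared-pathway evidence and sit in singleton modules rather than
being silently attached to a neighbour.

### Contribution scores

The contribution of module $m$ to disease $d$ is a normalized evidence tally:

$$\mathrm{CS}(m,d) = \frac{w(m,d)}{\sum_{m'} w(m',d)},\qquad
w(m,d) = \#\{(t,p)\ \text{edges}: t\in m,\ p \mapsto d\}.$$

This is the simplest tally that satisfies the defining property that every
scored disease's scores sum to one across modules, and it matches the
"share of pathway evidence" reading of a module's contribution. The tally is
deliberately a small, replaceable function; the sum-to-one invariant is
asserted to $10^{-9}$ on every random fixture in the test suite. The
highest-contributing module per disease is the argmax, with ties broken
toward the smaller module id and a warning.

### Integrated centrality

Within each module, four standard centralities are computed and min-max
normalized, and their mean is the integrated centrality:

$$\mathrm{IC}_i = \frac14\sum_{x \in \{DC, BC, CC, EC\}}
\frac{x_i - x_{\min}}{x_{\max} - x_{\min}} \in [0,1].$$

* **DC** — degree / (n − 1).
* **BC** — shortest-path betweenness normalized by (n−1)(n−2)/2, computed on
  the unweighted graph: shared-pathway weights measure evidence, not
  distance (an inverse-weight distance mode is available via igraph for
  users who disagree, but the packaged centralities are unweighted for
  paths).
* **CC** — Wasserman–Faust closeness with component scaling,
  $\frac{r_i}{n-1}\cdot\frac{r_i}{\sum_j d_{ij}}$ over the $r_i$ reachable
  vertices, so disconnected module subgraphs are handled without infinities.
* **EC** — eigenvector centrality of the (weighted) adjacency by shifted
  power iteration to an $L_2$ tolerance of $10^{-8}$, normalized to unit
  $L_2$ norm. On a disconnected graph the dominant component (largest
  leading eigenvalue; ties broken toward the component containing the
  lexicographically smallest vertex) carries the mass and all other vertices
  score 0. The diagonal shift (max row sum + 1) leaves eigenvectors
  unchanged while making the iteration converge on bipartite-like
  components, where the unshifted iteration can oscillate.

By construction IC = 1 iff a target attains its module's maximum of all four
centralities (given non-degenerate ranges) and IC = 0 at the joint minimum;
IC is invariant to rescaling any centrality within a module. All four
centralities are checked against an exhaustive brute-force oracle
(depth-first enumeration of all shortest paths; `eigen()` for EC) on every
connected graph with up to 5 vertices, all 112 isomorphism classes of
connected 6-vertex graphs, and random 8-vertex graphs.

**Degenerate ranges.** In a clique-like module a centrality can be constant
($x_{\max} = x_{\min}$). Such a centrality contributes 0 to IC by default:
a constant centrality carries no ranking information, and awarding 0.5 (the
available `"half"` option) would let every member of a small clique module
approach the selection cutoff on no evidence. Under the default rule a
perfect clique scores IC = 0 for every member.

**Scope.** Centralities are computed on each module's induced subgraph by
default — the normalization in the IC formula is explicitly per module, and
ranking "the most important target *in its functional module*" is the goal.
A `whole_graph` scope is provided for users who want global centralities
normalized per module.

Key targets are those with IC **strictly** above the threshold (default
0.8), sorted by decreasing IC with alphabetical tie-breaks.

## The synthetic-data generator

Real inputs to this pipeline come from external services (ADMET predictors,
target-prediction servers, enrichment tools), so the package ships a
generator that emulates all five tables with planted ground truth:

* **Planted modules.** Targets and pathways are split into `n_blocks`
  blocks; target $t$ annotates pathway $p$ with probability `p_in` (default
  0.6) inside its block and `p_out` (default 0.02) outside. Planting the
  structure in the *bipartite* target–pathway layer (rather than directly in
  a target–target graph) keeps the projection step on the test path.
* **Planted hubs.** One target per block annotates in-block pathways with
  probability `min(1, hub_boost * p_in)` (default boost 3, i.e. certainty),
  making it the designed integrated-centrality maximum of its module.
* **Disease concentration.** Each disease draws a configurable fraction
  (default 0.9) of its pathway links from one dominant block, so
  module→disease contribution scores have a known argmax.
* **Controlled screen.** Each compound passes the default ADMET screen with
  probability `admet_pass_fraction` (default 0.39, a typical shortlist rate
  for natural-product panels); failing compounds violate 1–3 randomly chosen
  rules. Interaction probabilities are Beta(2, 5) — right-skewed, mostly
  low-confidence, as target-prediction scores are in practice.
* **Tissue abundances.** Three tissue columns (`StR`, `StS`, `StF`: root,
  stem, flower) with 90% detection probability and log-normal intensities;
  chemical classes are sampled with weights giving lipid- and alkaloid-rich
  panels, the composition typical of the motivating material.

Each table draws from its own RNG substream derived from the master seed, so
regenerating one table never perturbs the others, and generation is
byte-deterministic for a fixed seed.

The default scale (`paper_scale_preset()`) is 200 compounds, 167 targets, 63
pathways, 10 disease categories, 5 blocks — the size of a single-herb study.

**Identifiability of the planted hub.** With few pathways per block a
non-hub target occasionally annotates *all* in-block pathways (probability
$p_{\text{in}}^{k}$ for $k$ pathways) and becomes an exact structural twin
of the hub, making "the hub is the IC argmax" ill-posed rather than false.
The recovery fixtures therefore use 25 pathways per block
($0.6^{25}\approx 3\times10^{-6}$), a choice made on identifiability
grounds. At the standard recovery conditions (4 blocks × 20 targets,
`p_in` = 0.6, `p_out` = 0.02, 20 seeds) module recovery reaches median
adjusted Rand index 1 and the planted hubs are the per-module IC argmax in
all seeds.

**What the generator does not emulate.** Real predictions are correlated
(similar compounds share targets), pathway annotations are hierarchical and
overlapping, module sizes are skewed, and ADMET properties are correlated
with chemical class. Passing tests on synthetic data therefore demonstrates
correctness of the computations and recoverability of planted structure —
not that any particular biological conclusion is right.

## Numerical and formatting choices

* Reported percentages (module sizes, tissue composition) are rounded
  **half-up** to two decimals — the convention of the tables this mirrors —
  rather than R's default round-half-to-even.
* Threshold comparisons follow their printed comparators literally: ties at
  `≥`/`≤` pass, `>`/`<` are strict (this is why a prediction at exactly 0.1
  and a target at IC exactly 0.8 are excluded).
* Degenerate inputs: an empty profile set screens to an empty passing set
  with a warning; a single-node centrality scope returns all-zero
  centralities; an empty projection (no shared pathways) is a valid graph of
  isolates; diseases with zero evidence are reported as unscored rather than
  dividing by zero.
* All exporters sort vertices lexicographically, making every artifact —
  Pajek (with an explicit 1-based id↔label map file), GraphML, SIF
  (`participates_in` / `implicated_in` / `shares_pathways` relations), edge
  lists, CSVs and the JSON run report — byte-deterministic for a fixed seed.
  The run report carries no timestamps for the same reason.

## Validation problem sizes

The test suite validates centralities exhaustively on all connected graphs
with ≤ 5 vertices plus the 112 connected 6-vertex isomorphism classes and 50
random 8-vertex graphs; contribution-score normalization and IC bounds on
100 random fixtures of 30 targets / 15 pathways / 5 diseases; block and hub
recovery on 20 seeds of the 80-target planted fixture; and the full pipeline
end-to-end at the 167-target preset scale. These sizes were chosen so the
entire suite exercises every claim in minutes on a laptop while keeping the
brute-force oracles genuinely exhaustive where they are exhaustive.

## Limitations

* The pipeline consumes *predicted* interactions and *pre-filtered*
  enrichment tables; it neither predicts ADMET/targets nor computes
  enrichment, and garbage upstream remains garbage downstream.
* Louvain is a heuristic: different seeds can yield different near-optimal
  partitions on weakly structured graphs. The seed is part of the reported
  provenance, and determinism is guaranteed only at fixed seed.
* The contribution-score tally weighs all target–pathway edges equally; no
  attempt is made to weight by interaction probability or enrichment
  strength.
* Gene symbols are opaque case-sensitive keys; no alias or identifier
  mapping is performed.
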