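---
title: "Motif-based PageRank for co-occurrence networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based PageRank for co-occurrence networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprank)
library(dplyr)
```

## The problem

Clinical prescription records — for acupuncture, one treated condition
together with the set of acupoints used for it — induce a weighted undirected
co-occurrence network: items are nodes, and two items are linked with weight
equal to the number of conditions in which they appear together (the
*acupoint–disease network*, ADN). Classical centralities rank nodes in such a
network by pairwise connectivity alone. But prescriptions act through
*combinations*: three points used jointly carry information that no pair of
edges represents. `mprank` scores nodes by a **motif-based PageRank (MPR)**:
the importance of a node is determined by how much higher-order synergy the
3-node motifs (closed triangles) around it carry, rather than by its raw edge
weights.

## The model

### Network construction

`build_adn()` links two item codes whenever they co-occur in at least one
case record; the weight is the number of shared cases. Items that never
co-occur with a partner remain isolated nodes — community reports must list
every known code. Weights stay integer case counts; all normalization happens
inside transition matrices downstream.

### Effective information

For a weight matrix $W$, every undirected edge is read as two directed edges
of equal weight, and each node's out-weights are normalized to a probability
vector $W_i^{out}$ over all $N$ node positions. The network's *effective
information* is

$$EI(G) \;=\; H\!\left(\langle W_i^{out}\rangle\right) \;-\;
  \big\langle H\!\left(W_i^{out}\right)\big\rangle ,$$

with base-2 entropies: the entropy of the average out-profile minus the
average per-node entropy. $EI$ measures how distinctly nodes distribute their
connection weight. Two numerical conventions matter and are applied
throughout:

* nodes with zero out-strength are excluded from both averages (the entropy
  of a zero vector is undefined, and motif removal can isolate nodes);
* a network with no edges has $EI = 0$.

By concavity of entropy $EI \ge 0$ always, with equality exactly when all
out-profiles are equal *as vectors*. Note that symmetric graphs do **not**
have zero $EI$: on a triangle with unit weights the three profiles are
permutations of $(0, \tfrac12, \tfrac12)$, not equal vectors, so
$EI(K_3) = \log_2 3 - 1 \approx 0.585$ bits, and in general any undirected
network with at least one edge has strictly positive $EI$ (identical profiles
would require self-loops). Vertex-transitive unit-weight graphs obey the
closed form $EI = \log_2 N - \log_2 k$ for degree $k$, which the test suite
uses as an oracle.

### Motif synergy and its sign convention

The motif class is the **closed triangle** only: the synergy of a triple is
attributed to each of its three pairs, which would be ill-defined for the
non-adjacent pair of an open triad. The synergy of a triangle $\Delta$ is the
change in $EI$ when its three edges are deleted from a copy of the network
(nodes are never deleted). The package's default reports

$$EI(\Delta) \;=\; EI(G') - EI(G),$$

the *rise* in effective information when the motif is dissolved. The
rationale is structural: a triangle whose members are jointly prescribed
across many conditions keeps their out-profiles broad and mutually aligned
with the network's average profile. Deleting those edges makes the three
profiles more individually deterministic, so $EI$ goes up; the size of the
rise measures how strongly the triple was bound into the network's shared
connectivity. Under this convention the bulk of triangle synergies on
realistic co-occurrence networks is positive with a heavy upper tail (the
power-law-like shape `plot_synergy_distribution()` shows), frequently
co-occurring triples carry the largest synergies, and the resulting ranking
correlates with diffusion-based influence.

The opposite convention — the *drop* $EI(G) - EI(G')$ — is retained via
`direction = "decrease"` on `motif_synergy()`, `synergy_matrix()` and
`mpr_scores()`. It is not the default because on every network of this class
it makes 98–99% of synergies negative (deleting edges usually *raises* $EI$:
rows become more concentrated on their remaining entries), which after
clamping reduces the synergy matrix to a handful of peripheral tight triads
and inverts the method's intent. Both directions are exact negations of each
other, and the motif table always carries the raw signed values so the choice
is auditable.

### The synergy matrix and clamping

Pairwise synergy aggregates over all triangles containing a pair:

$$S(v_i, v_j) \;=\; \sum_{(v_i, v_j)\in\Delta_k} EI(\Delta_k).$$

Negative per-motif values are clamped to 0 when building $S$ — a random-walk
transition matrix needs nonnegative weights — but are reported unclamped in
the motif table. The identity
$\sum_{u<v} S(u,v) = 3\sum_k \max(EI(\Delta_k), 0)$ (each triangle feeds
exactly three pairs) is asserted on every generated network in the tests.

`synergy_matrix()` computes all per-triangle values with an incremental
update: removing one triangle changes only its three rows of the transition
structure, so the mean-profile entropy is recomputed from maintained row
entropies and column sums rather than from scratch. The tests verify exact
agreement with full recomputation on random graphs.

### Scoring

$S$ replaces the raw weights in the PageRank transition matrix
$P_{ij} = H_{ij}/\sum_j H_{ij}$; all-zero rows (nodes in no positively
synergistic triangle) become uniform teleport rows, keeping $P$ stochastic so
the damped power iteration

$$\vec x_t = d\, P^T \vec x_{t-1} + \frac{1-d}{N}\,\vec e$$

converges. Defaults: damping $d = 0.85$ (the standard choice; the source
method never states one), uniform start vector, L1 residual tolerance
$10^{-10}$, iteration cap 1000 with a warning flag if hit. Scores sum to 1 at
every iteration.

### Communities and key-node selection

Acupoint codes carry their community in their prefix: 14 meridians
(LU, LI, ST, SP, HT, SI, BL, KI, PC, TE, GB, LR, GV, CV) plus 5 extra-point
regions (EX-HN/EX-HX head, EX-CA chest/abdomen, EX-B dorsum, EX-UE upper
limbs, EX-LE lower limbs) — 19 communities in all. `top_k_per_community()`
selects the top `k = 3` nodes per community, ties broken lexicographically by
code (deterministic), returning all members when a community has fewer than
`k` nodes. A two-column `node → community` table can override the prefix
partition.

## Evaluation metrics

* **Resolution** $f(r_A) = 1 - \sum_i N_i^2 / (R N^2)$ over $R$ score
  classes of sizes $N_i$ (values equal after rounding to 6 decimals form one
  class). A constant ranking scores exactly 0; all-distinct scores give the
  maximum $1 - 1/N^2$.
* **Network efficiency after removal**: delete a candidate key-node set and
  compute $\eta = \frac{1}{N'(N'-1)}\sum_{i\neq j} 1/d_{ij}$ with hop-count
  distances and $1/\infty = 0$. The summed-distance variant (without the
  reciprocal) is mathematically what a literal reading of the formula gives,
  but it is infinite on disconnected remainders and inverts the "lower is
  better" interpretation, so the reciprocal (global-efficiency) form is the
  default and the literal form sits behind `form = "literal"`. Distances use
  hop counts because weights are co-occurrence counts, not lengths; an
  inverse-weight proximity mode is available.
* **Weighted-cascade (WC) accuracy**: the benchmark simulates independent
  cascades on the directionalized network with activation probabilities
  $p_{ij} = W_{ij}/\sum_k W_{ik}$; a node's influence is its mean cascade
  size (seed excluded) over `runs` repetitions, fully determined by the seed.
  The benchmark always runs on the raw weight matrix $W$, never on $S$, so it
  stays independent of the scorer under test. Accuracy is the Kendall
  correlation between a scorer and the benchmark; the tie-corrected $\tau_b$
  is reported by default (ties are pervasive in centrality scores) with the
  plain pair-counting $\tau_a = 2(X_a - X_b)/(X(X-1))$ behind
  `variant = "tau-a"`. Ten runs is the conventional report setting; the
  bundled command-line tool defaults to 100 because 10 runs is high-variance.
* **CCDF** of a score vector for comparing how widely scorers spread values.

Baseline scorers: closeness, betweenness, eigenvector centrality (unweighted
topology), degree and weighted degree, plain weighted PageRank, and a
degenerate constant scorer as a resolution floor.

## The synthetic-data generator

Real prescription corpora are not freely redistributable, so
`generate_records()` emulates their statistical structure from a seeded
configuration:

* **Scale.** One record per treated condition. The default 150 cases over a
  198-item pool reproduces the reference network scale — about 197 nodes,
  ~1,900–2,100 edges, average weighted degree ≈ 40, average clustering
  ≈ 0.75 — because co-occurrence weights count *conditions*, and itemsets of
  3–12 points per condition at that record count yield exactly that edge
  mass. (Thousands of records would drive the network towards a 30%+ dense
  graph unlike any clinical co-occurrence network.)
* **Community concentration.** Each case samples a home community
  (probability ∝ community size) and draws items within it with probability
  $1 - p_{cross}$ ($p_{cross} = 0.05$), otherwise uniformly from the whole
  pool. This produces the observed unimodal, near-normal degree distribution
  and high clustering.
* **Planted hubs.** 5% of the pool (9 items) is designated as hubs,
  organized in within-community combinations of three — famous point
  combinations that dominate their own system's prescriptions. The boost
  factor (25) applies to home-community draws, and drawing one member of a
  combination pulls its partners into the candidate set. This is what makes
  planted nodes *high-synergy* under the motif measure: a structure that is
  merely high-degree (oversampled everywhere, edges spread thin) acquires
  high strength but low per-edge concentration and is invisible to
  triangle-synergy scoring. The recovery tests check that MPR places planted
  combo members in the global top-$2\times$planted across 20 seeds and that
  MPR's ranking resolution beats a degree ranking.
* **Itemset size** is uniform on 3–12; the real distribution is unreported,
  so the range is a configuration default, exposed in `generator_config()`.

What the generator does **not** emulate: real meridian-specific indication
patterns, longitudinal or source heterogeneity (classical vs modern
literature), and item-frequency tails beyond the planted combos. Passing
recovery tests therefore demonstrate that the pipeline identifies planted
high-synergy structure under realistic network statistics — not that the
method is clinically validated.

## Numerical choices and degenerate inputs

* Entropies in bits; float comparisons at $10^{-9}$ in tests; the EI
  incremental path treats out-strengths below $10^{-12}$ as zero.
* Empty record lists build empty networks (not an error); records with empty
  item codes are rejected naming the case.
* An edge list cannot carry isolated nodes, so `write_network()` records them
  on a leading `# isolated:` comment line that `read_network()` restores and
  generic TSV readers skip; GraphML keeps them natively.
* Ranking ties anywhere (top-k, tidy ranks) break lexicographically by node
  code, so all reports are deterministic.
* Dangling rows in any transition matrix become uniform rows.

## Problem sizes in the test suites

Unit oracles run on 8–30-node random graphs (exhaustive triple scans, dense
stationary solves, all-pairs BFS, $O(n^2)$ pair counting). The end-to-end
recovery suite uses 20 seeded default-scale networks (~197 nodes, ~8,000–
10,000 triangles each); the cascade benchmark check uses $10^4$ runs on a
3-node star against its closed-form expectation. The full suite completes in
well under a minute on one CPU.

## Known limitations

* Only 3-node closed-triangle motifs are implemented; larger motifs, open
  triads, hypergraph or simplicial representations are out of scope.
* The synergy computation is dense ($N \times N$ matrices); networks beyond a
  few thousand nodes would need a sparse rewrite.
* The WC benchmark is itself stochastic; accuracies computed from few runs
  are noisy, which is why the CLI default is 100 runs.
* The community partition is domain-given (code prefixes), never learned
  from the network.
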