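# mprank — Motif-based PageRank for weighted co-occurrence networks

`mprank` identifies **key nodes** in weighted undirected co-occurrence
networks — the motivating case is acupoint–disease networks (ADN), where
nodes are acupoints and an edge's weight counts the conditions two points
jointly treat. It is aimed at researchers mining prescription-style records
(case → itemset) for influential item combinations, and at network scientists
who want a higher-order alternative to plain centrality ranking.

## The method

Pairwise centralities ignore that items act in *combinations*. `mprank`
scores nodes with a **motif-based PageRank (MPR)** built from three pieces:

1. **Effective information (EI).** Each undirected edge becomes two directed
   edges; each node's out-weights are normalized into a distribution
   `W_i_out` over all N nodes. Then

   `EI(G) = H(⟨W_i_out⟩) − ⟨H(W_i_out)⟩`   (base-2 entropies)

   — the entropy of the average out-profile minus the average per-node
   entropy, a measure of how distinctly nodes spread their weight.

2. **Motif synergy.** For every closed triangle Δ, its synergy is the change
   in EI when its three edges are deleted: `EI(Δ) = EI(G′) − EI(G)`, the EI
   rise observed when the triple's joint binding is dissolved. Synergies
   aggregate into the pairwise **synergy matrix**

   `S(v_i, v_j) = Σ_{(v_i,v_j) ∈ Δ_k} EI(Δ_k)`   (negative terms clamped to 0),

   which replaces the raw adjacency weights.

3. **PageRank.** The row-normalized transition matrix `P_ij = S_ij / Σ_j S_ij`
   (all-zero rows → uniform teleport rows) feeds the damped power iteration
   `x_t = d Pᵀ x_{t−1} + (1−d)/N · e` with `d = 0.85`, tolerance `1e-10`.

Per community (the 14 meridians + 5 extra-point regions carried by code
prefixes), the top-3 nodes form the key-node report. Three evaluation metrics
compare scorers: ranking **resolution** `1 − Σ N_i²/(R·N²)`, **network
efficiency** after removing each scorer's key nodes (mean inverse shortest
path distance), and **accuracy** (Kendall correlation against a
weighted-cascade diffusion benchmark with `p_ij = W_ij / Σ_k W_ik`).

A seeded synthetic generator emulates prescription corpora (one record per
condition, community-concentrated itemsets, planted famous-combination hubs)
so the full pipeline is testable without clinical data.

## Worked example

```r
library(mprank)
library(dplyr)

cfg     <- generator_config(seed = 42)      # ~150 condition records, 198 items
records <- generate_records(cfg)            # tibble: case_id, item
net     <- build_adn(records)               # weighted co-occurrence network

glance(net)
#>   n_nodes n_edges avg_weighted_degree avg_clustering
#> 1     198    2031                44.0          0.711

scores <- mpr_scores(net)                   # synergy matrix -> PageRank
glance(scores)
#>   method n_nodes damping iterations residual converged
#> 1 mpr        198    0.85         84 8.91e-11 TRUE

head(tidy(scores), 5)
#>   node    score  rank
#> 1 ST15   0.0283     1
#> 2 ST7    0.0232     2
#> 3 ST4    0.0231     3
#> 4 EX-HX1 0.0150     4
#> 5 EX-HX2 0.0127     5

planted_hubs(cfg)
#> EX-HX1 EX-HX2 EX-HX4 LR1 LR2 LR7 ST15 ST4 ST7
```

The generator planted three famous point combinations; MPR puts their members
at the very top of the ranking — they sit in the most synergistic triangles,
not merely on the heaviest edges. Key nodes per community and the scorer
comparison:

```r
format_key_node_report(top_k_per_community(scores))
#>   community                        key_nodes
#> 1 Bladder meridian                 BL8, BL7, BL16
#> 2 Conception vessel                CV11, CV12, CV6
#> 3 Extra points (chest and abdomen) EX-CA1, EX-CA2
#> ... (19 communities)

evaluate_all(net, algorithms = c("mpr", "weighted-pagerank", "closeness"),
             runs = 100, seed = 42) |> as_tibble()
#>   algorithm         resolution efficiency accuracy
#> 1 mpr                    1.000      0.370  -0.0540
#> 2 weighted-pagerank      1.000      0.374  -0.0711
#> 3 closeness              1.000      0.313   0.178
```

`resolution` near its maximum `1 − 1/N²` means a scorer separates almost
every node; `efficiency` is the network's mean inverse path length after
removing that scorer's key nodes (lower = the removed nodes were more
bridging); `accuracy` is Kendall τ against the stochastic cascade benchmark
(noisy at this scale — see the methods vignette). `autoplot()` methods and
`plot_synergy_distribution()`, `plot_degree_distribution()`, `plot_ccdf()`
draw the standard diagnostics.

A thin command-line front end ships in `inst/scripts/mpr.R` with `simulate`,
`score` and `evaluate` subcommands over JSON/CSV records, TSV/GraphML
networks and TSV reports.

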