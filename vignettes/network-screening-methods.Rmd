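---
title: "Network propagation and screening: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network propagation and screening: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwrscreen)
```

## The problem

Known disease genes are rarely a complete catalog. When a disease — here the
motivating case is Menière's disease, an inner-ear disorder with a confirmed
genetic component — has a curated set of associated genes, the surrounding
protein–protein interaction (PPI) network can suggest further candidates:
proteins that interact closely with several known disease proteins tend to
share their function ("guilt by association"). `rwrscreen` implements that
idea as a two-part procedure: a **random walk with restart (RWR)** ranks every
protein in the network by its proximity to the known genes, and a **three-stage
screening cascade** strips the ranking of the false positives that network
topology alone produces.

## The propagation model

The network is an undirected weighted graph: nodes are proteins, edges carry
an integer confidence score $S(u,v) \in (0, 1000]$ (the scale used by the
STRING database, whose `protein.links` files this package reads natively).
Let $T$ be the column-normalized transition operator,

$$T_{vu} = \frac{S(u,v)}{\sum_x S(u,x)},$$

so a walker at $u$ steps to neighbor $v$ with probability proportional to the
edge weight. Because columns are normalized, the raw 0–1000 score scale is
irrelevant to the walk; scores are deliberately **not** rescaled to $[0,1]$,
which keeps the interaction-test cutoff (below) on the familiar STRING scale.

Starting from the restart distribution $P_0$ — uniform mass $1/|\text{seeds}|$
on each seed node — the walk iterates

$$P_{i+1} = (1 - c)\, T P_i + c\, P_0,$$

with restart probability $c$ (default $0.8$, weighting the walk strongly
toward the known genes) until $\lVert P_{i+1} - P_i \rVert_1 < 10^{-6}$. The
update is a contraction with factor $(1-c)$ in $L_1$, so convergence is
geometric and the fixed point is unique: the iterative result agrees with the
closed-form solve $P = c\,(I - (1-c)T)^{-1}P_0$ to $10^{-8}$ or better, which
the test suite asserts on random graphs against exactly that dense solve.

Three numerical conventions are worth stating explicitly:

* **Norm.** The convergence criterion does not intrinsically require a
  particular norm; $L_1$ is the natural choice for probability vectors and is
  the default, with `norm = "l2"` / `"max"` available.
* **Dangling nodes.** An isolated node has a zero column in $T$ and would
  leak walk mass. The mass that would be lost is re-injected through the
  restart distribution ($P_{i+1} = (1-c)TP_i + (c + (1-c)\ell_i)P_0$, where
  $\ell_i$ is the mass sitting on dangling nodes), so $\sum P_i = 1$ holds at
  every iteration — verifiable via `rwr_propagate(..., trace_mass = TRUE)`.
  On a typical PPI network every node has at least one edge and this rule is
  never exercised.
* **Seeds missing from the network** are dropped with a warning and $P_0$ is
  renormalized over the mapped seeds, so it remains a probability
  distribution.

Nodes (excluding the seeds themselves, which cannot be *novel*) with
steady-state probability strictly above $10^{-5}$ form the **RWR gene** set.
Ranked output is ordered by probability descending with ties broken by node
identifier, so runs are bit-for-bit reproducible.

## The screening cascade

RWR scores are driven partly by network topology (hubs accumulate mass under
*any* seed set), so three screens follow.

**Permutation test.** $n$ random seed sets (default 1000) of the same size as
the real one are drawn uniformly without replacement from all network nodes,
and the identical walk is run for each. A gene's empirical p-value is the
fraction of permutations in which its permuted probability *strictly exceeds*
its real probability; ties count as non-exceedance, matching the definition
"number of sets on which the probability is higher". A
`conservative = TRUE` option computes $(\Theta+1)/(n+1)$ instead. Genes with
$p < 0.05$ (strict) survive as **candidate genes**. Two deliberate choices:
random sets are *not* degree-matched (the procedure emulated draws ids
uniformly), and the real seeds are *not* excluded from the sampling pool.
A consequence of the latter matters at small test scale: a candidate gene can
itself be drawn into a permuted seed set, where the restart mass alone gives
it a large permuted probability, so every p-value has a floor of roughly
`seed_set_size / N`. At realistic scale (about 100 seeds in a 20,000-node
network, a 0.5% seed fraction) the floor is far below the 0.05 cutoff and
irrelevant; calibration tests in this package therefore use a comparably
small seed fraction (5 seeds in a 200-node network) so the floor (≈ 0.025)
stays clear of the cutoff and the approximate uniformity of null p-values is
actually measurable.

**Interaction test.** A candidate's maximum interaction score,
$\mathrm{MIS}(g) = \max_{g'} S(g, g')$ over seed genes $g'$, must reach
**900**, STRING's highest-confidence cutoff; the comparison is inclusive
($\geq 900$ passes). Candidates with no seed edge score 0. Argmax ties
resolve to the lexicographically smallest seed, so the reported "best
partner" is deterministic.

**Enrichment test.** Each gene is encoded as a feature vector $FV(g)$ over GO
terms and KEGG pathways, and a candidate's maximum enrichment score is the
best direction cosine against any seed,
$\mathrm{MES}(g) = \max_{g'} \cos\!\big(FV(g), FV(g')\big)$, required to
exceed **0.8** (strict). The cosine of a zero vector with anything is defined
as 0, so unannotated genes fail this screen with a warning rather than an
error. Which encoding the original procedure used for $FV$ is not
recoverable, so the package makes the encoding explicit and configurable:

* `binary` (default): entry $t$ is 1 iff the gene is annotated to term $t$.
  Deterministic, annotation-release-independent, and exactly reproducible
  from GMT files; with optional OBO ancestor propagation (`is_a`/`part_of`
  true-path rule) so genes annotated to a child term count for its
  ancestors too.
* `neighbor_enrichment`: entry $t$ is
  $\max(0, -\log_{10} p_t)$ with $p_t$ the hypergeometric upper-tail
  probability of the overlap between the gene's direct network neighbors and
  term $t$'s gene set, against the universe of all network nodes (not only
  annotated genes — stated here because the universe choice changes the
  tail).

GO and KEGG catalogs are concatenated into one term dictionary before
encoding, and terms annotating zero genes are pruned (they only pad
dimensions; cosines are unchanged, which the tests assert). Cosines are
invariant to positive rescaling of any vector, so the two encodings need no
cross-normalization.

A gene passing all three screens is an **inferred gene**. All thresholds live
in one place (`screen_thresholds()`), with the boundary semantics stated
above asserted literally in the test suite: $p = 0.05$ fails,
$\mathrm{MIS} = 900$ passes, $\mathrm{MES} = 0.8$ fails.

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `restart_prob` | 0.8 | restart probability $c$; higher = stay closer to seeds |
| `tolerance` | 1e-6 | $L_1$ convergence threshold of the walk |
| `prob_threshold` | 1e-5 | RWR-gene cutoff on steady-state probability (strict >) |
| `n_permutations` | 1000 | random seed sets for the empirical p-value |
| `p_value_max` | 0.05 | permutation cutoff (strict <) |
| `mis_min` | 900 | interaction-score cutoff (inclusive ≥; STRING "highest confidence") |
| `mes_min` | 0.8 | enrichment-cosine cutoff (strict >) |
| `min_bipartite_score` | 900 | score floor of the exported inferred–known subgraph |

## What the synthetic generator does and does not emulate

`planted_module_spec()` + `generate_planted_network()` build a stochastic
block model: communities with dense, high-scoring internal edges
(default $p = 0.25$, scores 800–1000) against sparse, low-scoring background
($p = 0.02$, scores 100–400), seeds confined to one community, and
community-structured annotations carried with a configurable fidelity. The
defaults (200 nodes, 2 communities, 10 seeds, 10 terms per community,
fidelity 0.9) are the package's standard recovery benchmark: the cascade
should recover seed-community members with precision above 0.8, and the
permutation screen should pass roughly 5% of genes when nothing is planted.

The block model is chosen over degree-matched rewiring for transparency: the
planted signal is exactly controlled, and the 0–1000 score ranges make the
MIS ≥ 900 cutoff meaningfully exercisable. What it does **not** mimic: the
heavy-tailed degree distribution of real PPI networks (hub effects on RWR are
therefore milder in fixtures than in real data), the GO DAG's depth and
term-size skew, or correlated annotation noise. Passing the recovery tests
shows the machinery is correct and the screens add specificity on planted
structure; it does not certify performance on a real interactome.

One structural observation from the benchmark is worth recording: on a clean
two-community block model the RWR ranking alone already orders essentially
all seed-community members above the other community, so the *top-k* RWR
ranks are as pure as the inferred set, and the screens' added value shows up
in the candidate *counts* (how much of the network survives) rather than in
top-rank precision. On real networks, where hubs contaminate the top ranks,
the permutation screen is precisely what removes them.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated data:
oracle-equivalence on 100 random graphs of up to 50 nodes; calibration on a
200-node network with 5 seeds and 500 permutations; recovery on the standard
200-node benchmark with 500 permutations. These sizes keep a full run in the
tens of seconds while leaving every code path — including dangling-node
handling and both feature encodings — exercised. The full-scale published
counts (20,770 proteins; 2,425,314 directed records; 4,514 propagated genes)
require the STRING v9.1 download and are checked only when that file is
present locally.

## Known limitations

* No degree-preserving permutation null; uniform sampling is faithful to the
  emulated procedure but conflates degree with disease-proximity.
* No multiple-testing correction beyond the raw $p < 0.05$ cut, by design.
* No GO semantic-similarity measures; the enrichment test is a cosine over
  explicit term vectors.
* Identifier spaces must already match between network, seeds and
  annotations; no ID mapping is performed.
* The dense feature-vector matrix is fine for thousands of candidates and
  tens of thousands of terms but is not engineered for millions of genes.
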