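---
title: "Inferring drug-modulation sub-networks with pcstnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring drug-modulation sub-networks with pcstnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcstnet)
```

## The model

`pcstnet` treats drug action as information flow on a protein–protein
interaction (PPI) network. A binding target of the drug is the **root**;
genes whose expression measurably changes under treatment are **leaves**;
everything the reconstruction places in between is a candidate **cryptic
genetic factor** — a gene with no expression change of its own that
nevertheless relays the perturbation. The reconstruction is a rooted
Prize-Collecting Steiner Tree (PCST): each interaction of confidence
$c \in (0,1]$ costs $1 - c$ to include, each leaf carries a prize
forfeited if it is left unconnected, and the tree minimizes included cost
plus forfeited prizes. Compared with per-leaf shortest paths, the joint
optimization shares high-confidence trunks between leaves and is less
eager to thread noisy edges, which matters on interactomes whose bulk
confidence is low.

Assumptions worth keeping in mind: the PPI is undirected and
context-free (no tissue specificity); confidence scores are treated as
independent edge qualities; and expression changes are taken as a usable
surrogate of drug response phenotype.

## Tunable parameters

* **Depth `D`** (default 5, unitless hops): no node of a sub-network may
  be more than `D` tree-hops from the root. This bounds the resolution of
  the reconstruction and keeps the search local; deeper trees increasingly
  pick up network hubs unrelated to the root.
* **Leaf prize `lambda`** (cost units): the data provide no natural prize
  scale, so by default `lambda` is set per root to twice the largest
  min-cost root→leaf distance within the depth-limited neighborhood. Every
  reachable leaf is then individually worth connecting, while a leaf whose
  *marginal* branch exceeds `lambda` during pruning — an expensive
  outlier — can still be dropped. A magnitude-weighted alternative
  (per-leaf multipliers, e.g. differential-expression effect sizes) is
  available via `builder_config(leaf_weights = ...)`; uniform prizes are
  the default because effect sizes are not always available and the
  uniform rule matches the "connect as many leaves as cheaply as
  possible" objective.
* **`min_confidence`** (fraction, default 0): confidence floor applied at
  parse time. No cutoff is applied by default; the solver's cost structure
  already disfavors weak edges.
* **Control cohort sizes** `n_R = 16`, `n_L = 20`, `n_K = 19`: sizes of
  the random-root, random-leaf-root and random-kinase-root cohorts,
  matching the case study the fixtures derive from.
* **Criticality percentile** (default 95) and **discrepancy spread**
  (default 25 percentage points), both on the scale of the criticality
  table percentages.

## Numerical and design choices

**Exact solver.** For a fixed node subset the optimal tree is its
minimum spanning tree on edge costs, so `pcst_solve_exact()` enumerates
root-containing connected subsets (feasible to ~12 nodes) and minimizes
directly. Objective ties break toward fewer edges, then the
lexicographically smallest node tuple, making the optimum unique and
reproducible. It exists purely as an oracle for the heuristic.

**Heuristic solver.** `pcst_solve_heuristic()` grows the tree by
attaching prized nodes one at a time, in order of increasing min-cost
distance from the root, each via the cheapest path from the *current*
tree. Paths are found with a level-indexed relaxation over hop counts
(a bounded Bellman–Ford), which yields the min-cost path using at most
`D` edges — a plain Dijkstra cannot respect the hop budget. During an
attach step, existing tree nodes act as path sources only; edges into
them are masked so a new branch meets the tree exactly once and node
depths stay consistent. The prune phase repeatedly removes the prized
node whose exclusive branch cost exceeds its prize by the largest margin
(dangling branch nodes go with it) until no removal lowers the
objective; the root-only solution is kept if it is at least as good. All
tie-breaks are lexicographic on gene symbol; the solver contains no
randomness. Against the exact oracle on random 5–12-node instances the
heuristic is never better (as it must be) and stays within a factor two
of optimal in the shipped test suite.

**Depth enforcement.** The depth limit is enforced twice: the PCST
instance is restricted to the BFS ball of radius `D` around the root,
*and* the grow phase's hop budget guarantees every tree path from the
root has at most `D` edges. Truncation alone does not imply the latter —
a cheap path inside the ball can use more than `D` hops — so the
builder asserts the tree-path invariant on every call.

**Participation.** Instances are counted with multiplicity: an
intermediate node belonging to three key pathways contributes three. The
root and collected leaves are excluded — the score is meant to describe
what the *reconstructed middle* of the tree does, not the inputs; a
config switch (`include_leaves`) restores leaf counting. Z-scores use
the mean and sample (n−1) standard deviation of the R-control cohort,
the normalization consistent with the published per-root Z table the
fixtures carry (its mean reproduces the summary-level
(131.4 − 117.6)/15.6 within 0.01).

**Criticality.** Betweenness is computed unweighted on the tree —
shortest paths in a tree are unique regardless of weighting — endpoints
excluded, normalized by $(n-1)(n-2)/2$; trees with fewer than three
nodes score zero everywhere. The critical threshold is the
linear-interpolation (type-7) 95th percentile, inclusive of ties, so
twenty equal scores are all critical. Roots and leaves are eligible:
published critical-gene tables contain genes that are also inputs, so
only participation — not criticality — excludes terminals.

**Controls.** The R-control universe excludes both the leaf set and the
experimental roots; a random root drawn from the leaves would reproduce
the L-control, and one drawn from the targets would not be a control at
all. K-control kinases are restricted to kinases present in the network
(sampling absent symbols would silently shrink the cohort). All cohorts
are sampled without replacement under a caller-supplied seed and are
byte-identical across reruns.

**Enrichment.** The over-representation module is a hypergeometric
upper-tail test with Benjamini–Hochberg correction, the standard modern
replacement for the web tool used in the original case study (whose
exact 2016 test and correction are unrecoverable). The universe defaults
to all network nodes and is configurable.

**Degenerate inputs.** A root with no reachable leaf yields a flagged
root-only sub-network rather than an error; unreachable leaves are
always reported by name; equal assay control signals, empty gene sets,
zero reference variance and malformed network lines are hard errors.

## The synthetic generator

`generate_synthetic_data()` emulates the study conditions end to end: a
250-gene preferential-attachment background PPI with Beta(4, 6)
confidences (mode ≈ 0.4, matching the mostly-low-confidence character of
real interactome scores), 6 planted target roots, 40 leaves, and per
target a dedicated 3-edge spine of confidence 0.9–0.99 fanning out to 8
assigned leaves. Eight key pathways of 25 genes include each planted
intermediate with probability 0.8; eight decoy pathways are uniform
draws; 10% of genes are labeled kinases. These sizes keep a full
four-cohort pipeline run in seconds while leaving the planted signal
modest rather than trivial — planted-root Z-scores average well under 1
per run, and the cohort separation is only reliably detectable across
seeds (the shipped 20-seed study rejects the sign-test null at
p ≈ 0.001), which is the regime the method actually operates in.

What the generator does **not** emulate: the degree distribution of a
real interactome beyond scale-free-ish attachment, correlated evidence
channels behind confidence scores, tissue-specific wiring, or leaf sets
with expression-magnitude structure. Passing the synthetic suite
therefore demonstrates algorithmic correctness and statistical behavior
under the planted model, not biological validity on any particular real
dataset.

## Limitations

* The heuristic has no approximation guarantee; its factor-two behavior
  is empirical, audited against the exact solver on small instances.
* Identifier harmonization (ENSP→symbol, aliases) is out of scope;
  inputs must share one symbol namespace.
* One sub-network per root: no joint multi-root tree is built.
* Participation depends on the curated key-pathway list; a biased list
  biases the Z-ordering of targets. Decoy pathways in the synthetic
  suite probe, but cannot eliminate, this dependence.
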