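---
title: "Integrated cell networks: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated cell networks: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements: the
fusion model and its solver, the graphlet statistics, the null models, the
enrichment machinery, and — importantly — the design decisions taken where
the design was genuinely open, with the numerical choices spelled out.

## The data and the problem

A cell's molecular organization is reported by several partial, noisy maps:
protein–protein interactions (PPI), co-expression (COEX) and genetic
interactions (GI). For a given tissue or condition, each map is a simple
undirected gene–gene network; restricted to the genes expressed in that
tissue, these are *tissue-specific* layers. The layers disagree heavily —
two layers rarely report the same pair as interacting (quantified in this
package by `edge_jaccard()`) — so naive unions inherit each layer's noise
while intersections are nearly empty. The goal is a single *integrated*
network per condition that borrows strength across layers, and then a way to
compare two conditions (e.g., tumor vs. control tissue) gene by gene.

## The fusion model

All `m` layers are aligned onto one gene index (lexicographically sorted,
union policy by default) as symmetric 0/1 adjacency matrices
$A_1, \dots, A_m$. The model factorizes all layers simultaneously with one
shared non-negative factor:

$$\min_{G \ge 0,\, S_i} \sum_{i=1}^{m} \lVert A_i - G S_i G^{\mathsf T} \rVert_F^2,$$

where $G$ is $n \times k$ (genes by clusters) and each $S_i$ is a symmetric
$k \times k$ summary of how clusters interact in layer $i$. Sharing $G$
across layers is what fuses them: the cluster structure must explain every
layer at once.

The solver alternates two steps per iteration:

1. **Closed-form $S_i$:** with $G$ fixed,
   $S_i = (G^{\mathsf T}G)^{-1} (G^{\mathsf T} A_i G) (G^{\mathsf T}G)^{-1}$.
   A ridge $\varepsilon = 10^{-10}$ is added to the Gram diagonal before
   inversion, and the result is symmetrized ($\tfrac12(S + S^{\mathsf T})$)
   to remove floating-point drift — symmetry of $S_i$ is implied by the
   symmetry of $A_i$ but does not survive round-off unaided.
2. **Multiplicative update of $G$:** an elementwise update of the form
   $G \leftarrow G \odot \sqrt{\text{numerator} / \text{denominator}}$ where
   matrices that can carry negative entries are split into positive and
   negative parts ($M^{+} = (\lvert M\rvert + M)/2$,
   $M^{-} = (\lvert M\rvert - M)/2$) so both numerator and denominator stay
   non-negative and $G \ge 0$ is preserved. The same $\varepsilon$ guards
   the denominator, and positions where numerator and denominator both
   vanish leave $G$ unchanged (the $0/0$ convention).

**Orientation of the update.** Two mirrored placements of the
positive/negative parts are algebraically plausible; only one of them
descends the objective. `update_g()` exposes both behind
`update_rule = c("standard", "as_printed")` and defaults to the descending
orientation — placing $(A_i G S_i)^{+}$ in the numerator — which we verified
empirically: on seeded random instances the default orientation yields a
monotonically non-increasing relative square error (RSE) over 1000
iterations, while the mirrored one diverges to RSE 1. Monotone descent is
the contract the whole solver relies on, so it is the default.

**Initialization.** Two generators are provided. `init_random()` draws
uniform entries — non-deterministic, used by the stability analysis.
`init_svd()` is deterministic: column $i$ of $G_\text{init}$ is
$\sigma_i g_i$ with $\sigma_i$ the square root of the $i$-th singular value
of the average adjacency $\bar A$ and $g_i$ whichever of the positive or
negative part of the $i$-th left singular vector has the larger norm. The
summed form of this initialization is interpreted column-wise (column $i$
gets $\sigma_i g_i$) because a rank-$k$ starting matrix needs $k$ distinct
columns. The norm comparison makes the construction invariant to the sign
ambiguity of singular vectors. If $k$ exceeds the numerical rank of
$\bar A$, trailing columns are zero with a warning.

**Stopping.** The reference behaviour is a fixed cap of 1000 iterations,
after which the RSE

$$\mathrm{RSE} = \frac{\sum_i \lVert A_i - G S_i G^{\mathsf T}\rVert_F^2}
                      {\sum_i \lVert A_i \rVert_F^2}$$

no longer decreases appreciably on the problem sizes we target. An optional
early stop (`early_stop = TRUE`: ten consecutive iterations with
$|\Delta \mathrm{RSE}| < 10^{-9}$) is provided but off by default.

**From factors to an integrated network.** The integrated network ("iCell")
is read off $W = G G^{\mathsf T}$ (diagonal zeroed first — the diagonal is
removed before thresholding): pair $(u,v)$ is kept iff $W[u,v]$ is among the
$\lceil q\,(n-1)\rceil$ largest positive entries of row $u$ *or* row $v$.
The union of the row rule and the column rule keeps the result symmetric;
ties keep all tied values. The package default is $q = 0.01$ (top 1% per
row and column), the value used at genome scale; for the synthetic fixtures
of a few hundred genes we use larger fractions (see below), since
$\lceil 0.01 \cdot 149\rceil = 2$ retained partners per gene carries almost
no wiring information. Hard clusters come from the row argmax of $G$, ties
to the lowest cluster index, all-zero rows to cluster 1 with a warning.

## Choosing the number of clusters

`select_k()` implements clustering-stability selection: for each candidate
$k$, the solver is run `runs` times (default 10) from random starts, each
run's hard clustering is encoded in a 0/1 co-membership (association)
matrix, and the matrices are averaged into $\bar C$. Two dispersion
coefficients summarize how binary (stable) $\bar C$ is:

$$\eta_k = \frac{\operatorname{var}(\mathrm{offdiag}(\bar C))}{p - p^2},
\quad p = \frac{n/k - 1}{n - 1}; \qquad
\nu_k = \frac{\sum_{i \ne j} (\bar C(i,j) - 1/k)^2}{n(n-1)(1/k - 1/k^2)}.$$

Two numerical choices matter here. First, $\eta_k$ uses the *population*
variance (divide by the count, not count minus one): only then does the
identity case — identical equal-size clusterings — give exactly 1. Second,
the two coefficients are aggregated by maximizing $\nu_k$ with $\eta_k$ as
tie-break (then smaller $k$): for identical equal-size clusterings
$\eta_k = 1$ for every $k$ while $\nu_k = (n-k+1)/(n-1)$ — exactly 1 only
at $k = 2$ and only asymptotically 1 otherwise — so $\nu_k$ is the
coefficient that discriminates across the grid and $\eta_k$ cannot order
candidates by itself. Both facts are regression-tested. For independent
random clusterings both coefficients have expectation about $1/\text{runs}$
— noticeably nonzero at the default 10 runs — and vanish only as the run
count grows.

A practical caveat: the multiplicative solver started from uniform random
factors frequently stalls in a near-parallel-column local optimum (all
columns close to the leading eigenvector), even on cleanly separated
planted structure at a few hundred genes, where the deterministic
initialization recovers the planted clusters exactly. Run-to-run consensus
then measures optimization failure as much as model structure, and the
stability profile over $k$ flattens. The dispersion machinery itself is
exact (all identity cases are asserted to machine precision); the
limitation is in the prescribed update scheme's behaviour from random
starts at small scale, and stability-based selection should be read with
that in mind. The default grid is $\{10, 20, \dots, 100\}$; the fixture
tests use small grids around the planted truth.

## Graphlet statistics

Graphlets are small connected induced subgraphs; orbits are the
automorphism classes of node positions within them. The 2–4-node catalogue
has 15 orbits (0–14); removing the four redundant ones (3, 12, 13, 14 —
each linearly determined by the rest) leaves the 11 non-redundant orbits
used throughout. `count_orbits()` computes exact counts of all 15 orbits
per node by enumerating every connected induced 3- and 4-node subgraph
exactly once (ESU enumeration, implemented in C++), classifying each by its
internal degree sequence. No sampling is involved; the counts are exact and
are tested against a brute-force subset-enumeration oracle.

The per-gene comparison statistic is the GDV distance: for orbit counts
$h, c$,

$$D_i = w_i \frac{\lvert \log(h_i + 1) - \log(c_i + 1)\rvert}
                 {\log(\max(h_i, c_i) + 2)}, \qquad
\mathrm{GDVD} = \frac{\sum_i D_i}{\sum_i w_i} \in [0, 1),$$

with natural logarithms (the ratio is base-invariant). The weights
$w_i = 1 - \log(o_i)/\log(73)$ down-weight orbits whose counts depend on
many others; the dependency counts $o_i$ (1, 2, 2 for orbits 0–2; 3, 4, 3,
3, 4, 3, 4, 4 for orbits 4–11) are the published dependency-count table of
the GDV-similarity methodology, hardcoded with two asserted sanity
properties: $w_0 = 1$ and monotone non-increase in $o_i$. The `+1` inside
and `+2` under the logarithm keep every per-orbit term strictly below its
weight, which bounds the distance strictly below 1.

Network-level comparison uses the graphlet correlation matrix (GCM):
Spearman correlations between the 11 orbit-count columns over all nodes,
with one artificial all-ones GDV row appended before correlating so that a
constant column (a network with, say, no 4-cliques anywhere) does not
produce an undefined correlation; ties get average ranks. GCD-11 is the
Euclidean distance between two GCMs' 55 strictly-upper-triangle entries.
Symmetry and zero distance for isomorphic inputs are asserted; the triangle
inequality is not claimed.

## Random-graph null models

Seven generators (`generate_model()`) match a data network's node count and
edge density (or degree sequence): ER (exact edge count), ER-DD (stub
matching with rejection of self-loops/multi-edges, up to 100 restarts,
residual stubs dropped with a message), GEO in 3 dimensions (the radius is
the order statistic of pairwise distances achieving the target edge count
exactly — equivalent to, but sharper than, bisection), GEO-GD (children
placed uniformly within a fixed dispersal step of a duplicated random
parent, then connected by the GEO rule at the order-statistic radius: the
dispersal process is scale-free, so the graph distribution depends only on
the step-to-radius ratio and the density constraint fixes the radius), SF
(preferential attachment with per-step attachment counts
distributed to hit the target edge count exactly), SF-GD (duplication–
divergence with parent-link probability $p = 0.3$ — the model literature
gives no canonical value, and density is insensitive to $p$ compared to
$q$ — and shared-neighbor prune probability $q$ calibrated to the target
density by bisection), and STICKY (stickiness
$\theta_i = d_i/\sqrt{\sum d}$, pair probability
$\min(1, \theta_i\theta_j)$, which reproduces the input degrees in
expectation). GEO dimensionality defaults to 3 and is exposed as a
parameter.

`fit_models()` scores a model by the overlap between two GCD-11 distance
distributions — data-to-model (30 replicates by default) and
model-to-model ($\binom{30}{2}$ pairs) — compared with a two-sided
Wilcoxon–Mann–Whitney test (normal approximation with tie correction);
$p \le 0.05$ rejects the model. Mean data-to-model distance orders models
by fit quality even when all are rejected.

## Enrichment statistics

All set statistics are hypergeometric, computed through the log-space
distribution functions of R's `stats` (no explicit factorials, so a
background of $2\times10^4$ genes is safe): enrichment is the upper tail
$P(X' \ge X)$, depletion the lower tail $P(X' \le X)$, and the routing
between them follows the fold enrichment $(X/N)/(K/M)$ — above 1 routes to
enrichment, otherwise depletion. Only annotated genes count toward set and
background sizes. Cluster-level testing corrects across all
(cluster, term) pairs jointly with Benjamini–Hochberg — the conservative
reading where the correction scope is not dictated — and a term is called
enriched at adjusted $p \le 0.05$. Clustering quality is the percentage of
annotated genes with at least one of *their own* annotations enriched in
*their own* cluster. The permutation utility `empirical_permutation_p()`
returns the add-one estimate $(r+1)/(n+1)$.

## Comparing conditions: rewiring

Given control and case integrated networks on the same gene universe,
`rewiring_scores()` ranks genes by the GDVD between their GDVs in the two
networks (most rewired first, ties broken by gene id; genes isolated in
both score 0). A gene present in the universe but absent from a network's
node list is an error rather than imputed zero — always-expressed genes
must appear in both networks by construction. "GDV similarity" is defined
as $1 - \mathrm{GDVD}$; `pan_cancer_scores()` averages it over all pairs of
networks and ranks least-rewired-first. GDVs are computed on the
thresholded integrated networks, not on the raw $W$ weights.

`compare_conditions()` packages the recommended two-condition protocol:
fit the control multiplex to convergence, then adapt that solution to the
case multiplex with a small number of warm-started iterations (default 3)
before thresholding both. The rationale is variance control: two
independent solver runs differ not only where the data differ but also
through initialization and optimization path, and at small $n$ that
variance swamps per-gene signal. Warm-starting the case fit from the
control solution makes the comparison paired — what moves is what the data
moved.

## The synthetic generator: what it emulates and what it does not

`simulate_multiplex()` is a multi-layer stochastic block model: `n` genes
in `k` equal planted clusters shared across `m` layers, within-cluster edge
probability `p_in`, between-cluster `p_out`. The standard benchmark used
throughout the tests is `n = 150, k = 3, m = 3, p_in = 0.3, p_out = 0.02` —
strong but noisy assortative structure, layer densities (~12%) well above
genome-scale sparsity so that 150-gene fixtures carry enough edges to be
informative. `simulate_condition_pair()` plants rewiring: selected genes
have a fraction (`rewiring_strength`) of their incident edges per layer
moved to uniformly chosen non-neighbors, preserving degree approximately
(replacement count equals removal count); rewired genes are always kept in
the expressed pool of both conditions. `simulate_annotations()` draws terms
as `coverage` of one cluster plus `noise` from outside.

What the generator does *not* emulate: heavy-tailed PPI degree
distributions, layer-specific densities and biases, overlapping or nested
functional modules, and genome scale. Passing the planted-recovery tests
therefore shows the machinery is correct and the statistics behave as
designed at fixture scale; it does not by itself certify performance on
real interactomes.

**A known limitation, quantified.** The planted co-clusters are recovered
essentially perfectly (ARI $\ge 0.9$ in 9/10 seeds on the standard
benchmark), but per-gene rewiring detection through the fused networks is
only partial at fixture scale: with the paired protocol above
(`k = 30`, threshold fraction 0.12), planted rewired genes reach a mean
rank around 29 of 150 (~80th percentile), yet typically only 4–6 of 10
land in the top 20. The cause is measurable: scoring the same fixture on
thresholded *consensus* (mean-adjacency) networks recovers 10/10 planted
genes, while $W = G G^{\mathsf T}$ correlates only ~0.35 with the consensus
adjacency at $n = 150$ for any $k$ — a low-rank non-negative factor cannot
represent a gene's idiosyncratic, mostly between-cluster rewired edges, so
the fusion step itself filters out part of the signal that the raw data
contain. At genome scale, with hundreds of retained partners per gene, the
regime is different; at fixture scale this is the accuracy ceiling, and the
corresponding acceptance test reports it honestly rather than relaxing the
bar.

## Problem sizes and determinism

The test and acceptance workloads are sized for a single CPU: fixtures of
60–150 genes and 2–3 layers for fusion and stability (up to 1000 solver
iterations), 300-node networks with ~1300 edges for the null-model
comparisons (10 replicates per model in the sanity suite; the package
default remains 30), brute-force graphlet oracles on 50 graphs of up to 25
nodes, and 10,000 random GDV pairs for the distance bound. Every stochastic
step takes an explicit seed, and all generators are deterministic given it;
the pipeline manifest (file hashes) is reproducible across reruns with the
same configuration.
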