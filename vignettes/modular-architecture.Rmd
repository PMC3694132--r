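---
title: "Modular architecture analysis of resting-state connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular architecture analysis of resting-state connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

`modnet` analyses resting-state functional connectivity (rsFC) as a graph:
nodes are parcellated brain regions (the bundled table has the 116 AAL
regions: 90 cerebral, 26 cerebellar), edges are inter-regional correlations
of low-frequency BOLD fluctuations. From each subject's node-by-volume time
series the package builds a weight matrix, thresholds it into a connected
graph at a fixed cost, characterises its small-world topology, partitions it
into modules, and asks two group-level questions: *do groups differ in their
modular architecture as a whole?* (normalized-mutual-information permutation
test) and *which individual regions switch functional community?* (per-node
co-module phi-coefficient scan with Bonferroni control). Because no
participant data ship with the package, a synthetic-cohort generator with
planted modular structure serves as the test bed: every downstream claim a
test makes is a claim about what the pipeline recovers from a known world.

## From time series to a connected graph

Per subject, the pipeline computes the Pearson correlation $r_{ij}$ between
every pair of node time series, applies the Fisher transform
$z_{ij} = \operatorname{atanh}(r_{ij})$, and rectifies to $|z_{ij}|$ as the
edge weight; the sign of a correlation is deliberately discarded. The weight
matrix is thresholded at a target *cost* $\kappa$ (the fraction of the
$n(n-1)/2$ node pairs kept as edges, so $m = \operatorname{round}(\kappa\,
n(n-1)/2)$, rounding half up). Plain global thresholding can fragment the
graph at sparse costs, which breaks path-based metrics, so thresholding is
done in two stages:

1. **Backbone**: a maximum-weight spanning tree ($n-1$ edges; Kruskal on
   descending weights, ties broken lexicographically by node index) —
   every node is connected, no islands;
2. **Growth**: remaining node pairs are added in descending weight order
   until the edge count reaches $m$.

Both stages use one fixed edge ranking per weight matrix, so graphs across
the conventional cost sweep (0.03 to 0.40 in 0.01 steps, 38 costs) are
*nested* by construction, and every graph is connected at every feasible
cost — two properties the test suite asserts on random matrices rather than
trusts. In binary mode retained edges become 1; in weighted mode they keep
$|z|$; both modes share the edge set at a given cost.

## Topological metrics and their null models

On the binarised topology the package computes the Watts–Strogatz pair —
clustering coefficient $C_p$ (mean over nodes of the fraction of a node's
neighbour pairs that are connected; 0 below degree 2) and characteristic
path length $L_p$ (mean shortest-path length over pairs) — and the
Latora–Marchiori efficiencies: $E_{global}$ (mean inverse shortest-path
length, with $1/\infty = 0$) and $E_{local}$ (mean over nodes of the global
efficiency of the neighbour-induced subgraph; 0 below two neighbours).
$L_p$ is only defined on connected graphs, which the thresholding
guarantees; the efficiencies tolerate disconnection, which matters for
neighbour subgraphs.

Small-worldness uses Humphries' ratio
$\sigma = (C_p/\langle C_p^{rand}\rangle) / (L_p/\langle L_p^{rand}\rangle)$
with degree-preserving rewired null graphs (double edge swaps, $10|E|$
attempts, every accepted swap keeps the graph connected; default 20 nulls,
which is stable for 116-node graphs). A same-size ring lattice is
constructed for visual context, as is conventional in per-cost metric
figures; no lattice-normalised statistic is tested. Per-cost group
comparisons use pooled two-tailed t tests, uncorrected across the 38 costs
— the emulated analysis reports no correction, and the pipeline flags the
ambiguity in its report rather than inventing one.

## Modular architecture and its group comparison

Partitions come from Louvain modularity maximisation. The optimiser is
greedy and order-dependent, so `detect_partition` runs it on `n_restarts`
random vertex orders (seeded) and keeps the best-Q labeling; in weighted
mode both the optimisation and Q use edge weights. The underlying method is
not prescribed by the emulated analysis; Louvain was chosen because it is
standard, fast, seedable, and handles weighted graphs, which the robustness
re-run needs. Group-level modular analyses run at cost 0.03, the sparsity
that preserves only the strongest connections (configurable).

Similarity between two partitions is normalized mutual information,
$\mathrm{NMI} = 2I(A;B)/(H(A)+H(B))$ in natural logs. Zero-entropy edge
cases are defined for continuity: two single-module partitions are
identical (NMI 1); a single-module against a structured partition is
uninformative (NMI 0). The group test statistic is *mean within-group
pairwise NMI (both groups pooled) minus mean between-group pairwise NMI*;
its null is built by shuffling the pooled group membership with group sizes
preserved (default 10000 shuffles), and the one-sided p-value uses the
add-one rule $p = (1 + \#\{T^{null} \ge T^{obs}\})/(1+B)$, so $p$ is never
exactly zero. The wording of the emulated analysis supports either pooling
the two within-group means or testing per group; pooling is the test
statistic, and both per-group means are reported descriptively.

For visualisation, each group gets a consensus map: the subject with the
highest mean NMI to the others is the representative (ties to the lowest
index); every other subject's module ids are renamed by solving the optimal
assignment on the module contingency table (Hungarian algorithm — renaming
only, co-membership structure and NMI are invariant; surplus modules get
fresh ids above the reference's maximum); each node then takes its modal
label, with the supporting frequency as assignment confidence (ties to the
smaller id). *Major modules* are modules with at least six nodes.

## The node-of-interest scan

For a node of interest (NOI), a subject's functional community is the
binary vector marking which other nodes share the NOI's module. Similarity
between subjects is the phi coefficient (Pearson correlation of 0/1
vectors) of these indicators. Per node, the statistic is again mean within-
minus between-group phi, permuted by group membership; one shuffle sequence
is shared across all 116 node tests, which makes the scan deterministic
given its seed and gives every node the same null ensemble. Significance is
Bonferroni-controlled at $\alpha/116 = 0.05/116$; uncorrected flags are
also reported, mirroring the two-tier display convention of such scans.

Zero-variance indicators (a subject whose NOI sits in a singleton module,
or whose partition is one module) make phi undefined for pairs involving
that subject; such pairs are excluded from the means and counted in the
output, a case the emulated analysis does not address.

Note a discreteness constraint: with $B$ permutations the smallest
attainable p is $1/(1+B)$, so Bonferroni discoveries at $0.05/116$ require
$B \ge 2320$. The calibration suite, which runs at a reduced $B = 1000$ for
runtime, therefore cannot produce corrected false positives — its
familywise-error check is structurally conservative — while power analyses
use $B = 5000$.

## The synthetic world

`generate_subject_timeseries` draws node series from a Gaussian factor
model: one latent factor per planted module, one global factor, independent
node noise,
$$x_i(t) = a\,g(t) + c\,f_{m(i)}(t) + \epsilon_i(t),$$
with loadings solved analytically from the target correlations
($V = \sigma^2/(1-r_w)$, $a = \sqrt{r_b V}$, $c = \sqrt{(r_w-r_b)V}$), so
same-module pairs correlate at $r_w$ and cross-module pairs at $r_b$
exactly in expectation. Infeasible requests ($r_b < 0$, $r_b > r_w$,
$r_w \ge 1$) are rejected as non-positive-definite; the degenerate request
$r_w = r_b$ is allowed and is the type-I-error fixture. Group-specific node
reassignments move selected nodes to another module's factor — the planted
effect every downstream test is asked to recover. Per-subject seeds are
fanned out from the master seed by a multiplicative hash of (group index,
subject index), so adding a group never changes existing subjects and
cohorts are bit-reproducible.

Defaults state the emulated world: 116 nodes, 200 volumes (a 204-volume
acquisition at TR 2.5 s minus four discarded volumes), and for the
demonstration design five planted modules of sizes 24/23/23/23/23 —
echoing the five major modules typically recovered in control resting-state
networks — with $r_w = 0.6$, $r_b = 0.1$, unit noise, and 20 subjects per
group for calibration studies. At cost 0.03 a single subject's Louvain
partition typically fragments the five planted modules into 6–8 communities
(sparse subgraphs split), yet the consensus map recovers exactly the five
planted major modules — a useful reminder that group-level maps are more
stable than per-subject partitions.

What the generator does **not** emulate: scanner drift and physiological
noise spectra, head motion, hemodynamic convolution, spatial smoothing,
inter-subject anatomical variability, or negatively correlated networks.
A green test therefore establishes that the *pipeline machinery* recovers
planted architecture at realistic dimensions and noise — not that any
neuroscientific claim about real cohorts is reproduced.

The preprocessing helpers mirror the usual order on node series: nuisance
regression (OLS residuals against intercept + covariates) first, then
zero-phase band-pass 0.01–0.1 Hz. The filter is a cascade of second-order
Butterworth high- and low-pass biquads, each applied forward–backward with
reflected padding; series are demeaned first so a constant maps exactly to
zero. Whether regression-then-filter versus the reverse matters cannot be
settled from the emulated description; the listed order is used. Voxel-level
preprocessing (realignment, normalisation, smoothing) is out of scope — the
generator produces node series directly.

## Numerical and interface choices

- Cost→edge-count rounding is half-up (`floor(x + 0.5)`); the convention is
  not prescribed anywhere, and half-up makes cost 0.03 on 116 nodes give
  exactly 200 edges.
- Tie-breaks are deterministic everywhere: edge ranking lexicographic,
  representative selection and consensus ties to the lowest index/id.
- Degenerate NMI and phi conventions as above; permutation p-values use the
  add-one rule.
- The summary-statistic tests use pooled (not Welch) variance — that is
  what reproduces the conventional printed degrees of freedom (e.g. df 54
  and 55 for groups of 27/29 and 27/30) — and the Tukey–Kramer harmonic-mean
  form for unequal sizes.
- Configs, manifests and reports are JSON (`jsonlite`); matrices,
  partitions, edge lists and time series are TSV; thresholded graphs are
  additionally exported as GraphML. Pipeline outputs are stamped with a
   32-bit FNV-1a hash of the configuration, and `summary.json` contains no
  wall-clock times, so a rerun with the same configuration is byte-identical.
- `select_representative` returns a 1-based index, the R convention.

## Known limitations

- Louvain is a heuristic: per-subject partitions are local optima, and the
  restart count trades determinism-cost against quality (20 by default; the
  simulation suites use 5, which calibration tolerates because
  exchangeability under the null does not depend on partition quality).
- The NMI group test detects *any* consistent architectural difference, not
  which regions drive it; the NOI scan localises, but flags every node
  whose community genuinely changes (when six nodes move between two
  modules, all members of both modules are affected — the scan correctly
  flags them all, which must be kept in mind when counting "false"
  positives against a planted truth).
- Costs below $2/n$ are infeasible (the backbone cannot fit) and error out.
- Weighted-mode modularity uses the rectified $|z|$ weights; no signed
  variant is provided.
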