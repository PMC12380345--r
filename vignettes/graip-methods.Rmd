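---
title: "Generating random graphs inside a probabilistic network's graphlet envelope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating random graphs inside a probabilistic network's graphlet envelope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graip)
```

## The problem

Interaction networks in biology are rarely certain: protein-protein
interaction databases attach a confidence score to every edge, reflecting
noisy experiments and error-prone inference. Treating such a network as a
deterministic graph -- keeping every edge, or thresholding -- discards
exactly the information that distinguishes a well-supported triangle from
a speculative one, and the topological properties of the *backbone* graph
can differ substantially from those of the graphs the probabilistic model
actually describes.

`graip` takes the probabilistic view seriously. An uncertain graph
$\mathcal{G} = (V, E, P)$ with independent edge probabilities
$P(e) \in (0,1]$ defines a distribution over $2^{|E|}$ deterministic
graphs ("possible worlds"): each edge is kept with probability $P(e)$.
The package answers the question: *how do we generate random deterministic
graphs that could plausibly have been drawn from this distribution,
as judged by their degree distribution and their graphlet content?*

Graphlets are the 29 connected non-isomorphic graphs on 3--5 nodes
(2 of order three, 6 of order four, 21 of order five), counted as induced
subgraphs. They capture local topology far beyond degree statistics, and
frequencies of small subgraph patterns are a standard currency for
comparing biological networks.

## The target envelope

Deriving exact graphlet count distributions under possible-world semantics
is computationally intractable (every sparser pattern inside every denser
backbone pattern contributes), so the envelope is estimated by Monte-Carlo
sampling: `graip(g, S, n_g)` draws `S` worlds, takes the largest connected
component of each (allowing the order $n$ to vary; ties are broken toward
the component with the smallest node label for reproducibility), and
records its order, size, degree histogram $N(k)$ and graphlet count
vector. Means $E$ and standard deviations $s$ (population form, divide by
`S`) of each quantity define the acceptance region
$[E - 2s,\, E + 2s]$, which would cover roughly 95% of the sampled worlds
under normality. Per-node degree moments are also available in closed
form: $E(k_v) = \sum_{e \ni v} P(e)$ and
$\mathrm{Var}(k_v) = \sum_{e \ni v} P(e)(1 - P(e))$.

```{r, eval = TRUE}
g <- make_uncertain_star(31, 0.7)
node_degree_moments(g, "v01")
```

### Degree binning

A deterministic graph cannot have half a node of degree 21. When the
target contains an isolated high-degree hub, sampling spreads its mass
over a broad peak of per-degree means all below one, and an unbinned
envelope would *forbid* the hub in any generated graph. The binning rule
therefore accumulates degrees from the highest observed degree downward
until a bin's weight (summed mean node count) reaches one; a complete
isolated peak thus collapses into one bin of weight exactly one --
empirical bin masses are integer sample counts divided by `S` -- whose
standard deviation is zero, forcing generated graphs to contain the hub.
Runs of degrees never observed in any sample get dedicated zero-weight
bins. Two adjustments keep the construction stable:

* **Tail rule.** Degrees occurring in fewer than 1% of samples are moved
  from the boundary of a peak bin into the adjacent zero bin, so bin
  widths do not keep growing as `S` increases. Only the edges move; the
  sub-1% mass stays attributed to its peak, preserving
  $\sum_i w_i = E_n$ and the weight-one property of complete peaks.
* **Wide-bin deviation.** For bins wider than one degree the per-degree
  sampled deviations are replaced by the minimal $s$ such that
  $[w - 2s,\, w + 2s]$ contains both $\lfloor w \rfloor$ and
  $\lceil w \rceil$ (the occupancy of a bin is an integer even when its
  weight is not): `wide_bin_stdev(1.6)` is 0.3, integer weights give 0.
  An epsilon of $10^{-9}$ absorbs floating error around integer weights.

Leading zero-weight bins below the lowest observed degree are dropped so
that bins tile the observed degree range; degrees of a candidate graph
falling outside that range are accumulated into the nearest boundary bin,
so such graphs register as out of bounds rather than failing. Degree 0 is
excluded throughout (largest components have no isolated nodes).

## The incremental generator

`graip_generate()` grows a graph by single-edge and single-node edits.
Every `node_step`-th step (default 5; a node edit moves several edges at
once, so node moves should be rarer than edge moves) proposes a node
insertion or removal, all other steps an edge insertion or removal.
Whether to grow or shrink is decided by a logistic gate
$f = 1/(1 + e^{-d})$ on the standardized deviation $d$ of the order from
$E_n$ (or, for edges, of the size with $m$ scaled by $E_n/n$, so a graph
of the wrong order is not additionally pushed toward the wrong density);
the move *adds* when a uniform draw exceeds $f$, so a graph far below
target grows almost surely and one at target adds or removes evenly.

Node insertion mimics preferential attachment: the anchor neighbor is
drawn with probability proportional to degree. If the anchor belongs to a
clique of order $\ge 4$, the new node joins the largest clique containing
the anchor -- large cliques occur in biological networks but would
otherwise be vanishingly unlikely to assemble edge by edge. (The clique
search is an exact branch-and-bound restricted to the anchor's
neighborhood, capped at order 12; the cliques this rule targets are
small.) Otherwise each further neighbor of the anchor is linked with
probability $p_{nb} = (\bar{CC} \cdot k_v(k_v+1)/2 - e_{nv})/k_v$,
clamped to $[0,1]$ -- the value that makes the anchor's expected local
clustering coefficient equal the target's mean clustering coefficient
$\bar{CC} = 3E[M_2] / (E[M_1] + 3E[M_2])$.

### Cost and acceptance

A proposal is scored against the envelope by a two-part cost, mixed with
weight `w` (default 2/3, which in practice balances the two terms):

* the **degree term** is the mean relative deviation of the *reversed
  cumulative* binned degree distribution (fraction of nodes of degree at
  least each bin's lower edge) from its target mean -- cumulative so that
  a surplus of low-degree nodes matched by a deficit of high-degree nodes
  is not penalized while hubs are still growing;
* the **graphlet term** sums, over types outside their interval, the
  logarithm of $C_i/E_i$ in base $1 + f_i$ (above) or $1 - f_i$ (below),
  with $f_i = 2 s_i / E_i$: the base is the factor by which $E_i$ must be
  multiplied to reach its bound. The logarithm reflects the combinatorial
  growth of contained-pattern counts -- a 10-clique holds
  $\binom{10}{5} = 252$ five-cliques but a 9-clique only 126, so single
  edits can change counts multiplicatively. Types inside their interval
  contribute nothing.

Degenerate inputs get explicit guards, chosen to keep the cost finite and
monotone in the deviation: cumulative bins with zero target mass are
skipped; a zero count below its lower bound enters the log as 0.5 (capped
at $E_i$); target means of zero are floored at 0.5; the lower base is
clamped to $[0.01, 1 - 10^{-6}]$ (it degenerates when $s_i \ge E_i/2$)
and the upper base to at least $1 + 10^{-6}$ (certain targets have
$s_i = 0$); each contribution is floored at zero.

A proposal is accepted when it strictly lowers the cost, or
unconditionally after `max_rej` consecutive rejections (default
$\max(1, \mathrm{round}(0.02\,E_m))$) -- the forced acceptance keeps the
walk from freezing when the graph is almost right. Proposal effects on the
count vector are computed *incrementally*: for an edge edit only connected
node sets through both endpoints are enumerated (on the graph with the
edge present, whichever direction the edit goes; the edit is then a
single bit flip in each set's encoding), for a node edit only sets through
that node. The candidate graph is never materialized; rejected proposals
undo a temporary adjacency extension. Generation stops the moment the
graph lies within bounds (checked at the top of every iteration,
including the first, with closed intervals) or after `max_s` steps.

The seed graph is a preferential-attachment graph with 20% of the
target's nodes and edges (attachment parameter
$\mathrm{round}(E_m/E_n)$, edge count then adjusted exactly); a
scale-free seed is a plausible embryo for biological-like targets and is
small enough that its topology washes out. Targets with $E_n < 5$ are
rejected as degenerate. All randomness flows through R's RNG with a fixed
per-step draw order (gate first, then proposal draws), so a seed
reproduces a run exactly.

## The counting engine

The enumeration core (C++ via Rcpp, as is usual for subgraph counting) is
shared by the full counter, the incremental deltas and the sampling loop.
Connected sets are enumerated once each by exclusive-neighborhood
extension (ESU style): candidates extending a set are neighbors of the
newest member that are neither in the set nor adjacent to its older
members, which partitions the enumeration tree so no set is visited
twice; the full counter additionally roots each tree at the set's minimum
label. Each set of size $k$ is encoded as a bit-string -- pair $(v_i,
v_j)$, $i<j$, maps to bit $(j-1)(j-2)/2 + (i-1)$ -- and classified by a
precomputed lookup table (sizes $2^3$, $2^6$, $2^{10}$) mapping every
labelled edge set to its isomorphism class, or to nothing when
disconnected. Tables are built once per session by brute-force
canonicalization over all $k! \le 120$ relabelings; the build takes
milliseconds, so there is nothing to persist.

Because the exact per-type numbering of the 5-node types varies across
the literature, the catalog fixes its own deterministic order -- (order,
edge count ascending, maximum degree descending, canonical form) -- which
anchors M1 = 3-path, M2 = triangle, M3 = 4-star, M8 = 4-clique,
M9 = 5-star and M29 = 5-clique; `graphlet_catalog()` documents the rest.

The headline correctness property -- incremental deltas agree exactly
with full recounts over long randomized edit sequences, for all of
$n_g \in \{3,4,5\}$ -- is asserted in the test suite, with the full
counter cross-checked against an independent motif census (igraph) for
orders 3--4 and against closed-form clique counts.

## SwapCon baseline

The baseline generator draws a degree sequence from the binned expected
degree distribution, realizes it by configuration-model stub matching
(projected to a simple graph), and then anneals degree-preserving double
edge swaps toward the expected graphlet counts. Three interpretation
choices were open:

* the annealing **energy** is the mean relative deviation
  $\frac{1}{T}\sum_i |C_i - E_i| / \max(E_i, 1)$, making the 5% stopping
  threshold read as "5% average relative error";
* each bin's **representative degree** is the sampled-histogram-weighted
  mean of the degrees inside it (a plain geometric midpoint of wide bins
  biases the drawn mean degree upward by several percent);
* energy-**neutral swaps are executed but do not reset the stall
  counter** (temperature 0.01, cooling 0.99 per proposal, stop after
  `round(E_m)` proposals without improvement); accepting them keeps the
  graph randomizing on plateaus, but counting them as progress would
  prevent termination.

Counts are recomputed with the full counter per proposal: a swap touches
four edges, so the local-delta machinery would enumerate four
neighborhoods and is generally no faster here.

## Evaluation metrics

Ensembles of generated graphs are compared to freshly sampled worlds with
the unbiased squared maximum mean discrepancy under a Gaussian kernel,
computed on either normalized degree histograms (zero-padded to the
ensemble-wide maximum degree) or raw graphlet count vectors. The
bandwidth defaults to the median pairwise distance of the pooled vectors;
absolute MMD values therefore depend on that choice and only
*comparisons under one bandwidth* are meaningful. A permutation-null
helper (`mmd_null_quantile`) gives a calibrated reference: ensembles from
the same distribution fall below the null's 95th percentile at roughly
the nominal rate.

Randomness is summarized by spread ratios of properties no generator here
controls directly -- the diameter of the largest component and the mean
local clustering coefficient -- where the spread is the 95th minus the
5th percentile and the ratio is generated over sampled. Percentiles use
piecewise-linear interpolation through order-statistic midpoints
(`quantile(type = 5)`), under which 100 values $1..100$ give a spread of
exactly 90. A zero sampled spread makes the ratio undefined and is
reported as `NA`.

## What the synthetic fixtures do and do not emulate

The fixture module generates uncertain Erdős–Rényi and preferential-
attachment backbones with edge probabilities uniform on $(0,1]$, plus a
31-node star with uniform probability 0.7 as the canonical
hub-peak example. The ER fixture uses the fixed-edge-count variant
$G(n,m)$ so a requested mean degree is exact; the BA fixture distributes
per-node attachment quotas to hit the requested edge total exactly.
These match the controlled conditions under which the generator is
validated: uniform, degree-independent edge uncertainty and clean model
backbones. Real interaction networks differ in ways the fixtures do not
capture -- confidence scores are bimodal rather than uniform, correlate
with node degree and study bias, and edges are not independent. Passing
tests on fixtures therefore demonstrate the correctness of the machinery
and the attainability of the envelope under the stated conditions, not
that any particular biological network is well modelled.

## Problem sizes and known limitations

The test suite exercises: the ER study condition (50 nodes, mean degree
4, envelope from 500 worlds, order-4 graphlets; ten seeded generation
runs, all required to end inside the envelope), preferential-attachment
targets at 100--400 nodes and mean degree 5 (200--300 worlds) for the
scaling and convergence checks, 10 000-world sampling for the star
fixture, and 210 randomized edits for the incremental-counting oracle.
These sizes were chosen so the full suite documents the method at desk
scale; the same code runs unchanged on larger networks.

Limitations worth knowing:

* enumeration-based counting is effective on *sparse* graphs; at high
  density (or $n_g = 5$ on dense neighborhoods) the local neighborhood of
  an edit approaches the whole graph and per-iteration cost grows;
* the generator guarantees termination inside the envelope only when run
  without a step cap and when the envelope is attainable; capped runs
  return the current graph with `within_bounds = FALSE` recorded;
* SwapCon frequently stalls above the 5% energy threshold on loose
  envelopes (the annealing has no forced-acceptance analogue); its final
  energy is still no worse than its initial one;
* absolute MMD scores are bandwidth-dependent and not comparable across
  studies; use the permutation null or fix `sigma` explicitly.
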