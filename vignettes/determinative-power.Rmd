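---
title: "Determinative power and minimal determinative subnetworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determinative power and minimal determinative subnetworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(booldp)
```

## The model

A Boolean network places `n` binary nodes `X_1, ..., X_n` on a wiring
digraph. A *regulated* node `i` carries an update rule `f_i`, a Boolean
function of an ordered subset of node states (its inputs); all regulated
nodes update synchronously. A node with no rule is an *external component* —
a ligand, stress signal, or other exogenous input — and is a full member of
the network: it has no dynamics of its own but can drive the nodes it feeds.
Rules are stored as explicit truth tables, in ascending binary row order
with the first listed input as the most significant bit; that convention
fixes the bijection between table rows and input assignments everywhere in
the package (parsers, serializers, evaluators).

Node states are modelled as independent Bernoulli variables with activation
probabilities `p_j = P(X_j = 1)`. The default is `p_j = 1/2` for every node,
i.e. all `2^n` current states equally likely — the ergodic assumption that
is standard in this literature. Biased, still-independent distributions are
supported throughout because every formula below holds for any product
distribution; correlated or attractor-weighted distributions are out of
scope.

## Determinative power

How much does knowing the current state of node `j` tell us about the next
state of the network? For a single target rule this is a mutual
information,

$$MI(f_i(X); X_j) = H(f_i(X)) - H(f_i(X) \mid X_j),$$

and because `f_i(X)` is a Bernoulli variable its entropies reduce to the
binary entropy `h` of *support masses*: with `supp f_i = {x : f_i(x) = 1}`,

$$MI(f_i(X); X_j) = h\Big(\sum_{x \in \mathrm{supp} f_i} p_x\Big)
 - \sum_{b \in \{0,1\}} P(X_j = b)\,
   h\Big(\sum_{x \in \mathrm{supp} f_i} P(X = x \mid X_j = b)\Big).$$

This is exact and costs `O(2^{k_i})` for a rule with `k_i` inputs — never
`2^n`. The *determinative power* of node `j` sums these information gains
over the nodes that list `j` as an input:

$$DP(j) = \sum_{i=1}^{n} MI(f_i(X); X_j).$$

Each MI term lies in `[0, 1]` bit, so `DP(j)` is bounded by the out-degree
of `j`; the bound is attained only when every output of `j` is fully
determined by `j` alone. A node can have many outputs and still a small DP
(e.g. XOR-like rules, for which each single input carries zero
information), which is exactly why DP rather than out-degree is the ranking
criterion.

On the bundled four-node example (`example1_network()`: an AND-NOT rule, a
nested AND-OR rule, an OR rule, and one external input), the package
computes `DP = (0.8601, 0.4980, 0.1867, 0.1379)` for nodes `x1..x4`,
ranking `x1 > x2 > x3 > x4`. These values are verified in the test suite by
a second, independent route — full `2^4` joint-state enumeration — and the
same dual-route check runs over a hundred seeded random networks at
tolerance `1e-9` bits.

```{r example}
net <- example1_network()
determinative_power(net)
```

## Selecting a minimal determinative subnetwork

Rank all nodes by DP and let `S_l` be the top `l`. The uncertainty left in
the network once `S_l` is known is bounded above by summing per-node
conditional entropies:

$$H(X' \mid X_{S_l}) \;\le\; A(l) = \sum_{i} H(X'_i \mid X_{S_l}),$$

where `X'` is the next network state. For a regulated node the term is
`H(f_i(X) | X_{S_l})`, computed locally from the rule's truth table with
the unselected inputs marginalized; for an external node it is its own
state entropy `h(p)` until the node is selected, and 0 afterwards.

Two interpretive choices deserve note, because the bound's definition does
not force them:

* **One-step reading.** `H(X_i | X_{S_l})` is implemented as the entropy of
  node `i`'s *next* value given the *current* states of `S_l`. This is the
  only reading that is computable for networks with feedback cycles and the
  one consistent with the support-based MI formulas; it also makes `A`
  provably non-increasing with `A(n) = 0` when every node is selectable.
* **Candidate policy.** By default every node — external included — is
  rankable and selectable (`candidates = "all"`), since external inputs have
  DP and the worked example counts one among its four nodes. The
  alternative `candidates = "regulated"` never selects externals, so their
  state entropy persists in the curve and `A` converges to a positive
  plateau; this reproduces the behaviour seen in models whose exogenous
  inputs are treated as unconditioned randomness.

The cutoff is found on the decrement sequence `B(l) = |A(l+1) - A(l)|`,
smoothed by a centered moving average of window `d`:

* `d = ceiling(0.1 (n-1))`, with a floor of 1. One tenth of the sequence
  length trades smoothing against responsiveness; much larger windows blur
  the elbow, much smaller ones stop at noise.
* Padding: the first windowed mean is repeated `floor((d-1)/2)` times at
  the front, the last `ceiling((d-1)/2)` times at the back, so the smoothed
  sequence keeps length `n - 1`; an even `d` repeats the last element once
  more than the first. This exact split is pinned by unit tests on three
  worked ten-term sequences.
* Threshold `T = max(MA_d)/4` (tunable via `t_factor`). The cutoff `L` is
  the smallest rank at which `MA_d(L) <= T` *and* the mean of the next `d`
  smoothed values (dividing by `d` even when the window is truncated at
  `n - 1`) is also `<= T` — the decrements must drop below the threshold
  and stay there on average. If no rank qualifies, `L = n`: the whole
  network is kept rather than guessing.

`select_subnetwork()` composes the pipeline and returns the full trace
(`A`, `B`, `MA`, `d`, `T`, `L`, the ranking and the selected set);
`sweep_cutoff()` recomputes `L` over a `d` × `T` grid to expose the
parameter sensitivity (`L` is non-increasing in `T` row-wise). Exact
enumeration costs `2^{k_i}` per rule; rules with more than 24 inputs are
refused with a clear error rather than silently approximated.

## Topological attributes

The wiring digraph has an edge `j -> i` whenever `j` is a listed input of
`i`. Degree counts include self-inputs; path-based measures exclude
self-loops. Distances use the convention `d(i, j) = 0` when no path exists,
so unreachable pairs simply drop out of the farness sums
`F_in(i) = sum_j d(j, i)`; note this *inflates* closeness for poorly
connected nodes relative to conventions that penalize unreachability, and
it is applied verbatim because the downstream definitions assume it.
Closeness is the squared reachable fraction over farness,
`C_in(i) = (A_in(i)/(n-1))^2 / F_in(i)` (0 when nothing reaches `i`), and
betweenness accumulates, over ordered pairs of distinct third nodes, the
fraction of shortest paths passing through `i`, computed by breadth-first
shortest-path counting with dependency accumulation. Both are verified
against exhaustive depth-first path-enumeration oracles on every digraph
over 4 nodes and on random 7-node digraphs.

The wiring graph is built from *listed* inputs, not essential dependence: a
rule may list a fictitious input (one that never changes its output), and
that edge still counts, because model files record listed inputs and the
degree/edge statistics are defined on them.

## Cohort statistics and essentiality

`summarize_network()` collects the eight per-network variables (`n`, `L`,
`E`, max/avg DP, `L/n`, `E/n^2`); `cohort_regressions()` fits the standard
3 × 4 grid of least-squares lines (responses `L`, `L/n`, max DP, avg DP
against predictors `n`, `E`, `E/n^2`) with `R^2` as the squared Pearson
correlation. `essential_overlap()` compares the proportion of externally
labelled essential nodes among the top-`k` DP ranks with the background
proportion and reports a one-sided hypergeometric tail p-value. The
hypergeometric (Fisher) test is a design choice: it is the exact test for
drawing `k` nodes from a finite labelled universe, and the test is verified
against direct tail summation; database lookups that would produce the
essentiality labels themselves are out of scope — the labels arrive as a
plain text list.

## The random-network generator

`generate_random_network()` draws, per regulated node, an in-degree (fixed
or ranged), distinct inputs, and i.i.d. Bernoulli truth-table bits with a
configurable bias; a fraction of nodes is left external and self-inputs are
injected with a configurable probability (default 0, so that code path is
exercised deliberately rather than by accident). Defaults — `k` small
relative to `n`, bias near 1/2, a modest external fraction — mirror the
sparse wiring (`E/n^2` well below 0.15) and mixed rule biases of published
signal-transduction models. What the generator does **not** emulate:
canalizing or nested-canalizing rule structure, scale-free degree
distributions, or correlated input states. Passing tests on generated
networks therefore establishes the *mathematical* correctness of the
measures, not that any biological claim transfers to a particular published
model.

## Numerical choices and problem sizes

* Logarithms are base 2 throughout; `0 log 0 = 0`; MI values are clamped at
  0 against `-1e-16`-scale float residue.
* DP ties are broken by original node order (stable sort), making rankings
  deterministic.
* Dual-route verifications run at `1e-9` bits (MI vs enumeration), machine
  precision for the `MI = H - H(·|·)` identity, and `1e-12` for centrality
  oracles.
* Test problem sizes were chosen so the exhaustive oracles stay exact and
  the whole suite runs in minutes: networks of up to 8 nodes for MI
  enumeration (100 draws), up to 6 for joint-entropy bounds (20 draws),
  4096 four-node digraphs plus 50 seven-node digraphs for centralities.
  These sizes are oracle-driven: beyond them brute-force enumeration stops
  being a trustworthy independent reference, not because the implementation
  slows down (it handles hundred-node models comfortably).

## Known limitations

* The input distribution must be a product distribution; steady-state or
  attractor-conditioned weighting is not supported.
* The selection algorithm reduces node *count*, not dynamics: the selected
  subnetwork is reported as a node set, and no rewired reduced model is
  constructed.
* SBML-qual import is not provided; models enter as logic-expression files
  or truth-table directories.
* The unreachable-pair distance convention makes closeness values
  incomparable with most other network toolkits' closeness; use the
  exported `A_in`/`F_in` columns to re-derive alternatives if needed.
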