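# booldp — determinative power analysis of Boolean network models

Logical (Boolean) models are a workhorse for signal-transduction and gene
regulatory networks: each node is on/off and updated by a logic rule of a
few inputs. For models with dozens to hundreds of nodes, a natural question
is *which nodes determine the network's behaviour* — knowing the states of
which small node set leaves the least uncertainty about everything else?

`booldp` answers this information-theoretically, for modellers working with
logic-rule or truth-table model files:

- **Determinative power (DP).** For each node `j`,
  `DP(j) = Σ_i MI(f_i(X); X_j)` — the summed mutual information between
  `j`'s state and the update rules of the nodes it feeds, computed *exactly*
  from truth-table supports under independent inputs (uniform by default).
  Cost is `2^k` per rule of `k` inputs, never `2^n`.
- **Minimal determinative subnetwork.** Ranking nodes by DP, the
  conditional-entropy upper bound
  `A(l) = Σ_i H(X'_i | X_{S_l})` (with `S_l` the top-`l` nodes) decreases as
  nodes are added; the package smooths its decrements with a padded moving
  average of window `d = ⌈0.1(n−1)⌉` and cuts at the first rank `L` where
  the smoothed decrements fall, and on average stay, below
  `T = max(MA_d)/4`. The top-`L` nodes are the selected subnetwork.
- **Topology.** In/out-degrees, in/out-closeness
  `C_in(i) = (A_in(i)/(n−1))² / F_in(i)` with the unreachable-pair
  convention `d = 0`, and shortest-path betweenness on the wiring digraph.
- **Cohort statistics.** Per-network summaries (`n`, `L`, `E`, max/avg DP,
  `L/n`, `E/n²`), least-squares regression grids with `R²`, and top-k
  essential-node enrichment (one-sided hypergeometric test).
- **I/O and synthesis.** Parsers/writers for `.bnet`-style logic-expression
  files and per-node truth-table directories (Cell Collective-style
  exports), GraphML/DOT export of the wiring digraph, and a seeded
  random-network generator with brute-force enumeration oracles used by the
  test suite.

## Worked example

The bundled four-node model has rules `x1 <- x2 & x3 & !x4`,
`x2 <- x1 & (x2 | x3)`, `x3 <- x1 | x2`; `x4` has no rule (an external
input feeding `x1`).

```r
library(booldp)
net <- example1_network()
determinative_power(net)
#> Determinative power, 4 nodes
#>  node        dp out_degree rank
#>    x1 0.8600731          2    1
#>    x2 0.4979984          3    2
#>    x3 0.1867203          2    3
#>    x4 0.1379254          1    4
```

`x1` is the most determinative node: its two outputs yield
`MI(f2; X1) = 0.5488` and `MI(f3; X1) = 0.3113` bits, summing to
`DP(x1) = 0.8601`. Note `x2` has *more* outputs (3) but less determinative
power — rule structure, not out-degree, drives DP. The external `x4`
determines its single output only weakly (0.1379 bits) because the AND-NOT
rule it enters is rarely decided by `x4` alone.

```r
select_subnetwork(net)
#> Subnetwork selection: L = 4 of 4 candidates (d = 1, T = 0.3125 bits)
#> Selected: x1, x2, x3, x4
```

On a network this small every entropy decrement stays above the threshold,
so the whole network is kept (`L = n` fallback). On realistic models the
curve elbows much earlier; e.g. a 94-node T-cell receptor signalling model
selects 40 nodes under the same defaults.

A command-line driver wraps the same functions:

```sh
exec/booldp select --model model.bnet --out run1     # trace.csv, selected.txt, manifest.json
exec/booldp dp --model tables_dir --out run2         # dp.csv, mi.csv
exec/booldp topology --model model.bnet --out run3   # centrality.csv
```

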