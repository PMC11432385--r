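# organspan

Which organ does a multi-compound preparation predominantly act on?
**organspan** answers that question on organ-specific protein–protein
interaction networks. It is aimed at systems-pharmacology analysts who have,
per organ, a tissue protein list and an interaction-score table, plus three
evidence channels about the compound set: predicted targets from a
network-pharmacology platform, post-processed docking scores, and a
differential-expression result table.

## The method

For each organ network *G* (nodes = tissue proteins, edges = interactions
with combined score ≥ 700, components with < 10 nodes pruned):

* **Hubs** — the top 20% of the raw degree distribution, with ties at the
  cut degree included, so membership is `{v : deg(v) > d*}` for an integer
  threshold `d*`.
* **Evidence sets** — NP targets (prediction score ≥ 10), dockable proteins
  (> 10 docking interactions at affinity < −8 kcal/mol), DEGs
  (|log2FC| > log2(1.5), adjusted p < 0.05), and their integration
  IP = DP ∪ DEG.
* **Hit ratios** — `|mapped ∩ R| / |R|` for reference set *R* = whole
  network or hub set, printed as half-up-rounded percentages.
* **Permutation test** — draw `|mapped|` nodes uniformly without replacement
  `N` times (default 100,000) and rank the observed hub-hit count:
  `p = #{count ≥ observed}/N`, displayed `<1/N` at zero exceedances. The
  exact hypergeometric tail `P(X ≥ observed)` is provided as an independent
  oracle.
* **Spanning** — treat each node as one dimension of the organ's functional
  space; `covered(k)` = nodes within *k* BFS hops of the IP seeds, the
  shell-1 rate is the first-shell coverage, and *walks to full span* is the
  seed-set eccentricity over reachable nodes.
* **Verdict** — majority over four criteria (lower IP permutation p, higher
  IP hub hit ratio, higher shell-1 spanning, fewer walks to full), each also
  reported individually.

A fully parameterised synthetic-data generator (`synthetic_config()`,
`simulate_bundle()`) emits every input with known ground truth, including a
`hub_bias` knob that plants evidence on or off the hubs, so the whole
pipeline is testable without any external database.

## Worked example

Two synthetic organs: a "brain-like" bundle whose evidence is planted on
hubs (`hub_bias = 0.8`) and an "intestine-like" bundle with nearly unbiased
evidence:

```r
library(organspan)

bsn <- simulate_bundle(synthetic_config(seed = 1, hub_bias = 0.8), label = "BSN")
isn <- simulate_bundle(synthetic_config(seed = 2, hub_bias = 0.1), label = "ISN")
report <- run_pipeline(list(bsn, isn),
                       params = default_params(n_permutations = 10000),
                       seed = 42)
report
```

```
== Organ-dominance comparison ==

Whole-network hit ratios:
 analysis network denominator n_hit percent
       NP     BSN         275    50  18.18%
       DP     BSN         275     7   2.55%
      DEG     BSN         275    65  23.64%
       IP     BSN         275    69  25.09%
       NP     ISN         285    50  17.54%
       DP     ISN         285     7   2.46%
      DEG     ISN         285    65  22.81%
       IP     ISN         285    71  24.91%

Hub hit ratios and permutation p:
 analysis network denominator degree_threshold n_hit percent p_display
       NP     BSN          56                3    39  69.64%   <0.0001
       DP     BSN          56                3     5   8.93%    0.0045
      DEG     BSN          56                3    44  78.57%   <0.0001
       IP     BSN          56                3    46  82.14%   <0.0001
       NP     ISN          62                3     3   4.84%    0.9997
       DP     ISN          62                3     3   4.84%    0.1692
      DEG     ISN          62                3     6   9.68%    0.9993
       IP     ISN          62                3     9  14.52%    0.9925

Spanning (IP seeds):
 network seed_size n_nodes covered_shell1 rate_shell1 percent_shell1
     BSN        69     275            228   0.8290909         82.91%
     ISN        71     285            154   0.5403509         54.04%
 walks_to_full unreachable
             3           0
             3           0

Dominant organ: BSN
  - lower IP permutation p: BSN
  - higher IP hub hit ratio: BSN
  - higher shell-1 spanning rate: BSN
  - fewer walks to full span: tie
```

Reading it: the hub-planted organ's integrated evidence hits 82.14% of its
hubs (46 of 56) — no permutation of 10,000 reached that count, so the test
prints `<0.0001` — and its first shell covers 82.91% of the network's
dimensions, versus 14.52% hub hits (p ≈ 0.99) and 54.04% coverage for the
unbiased organ. Three of four criteria vote BSN (walks-to-full ties at 3),
so BSN is declared the dominant organ.

Every result object is a tidy citizen: `tidy()` / `glance()` return tibbles,
`autoplot()` draws the null distribution of a permutation test or the
spanning coverage curve, and `write_report()` / `export_network_views()`
emit GraphML, SIF and node-attribute TSVs for Cytoscape. A thin CLI lives at
`inst/scripts/organspan` (`simulate` and `run` subcommands driven by a YAML
config; see `?read_run_config`).

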