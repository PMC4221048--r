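# sigorg

Self-organization analysis of mass-action signalling networks.

## The problem

Signalling cascades such as the EGF-induced MAPK pathway are usually
described module by module — receptor layer, adaptors, the
Ras/Raf/MEK/ERK core, phosphatases. `sigorg` characterizes the same
network *functionally*: proteins whose concentration time-courses share
a shape are grouped together, whatever module they belong to, and the
way those groups reorganize with stimulus intensity is quantified. The
package is aimed at systems biologists who have (or can write down) a
mass-action model of a pathway and want to know

* which proteins behave as functional units at each stimulus level,
* how the functional organization changes from low to high stimulus,
* which groups are robust across all levels (consensus groups) and
  which proteins typify them,
* which measurable output parameter best encodes stimulus intensity,
* and which single-protein removals silence, dampen or disinhibit the
  output.

## Methods at the core

* **Simulation** — mass-action kinetics $\dot c = S\,v(c)$,
  $v_r = k_r \prod_i c_i^{s_{ir}}$, integrated by an embedded adaptive
  Runge–Kutta–Fehlberg 4(5) scheme over 100 min, across grids of
  constant-stimulus levels (101 levels for clustering, 630 for
  information estimates).
* **Dominant-sets clustering** — per stimulus level, normalized
  profiles give a similarity matrix $A_{ij} = e^{-d_{ij}/\sigma}$
  ($A_{ii}=0$); groups are extracted as local maximizers of the
  cohesiveness $F(m) = m^\top A m$ over the simplex via replicator
  dynamics $m_i \leftarrow m_i (Am)_i / (m^\top A m)$, peeled
  iteratively, with the group count calibrated against a permutation
  "chance level" (1000 permutations, $\alpha = 0.005$).
* **Variation of information** — clusterings are compared with the
  metric $\mathrm{VI} = H(c_1) + H(c_2) - 2I(c_1,c_2)$ (nats), embedded
  by classical MDS, and aggregated through the co-assignment consensus
  matrix, which is re-clustered with the same dominant-sets machinery.
* **Mutual information** — nine output-derived parameters (AUC, maximum
  activation rate and its timing for each of the two outputs, plus
  combined AUC-sum, OR-max-rate, OR-min-timing) are ranked by the
  Kraskov–Stögbauer–Grassberger kNN estimator (variant 1, $k=5$).
* **Screens** — single-species knockouts (concentration pinned at zero)
  scored by percent change of the OR-max-rate index, and rate-constant
  noise scans scored by VI divergence of the regrouping.

See the vignette (`vignettes/self-organization-analysis.Rmd`) for the
full account of assumptions, defaults and numerical choices.

## Worked example

The package ships a seeded toy cascade — ligand, receptor, three kinase
tiers with phosphatases, a duplicated "internalized" route, degradation
sinks, two outputs — so everything runs with zero downloads:

```r
library(sigorg)
net <- make_toy_cascade(seed = 1)
net
#> reaction_network: 18 species, 16 reactions
#>   cell volume: 1e-12 L
#>   stimulus: S
#>   outputs: X3a, X3ai

vm <- vulnerability_screen(net, stimulus_level = 5000,
                           grid = time_grid(100, 1001))
print(head(vm, 8), digits = 3)
#>   species baseline_index knockout_index pct_change rank
#> 1       R            103            0.0     -100.0    1
#> 2      RS            103            0.0     -100.0    2
#> 3       S            103            0.0     -100.0    3
#> 4      X1            103            0.0     -100.0    4
#> 5      X2            103            0.0     -100.0    5
#> 6      X3            103            0.0     -100.0    6
#> 7    X2ai            103           89.8      -13.1    7
#> 8    X1ai            103           91.1      -11.8    8
print(tail(vm, 3), digits = 3)
#>    species baseline_index knockout_index pct_change rank
#> 14      P1            103            135       30.4   14
#> 15      P2            103            150       44.7   15
#> 16      P3            103            208      101.4   16
```

Reading: the baseline maximum activation rate of either output is 103
molecules/min. Removing the stimulus, the receptor, the bound receptor
complex or any shared kinase pool silences the network completely
(−100%); removing internalized-route species only dampens it (the
surface route carries most of the signal); removing a phosphatase
*disinhibits* the output — knocking out the terminal phosphatase P3
doubles the maximum activation rate (+101%).

The full study — per-level clusterings, VI/MDS comparison, consensus
groups with representatives, MI ranking, screens — runs as composable
stages writing CSV artifacts plus JSON manifests:

```r
cfg <- pipeline_config(out_dir = "sigorg-out")
run_stage("all", cfg)           # cached; re-runs reuse simulations
read.csv("sigorg-out/mi_ranking.csv")
```

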