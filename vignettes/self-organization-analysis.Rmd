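---
title: "Functional self-organization analysis of signalling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional self-organization analysis of signalling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sigorg)
```

## The question the package answers

A growth-factor signalling cascade such as the EGF-induced MAPK pathway
is usually drawn as a stack of modules: receptor layer, adaptor layer,
the Ras/Raf/MEK/ERK kinase core, phosphatases. `sigorg` asks a different
question: which proteins *behave* together? Two species are treated as
functionally coupled when their concentration time-courses have similar
shapes, regardless of where they sit in the wiring diagram. The package
chains five analysis layers to answer it:

1. **Simulate** a mass-action reaction network deterministically across
   a grid of stimulus levels.
2. **Profile** each tracked species: min–max normalize its time-course
   to $[0,1]$ and build a Euclidean distance and exponential similarity
   matrix over species.
3. **Cluster** each similarity matrix with the dominant-sets algorithm,
   which both groups the species and decides the number of groups via a
   permutation "chance level".
4. **Compare** the per-level groupings with the variation-of-information
   (VI) metric, embed them by classical MDS, and **aggregate** them into
   a consensus clustering with representative proteins per group.
5. **Rank** candidate output parameters by their mutual information with
   the stimulus level, then **screen** the network by in-silico knockout
   and by rate-constant noise.

## Model class and simulation

A `reaction_network` is a species table plus a list of mass-action
reactions of order at most two. Canonical units are molecules/cell for
amounts, minutes for time, and 1/(min·molecule) for second-order rate
constants; `rescale_units()` converts per-second constants (×60),
nanomolar amounts (1 nM in a cell volume $V$ litres is
$10^{-9} V N_A \approx 602$ molecules at $V = 10^{-12}$ L, the default
volume) and mass concentrations (requiring a molecular weight in the
model file). The kinetics are

$$\dot{c} = S\,v(c), \qquad v_r(c) = k_r \prod_i c_i^{\,s_{ir}},$$

integrated with an embedded adaptive Runge–Kutta–Fehlberg 4(5) scheme
(deSolve's `rk45f`) at `rtol = atol = 1e-6`. Conformance is defined
behaviourally — agreement with a fixed-step RK4 oracle at $dt = 10^{-3}$
min to better than $10^{-4}$ relative error — rather than by a specific
tableau. The sampling grid is 1001 uniform points over 100 min
($dt = 0.1$ min), fine enough to resolve the fastest receptor-layer
transients that later define the fastest-dynamics group. Tiny negative
excursions (inherent to non-stiff adaptive stepping near zero) are
clipped to zero; an excursion beyond $-10\,\mathrm{atol}$ aborts the
run as a genuine integration failure.

Two stimulus conventions exist. By default the stimulus species simply
starts at the requested level and is consumed by its binding reactions
(the behaviour of the underlying ligand–receptor model); a
`stimulus_mode = "clamped"` switch pins it constant instead. Knockouts
follow the "zero the initial amount and its rate equation" convention:
the species is pinned at zero, reactions are kept, and anything
consuming the species simply sees no substrate.

Two standard stimulus grids are built in. The clustering grid is 101
levels spanning 5–5000 molecules/cell; uniform linear spacing is used
because only the endpoints and the count are fixed by the study design.
The information grid enumerates 1–500 step 1, 500–1000 step 10 and
1000–5000 step 50 with duplicates removed, which yields 630 unique
levels (direct enumeration of the three ranges; one fewer simulation —
629 — is sometimes quoted for the same design, a discrepancy the grid
builder documents by construction).

## Profiles, similarity, and dominant sets

Each tracked species' trajectory is independently min–max scaled, so
only the *shape* of activation matters. A profile whose dynamic range is
below $10^{-12}\max(1, \max)$ is kept as an all-zero row and flagged —
keeping $N$ stable across stimulus levels — rather than dropped.
Similarities are $A_{ij} = \exp(-d_{ij}/\sigma)$ with zero diagonal,
where $d_{ij}$ is the Euclidean distance between profiles and $\sigma$
defaults to the mean off-diagonal distance (the "radius of influence").

A *dominant set* is a subset of points whose internal similarity beats
its similarity to the rest; it is characterized as a local maximizer of
the cohesiveness

$$F(m) = m^\top A\, m, \qquad m \in \Delta$$

over the probability simplex. The package finds it with discrete
replicator dynamics, $m_i \leftarrow m_i (Am)_i / (m^\top A m)$, which
never decreases $F$ on symmetric non-negative $A$. Numerical choices
worth stating:

* **Initialization.** The iteration starts at the barycenter with a
  deterministic relative tilt of $10^{-3}$ favouring lower indices. On
  exactly tie-symmetric matrices (two identical planted blocks, say) the
  barycenter is itself an unstable fixed point that pure-barycenter
  iteration can never leave; the tilt lets the dynamics escape while
  implementing the package's tie-break rule (lower smallest index wins)
  deterministically. Where the barycenter is the true maximizer —
  uniform similarities — the dynamics return to it.
* **Convergence.** Iteration stops when the $F$-change falls below
  $10^{-12}$ *and* the membership change below $10^{-9}$ (or at $10^4$
  iterations). The second condition prevents the saddle-escape phase,
  where $F$ barely moves but the membership drifts, from being mistaken
  for convergence.
* **Support.** Members are the indices with $m_i > 10^{-6}\max(m)$.

Clustering proceeds by peeling: extract a dominant set, remove its
members, repeat on the residual matrix. Groups are ranked by
cohesiveness (label 1 = most cohesive). The number of groups is
calibrated by a *chance level*: the extractor is run on randomized
copies of $A$ and the $(1-\alpha)$ quantile of the null cohesiveness
distribution (defaults: 1000 copies, $\alpha = 0.005$) becomes the
threshold. Note a subtlety in the randomization: applying one random
permutation jointly to the rows and columns of a symmetric matrix only
relabels the points and cannot destroy structure, so the default null
instead shuffles the upper-triangle entries and mirrors them —
preserving the similarity distribution while destroying its
arrangement. The joint row/column permutation is retained as a
diagnostic option. Per-level clustering stops peeling at the first
below-chance set (leftovers become singletons); the consensus stage
instead retains below-chance groups with a flag, matching the
convention of reporting the least coherent consensus group marked as
at-chance rather than hiding it.

## Comparing and aggregating clusterings

Two clusterings of the same $N$ species are compared with the variation
of information,

$$\mathrm{VI}(c_1, c_2) = H(c_1) + H(c_2) - 2 I(c_1, c_2)$$

in nats, a true metric on partitions bounded by $\ln N$. The $101
\times 101$ VI matrix over stimulus levels is embedded in 2-D by
classical (Torgerson) MDS — deterministic, seed-free, with the usual
rotation/reflection indeterminacy, which is why all comparisons are
made on embedded distances, never raw coordinates. The first embedding
coordinate as a function of stimulus level (`r1_vs_level()`) reads off
regime structure: plateaus of identical groupings appear as flat
stretches.

Consensus aggregation forms the co-assignment matrix $P_{ij}$ (fraction
of clusterings placing $i$ and $j$ together), zeroes its diagonal for
consistency with the similarity convention, and reuses the
dominant-sets machinery on $P$ with its own chance level. Per group,
the `representatives()` are the members with the highest converged
membership weights — the most "typical" proteins, the ones an
experimentalist would measure as proxies for their group.

## Information ranking and screens

Nine candidate readout parameters are extracted from the raw
(unnormalized) trajectories of the two output species (surface and
internalized): area under the curve (trapezoid rule), maximum
activation rate (largest forward difference on the 0.1-min grid, no
smoothing — the simplest faithful reading of "maximum rate"), its
timing (earliest grid time on ties), and the combined parameters
AUC-sum, the OR-maximum rate, and the OR-minimum timing. Each parameter
is scored by its mutual information with the stimulus level using the
Kraskov–Stögbauer–Grassberger kNN estimator, variant 1, $k = 5$,
natural log. Variant 1 is the common default of that estimator family;
a deterministic seeded jitter of scale $10^{-10}$ SD breaks ties so the
pipeline is exactly reproducible, and estimates are clipped at zero.
MI is computed on raw values (a rank-transform switch exists for
robustness checks).

The knockout screen removes one species at a time at a fixed stimulus
(default 5000 molecules/cell) and records the percent change of the
OR-maximum-rate index; a silenced network scores exactly $-100$.
Output species are excluded by default (knocking out the readout is
degenerate), and the screen knocks out exactly the named model species,
not every complex containing the protein — the single-state-variable
reading of "zeroing its concentration rate equation". The noise screen
perturbs every rate constant by multiplicative Gaussian noise (clipped
at zero to stay physical), re-simulates, re-clusters, and reports the
VI divergence from the unperturbed grouping, next to a random-label
baseline (VI between the baseline grouping and a random permutation of
its own labels) as the divergence an unstructured regrouping would
show. Defaults: noise 0–40% in 5% steps, 10 replicates per level.

## What the synthetic generators emulate — and what they do not

The package ships four generators so every stage can be validated
without any external model file:

* `make_toy_cascade()` mirrors the *architecture* of the EGFR/MAPK
  study system — ligand–receptor binding, a layered kinase cascade with
  growing substrate pools (amplification), an optional internalized
  parallel route with its own output, per-tier phosphatases,
  degradation sinks — with rate constants drawn reproducibly around
  field-typical magnitudes (binding $10^{-4}$, activation
  $2\times10^{-5}$ 1/(min·molecule), internalization 0.05/min, ...).
  It is a structural stand-in: it makes no attempt to reproduce any
  published model's quantitative behaviour, so full-model results
  (specific MI values, specific knockout lists) are out of its reach by
  design.
* `make_planted_profiles()` builds groups from six smooth templates —
  fast peak-and-decline, biphasic double peak, slow ramp,
  rise-to-plateau, fast early spike, drop-and-recover — echoing the
  archetypal dynamics reported for signalling protein groups.
* `make_known_mi_pairs()` provides samples with closed-form MI
  (bivariate Gaussian: $-\tfrac12\ln(1-\rho^2)$) for estimator
  calibration.
* `make_clustering_ensemble()` provides label ensembles with controlled
  flip noise for consensus validation.

Passing the test suite on these fixtures demonstrates that each
algorithmic component is correct and that the pipeline composes; it
does *not* demonstrate anything about a particular biological model's
parameter values. Reproducing published full-model numbers additionally
requires that model's complete rate parameterization encoded as a model
file (`inst/extdata/schoeberl2002.yaml` is the expected location for
the EGFR/MAPK case); the tier-2 acceptance tests are written against
that file and fail cleanly when it is absent.

## Problem sizes and determinism

The default study sizes are the full design: 101 clustering levels, 630
information levels, 1001 time samples, 1000 chance-level permutations.
The test suite exercises the same code paths at reduced sizes (5–12
levels, 100–200 permutations, 201–301 samples) chosen so the whole
suite runs in a few minutes on one CPU; the acceptance checks use the
full calibration sizes stated above. Every stochastic step — rate
draws, noise realizations, permutation nulls, MI jitter — flows through
an explicit integer seed, and the seeded helpers restore the caller's
RNG state, so `run_stage("all", cfg)` is reproducible end to end and
repeated runs are byte-identical.

## Known limitations

* Kinetics are restricted to mass action of order ≤ 2; Michaelis–Menten
  or Hill laws are rejected at import, not approximated.
* The SBML/CellML importers cover only the mass-action subset
  (rate-constant × reactant products, optionally reversible); documents
  encoding the model purely as ODE mathematics are rejected.
* Classical MDS gives coordinates only up to rotation/reflection;
  orientation of published maps cannot (and need not) be matched — only
  their distance structure.
* The chance-level null preserves the similarity *distribution* but not
  higher-order constraints of a Euclidean embedding; on very small or
  strongly bimodal similarity matrices the null can be conservative.
* Hard labels are reported; soft memberships are exposed per group but
  there is no out-of-sample assignment.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(out_dir = tempfile("sigorg-demo-"),
                       clustering_levels = seq(5, 5000, length.out = 21),
                       mi_levels = seq(5, 5000, length.out = 60),
                       n_perm = 200)
run_stage("all", cfg)
read.csv(file.path(cfg$out_dir, "mi_ranking.csv"))
```
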