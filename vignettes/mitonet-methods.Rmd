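---
title: "Quantifying mitochondrial network fragmentation: methods and model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial network fragmentation: methods and model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonet)
```

Mitochondria form tubular networks that continuously remodel through
fission and fusion. Many degenerative conditions shift this balance toward
fission, fragmenting the network into smaller clusters. `mitonet`
implements the two computations needed to quantify that shift: (i) a
morphometric pipeline that turns a fluorescence micrograph into a graph
and a bundle of topology metrics, and (ii) an agent-based stochastic model
of fission–fusion kinetics whose two dimensionless parameters are fitted
to the observed metrics, turning image statistics into microscopic rate
ratios.

## From micrograph to graph

The image path follows the standard morphometric recipe:

1. **Preprocessing** (`preprocess()`): legends, scale bars and
   non-mitochondrial stains are removed. Which regions to mask is explicit
   user input — published figures do not record how they were cleaned, so
   the package refuses to guess.
2. **Grayscale and binarization** (`to_grayscale()`, `otsu_threshold()`,
   `binarize()`): a global Otsu threshold over a 256-bin histogram of the
   `[0, 1]` intensity range. Otsu is deterministic and parameter-free; the
   implementation is cross-checked in the test suite against both an
   exhaustive search over all cut points and the EBImage reference. A
   constant image has no threshold and is an error.
3. **Skeletonization** (`skeletonize()`): sequential removal of simple
   pixels (ring transition count 1, neighbour count 2–7, at least one
   4-connected background neighbour) until convergence. Removing one
   simple pixel at a time — rather than whole parallel sub-iterations —
   costs a little speed but *provably* preserves the component count and
   the cycle rank of every component, which the round-trip tests require
   exactly. The classic parallel thinning schemes can erase 2×2 blocks
   outright. Directional sub-passes keep the skeleton centred. The
   operation is idempotent.
4. **Graph conversion** (`label_components()`, `skeleton_to_graph()`):
   one node per skeleton pixel, one edge per 8-adjacent pixel pair,
   *after* dropping any diagonal adjacency whose two pixels share a
   4-connected common neighbour. Raw 8-adjacency would mint a spurious
   3-cycle at every diagonal step and inflate every loop statistic.
   8-connectivity is used throughout; 4-connectivity shatters thinned
   diagonals into fragments.

Pixel-as-node is a deliberate choice over a junction-only graph: observed
mean degrees of mitochondrial networks sit in the 1.4–1.8 range, which is
only attainable when degree-2 chain nodes are first-class citizens.

## Network statistics

`network_stats()` bundles: edge count $N$, mean degree
$\langle k\rangle = 2E/V$ over all nodes (isolated nodes included),
cluster count (components with at least one edge), average cluster size
$N/\mathrm{clusters}$, giant cluster $N_g$ (the component with the most
edges) and its fraction $N_g/N$, plus three size distributions measured in
unit edges:

* **loops** (`loop_sizes()`) — cycles with no open ends. Degree-2 chains
  are collapsed into weighted super-edges and a *minimum-weight cycle
  basis* is computed per component (Horton candidate cycles, greedy
  selection under GF(2) independence). The number of loops then equals the
  cycle rank $E - V + C$ exactly, and nested cycles resolve to the
  smallest independent set — the natural reading for sparse, mostly
  tree-like clusters, since no convention for nested loops is established
  in the field. The basis computation is exact but grows with the cycle
  rank of a component; densely looped giant clusters (far beyond the
  physiological regime) get expensive.
* **branches** (`branch_lengths()`) — maximal degree-2 chains with at
  least one degree-1 terminal. An isolated path is one branch; isolated
  cycles contribute none. Branch and loop edge sets are disjoint by
  construction.
* **clusters** (`cluster_size_distribution()`) — per-component edge
  counts with a cumulative probability over clusters (not edge-weighted).

All statistics are computed on the same multigraph type whether the
network came from an image or from the simulator, so the two halves of the
package are directly comparable.

## The fission–fusion model

The model tracks $N$ identical unit edges ("minimal segments"); each edge
has two tips, and tips merge into nodes of degree 1, 2 or 3 ($X_1, X_2,
X_3$ — degree-4 junctions are rare in real mitochondrial networks and are
excluded by construction). Two reversible reactions act on the tips:

$$X_1 + X_1 \underset{b_1}{\overset{a_1}{\rightleftharpoons}} X_2
\qquad\qquad
X_1 + X_2 \underset{b_2}{\overset{a_2}{\rightleftharpoons}} X_3$$

tip-to-tip (longitudinal) and tip-to-side (lateral) fusion with their
fissions. Fission rates are fixed at $b_1 = 0.01$ and $b_2 = 3b_1/2$; the
fitted quantities are the dimensionless ratios $C_1 = a_1/b_1$ and
$C_2 = a_2/b_2$. The simulation is an exact Gillespie process
(`ff_run()`, compiled core): exponential waiting times from the total
propensity, reaction chosen proportionally, reactants uniform among
eligible nodes. The model is well-mixed — there is no spatial structure —
so two tips of the same edge may legitimately fuse into a one-edge loop,
and parallel edges between node pairs occur. Runs start from the fully
fissioned state ($X_1 = 2N$) and execute $5N$ reaction events, which the
test suite verifies is stationary by comparing against $10N$-event runs.
`ff_ensemble()` repeats runs with per-run seeds derived from one master
seed, so every published number is bit-reproducible.

Invariants asserted throughout: $X_1 + 2X_2 + 3X_3 = 2N$ after every
event, no node above degree 3, realized graph always has exactly $N$
edges.

### Propensity conventions and the calibration

The mass-action propensities are
$s_{tt}\, a_1 X_1 (X_1 - 1)/2$, $b_1 X_2$, $s_{ts}\, a_2 X_1 X_2$ and
$b_2 X_3$, where $(s_{tt}, s_{ts})$ is a *convention multiplier*
(`ff_convention()`). This knob exists because the reference
implementation of this model family is unpublished and the published
steady-state tables it produced are not mutually consistent under any
single textbook convention: the condition printed with $N = 103$ cannot
reach a mean degree of 1.75 under any count-based mass action at the
printed ratios (quadratic fusion propensities are simply too small at
small counts), and the printed species fractions imply a different mean
degree than the printed mean-degree column. Rather than silently forcing
agreement, `scripts/calibration.R` scores every candidate convention
against all eighteen published condition rows (mean degree and
$N_g/N$), writes the full per-row report to
`inst/extdata/calibration_report.csv`, and the winner — `"ordered"`,
$(2, 1)$, i.e. ordered-pair counting of the tip-to-tip channel — ships as
the default. With it, nine of the eighteen rows reproduce within 0.06
absolute in $\langle k\rangle$ and 40% relative in $N_g/N$; the report
documents the rest, row by row, for every convention.

### The mean-field oracle

`ff_meanfield()` solves the deterministic fixed point: each reversible
channel balances separately, giving
$X_2 = s_{tt}(C_1/2) X_1 (X_1 - 1)$ and $X_3 = s_{ts} C_2 X_1 X_2$ under
tip conservation. The reduced cubic in $X_1$ has exactly one root in
$[1, 2N]$, found by bracketed root-finding (no polynomial solvers, no
complex roots); the conservation residual is held below $10^{-9} \cdot
2N$. The oracle mirrors whatever convention the simulator uses, so
simulator and oracle always test the same model. Ensemble means at
$N = 2000$ match the fixed point within Monte-Carlo error (three standard
errors over 200 runs) — the module's reason to exist.

```{r meanfield}
ff_meanfield(C1 = 4.9e-4, C2 = 4.4e-5, N = 2664)
```

## Phase-space fitting

`phase_scan()` simulates ensembles over a log-spaced grid — by default
$C_1 \in [10^{-5}, 5\times10^{-3}]$, $C_2 \in [10^{-6}, 5\times10^{-4}]$,
covering every published value with uniform relative resolution — and
`phase_fit()` maps an observed $(\langle k\rangle, N_g/N)$ pair to the
cell minimizing the relative misfit

$$\left(\frac{k_{sim}-k_{obs}}{k_{obs}}\right)^2 +
  \left(\frac{g_{sim}-g_{obs}}{g_{obs}}\right)^2 .$$

Relative errors keep the small giant-cluster fractions from being swamped
by the mean degree; ties break toward smaller ratios, lexicographically,
so fits are deterministic. Observations outside the scanned range by more
than three standard errors in *both* metrics are refused rather than
extrapolated. `phase_refine()` re-scans one grid step around the best
cell, so resolution is paid for only where it matters. Cells are seeded
from the scan key, making scans order-independent, reproducible and
resumable from a cache directory. The fitting procedure is validated by
parameter recovery — simulate at known ratios, fit the summary statistics
back — which lands within one grid step in 20 of 20 seeded conditions at
100 repetitions per cell (at lighter, 60-repetition smoke scans the rate
drops to ~85–95% because $C_2$ is weakly identified where the giant
fraction is small and flat).

`compare_conditions()` emits the normal/diseased ratio table
($C_{1n}/C_{1d}$, $C_{2n}/C_{2d}$, steady-state $X_{1,2,3}$ fractions and
their ratios), and `distribution_report()` the loop/branch/cluster means
with standard errors and the difference of means.

## Synthetic micrographs

No micrographs are redistributable, so `make_toy_graph()` +
`render_graph_to_image()` generate the test inputs: disjoint unions of
paths, cycles, stars, thetas and isolated edges, rasterized as
8-connected one-pixel strokes, dilated to the requested stroke width,
with optional Gaussian noise, blur, legend boxes and a second
fluorescence channel (`add_artifacts()`). One toy edge maps to a fixed
pixel length (`edge_px`, default 8 px, even), so loop and branch sizes
measured on the rendering divide back to toy units deterministically
(`pixels_to_edges()`, rounding absorbs the ±2 px that corners and
junction re-centring introduce).

Layout is collision-free by construction: components sit on a jittered
shelf grid with separation `stroke_width + 4`, and each kind has an exact
axis-aligned router. Geometry imposes honest limits, reported as errors
naming the offending component rather than silently distorted drawings: a
raster star can host at most 4 arms at a single junction pixel (adjacent
compass directions merge), so 5–8 arms render on a short junction bar —
this preserves branch and loop statistics though not the single central
node — and more than 8 arms is an error; a cycle whose perimeter cannot
keep a hole at the requested stroke width is an error; theta components
are drawn as a straight chain plus two rectangular arcs, which requires
the two shortest chains to differ, so theta edge budgets are split
unevenly whenever possible (6 → 1+2+3) and the 3- and 4-edge thetas are
unrenderable. Simulated networks take a seeded force-directed layout
whose rendering is verified by re-extraction and retried on collision
(intended for stroke width 1–2).

What passing round-trip tests show — and what they do not: clean
renderings prove the binarize–skeletonize–graph chain recovers component
counts, cycle ranks, loop sizes and branch lengths *exactly*. Real
micrographs add out-of-focus light, intensity gradients, touching
filaments and anisotropic PSFs that this generator deliberately does not
model (no photorealism, no 3-D stacks); on such data the pipeline
inherits the usual limits of global thresholding.

## Problem sizes and numerical choices

The test suite runs the model at the study's own scales: conservation
checks per event; oracle agreement at $N = 2000$, 200 repetitions;
monotonicity of $\langle k\rangle$ and $N_g/N$ in both ratios on a 6×6
grid at $N = 500$, 20 repetitions (as a statistical claim: no decrease
beyond 3 SE anywhere and at least 95% of the 110 consecutive-pair
comparisons within 2 SE — a handful of 2-SE fluctuations among 110
comparisons is expected by chance); 25 rendering round-trips; parameter
recovery over 20 conditions at 100 repetitions; and direct re-simulation
of the published condition rows at their printed $(C_1, C_2, N)$ with 100
runs of $5N$ events. The published-row checks encode the calibration
caveat above: each row must either reproduce within the stated bands or
be documented per convention in the committed calibration report, and at
least six rows must genuinely reproduce.

Known limitations, beyond those already noted: the loop-size basis is
exact but super-linear in cycle rank; the renderer's generic (simulated
network) layout is best-effort with retries; and the model has no spatial
embedding, mass change (mitophagy/biogenesis), or degree-4 junctions, so
parameters fitted through it describe a well-mixed approximation of the
cell.
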