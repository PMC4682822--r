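---
title: "Wiring-economy placement: models, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wiring-economy placement: models, solvers and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wireopt)
```

## The model

A spatial neural network is a weighted graph whose nodes carry 2D
coordinates (mm; axis 1 anterior→posterior, axis 2 ventral→dorsal —
positions are cell-body projections onto the body plane). Chemical
connections are directed and carry synapse counts; electrical
connections (gap junctions) are symmetric and carry junction counts.
The total wiring length of a layout `X` under a link-weight matrix `A`
and cost function `d` is

$$\mathrm{TWL}(X) = \sum_{i,j} A_{ij}\, d(x_i, x_j),$$

summed over ordered pairs. Because cell-body distance is a proxy for
wire length (synapses form *en passant* along neurites), the cost is a
function of straight-line separation only: the l1 norm, the Euclidean
norm, or its square, cube or fourth power. Only the Euclidean norm and
l1 are metrics; the powered variants are convex cost surrogates that
penalize long wires progressively harder.

The optimization fixes motor and sensory neurons at their observed
positions — their placement is plausibly dictated by the muscles and
sensory organs they serve — and treats interneuron positions as free
variables. All costs considered are convex in the free coordinates, so
the unconstrained anchored problem has a global optimum.

### Weighting schemes

Four conventions turn connectivity into `A` (see `weight_scheme()`):
unit weight per connection (`unit_joint`, the default:
`A = A_ch + 0.5 A_el` on indicators, entries in {0, 0.5, 1, 1.5}),
synapse/gap-junction counts (`synapse_counts`), a type- and
multiplicity-blind indicator (`binary_union`), and type-specific scales
(`scaled`). The factor 0.5 on the electrical matrix compensates for
each electrical connection appearing twice in a symmetric matrix, so
every connection contributes exactly once to the ordered-pair sum.
Whether that halving should survive the switch from indicators to
counts is genuinely underdetermined; we retain it (counts mode uses
`A = nsyn + 0.5 ngap`) so that the two modes differ only in
multiplicity, and expose it as `elec_factor` for users who prefer
ngap to count per directed link.

## Solvers

Each convex class gets the standard method for it, all behind
`solve_placement()`:

* **Squared Euclidean** (`solve_squared_l2`): the objective is a
  quadratic form in the free coordinates; stationarity gives the
  anchored graph-Laplacian system
  \(x_i \sum_j u_{ij} = \sum_j u_{ij} x_j\) with \(u = A + A^T\),
  solved exactly as one sparse linear system per coordinate
  (Matrix package). This is also the warm start for every other solver.
* **Euclidean / Weber** (`solve_weber_l2`): iteratively reweighted
  least squares on the smoothed cost \(\sqrt{d^2+\varepsilon^2}\) (the
  multifacility form of Weiszfeld's method). The smoothing
  \(\varepsilon\) starts at `1e-3` of problem scale and is divided by
  100 whenever the smoothed objective stalls (relative change below
  `1e-10`), down to a floor of `1e-12` of scale. The iteration cap
  (`1e4`) returns the best layout with `converged = FALSE` rather than
  failing.
* **l1** (`solve_l1`): the cost separates by axis into 1D weighted
  absolute-deviation problems. A single free node is solved exactly by
  the weighted median; multi-node axes run the same IRLS machinery in
  1D (smoothing floor `1e-8` of scale) followed by weighted-median
  coordinate-descent polish, which lands on a vertex of the piecewise
  linear objective. When a median is an interval, its midpoint is
  returned, for determinism.
* **Cubed / fourth power** (`solve_power_p`): smooth convex
  minimization by L-BFGS-B with analytic gradients, warm-started from
  the quadratic solution; the stopping rule is a gradient infinity
  norm below `1e-10 ×` scale `×` total weight, with a handful of
  restarts. Routing p = 2 through this path reproduces the exact
  linear solve to 1e-8, which the tests assert.

**Degeneracies.** A free neuron with no connections has no preferred
position: it keeps its input coordinates and is reported in
`diagnostics$isolated` rather than failing the solve. A free component
with connections but no weighted path to any anchor has an undefined
optimum and is an error naming the component (`placement_problem()`
already warns at construction). Non-unique optima (collinear Weber
instances, median intervals) are resolved arbitrarily except for the
l1 midpoint rule; tests compare objectives, never coordinates, in
degenerate cases.

**Minimal inter-neuron distance** (`solve_with_min_distance`): somata
have finite size, so one may require every pair involving a free
neuron to be at least δ apart. The constraint is non-convex; we refine
the convex optimum by quadratic-penalty iterations (penalty weight
escalating ×10 until all constraints hold to `1e-9 δ`), with an
optional bounding-box clamp. Exactly coincident violating pairs have a
zero penalty gradient and are deterministically nudged apart first. If
the warm start already satisfies the constraint it is returned
unchanged. With `min_distance = "auto"` in `run_scenario()`, δ is the
smallest pairwise distance of the real layout — a data-derived choice,
since any fixed literal is dataset-specific. A body-outline
containment constraint is deliberately not part of the default
problem: optimal positions fall inside the anchor hull in practice,
and the clamp is available in the refinement for the rare cases where
the penalty pushes a node outside.

## Null models and comparison statistics

`random_baseline()` draws free positions i.i.d. uniform over the body
region and recomputes the TWL per draw. The body outline is not part
of the input data, so the region is reconstructed from the positions
themselves: the bounding box of all real positions (default) or their
convex hull (`region = "hull"`, rejection sampling); the choice is
recorded in the result. The draws, their mean and sd, and the seed are
returned; bit-exact reproducibility given the seed is tested.

`run_scenario()` assembles the comparison: real TWL, optimal TWL,
optionally the random mean, and the derived identities
(`comparison_stats()`): absolute reduction `twl_real − twl_opt`,
relative reduction in percent of the real TWL, and the percent by
which the real TWL sits below the random mean (plus the converse,
percent of random above real). Displacements between real and optimal
positions are always summarized in plain Euclidean mm, whatever cost
was optimized — powered-cost averages carry units of mm^p and shrink
mechanically as p grows (distances below 1 mm raised to higher powers),
so comparing them across costs misleads; the cost-consistent average is
additionally reported as `mean_displacement_spec`. Mean displacement is
also expressed as a percentage of body length, taken as the
anterior–posterior span of the anchored neurons since no explicit body
length is part of the inputs.

Outlier detection (`detect_outliers`) is gap-based: sort the free
neurons' displacements, find the largest gap between consecutive
values, and flag everything above it if the gap exceeds 0.2 mm. A
fixed displacement cutoff would encode one dataset's empty band
(0.3–0.7 mm in the real connectome); the gap criterion finds such a
band wherever it lies. Re-anchoring the flagged neurons and re-solving
(`run_scenario(extra_fixed = ...)`) quantifies their contribution to
the real-vs-optimal difference; anchoring can only raise the optimal
objective, a monotonicity the tests verify.

## The synthetic generator

`generate_instance(synth_config(...))` emulates the statistical
structure the analysis assumes, so every stage is testable offline:

* **Geometry**: a 1.16 × 0.08 mm body rectangle (the scale of an adult
  hermaphrodite projected to 2D), with anchor clusters in the head
  (x < 0.15 L) and tail (x > 0.85 L) and a sparse ventral-cord line of
  anchors between them; free interneurons anywhere. Defaults of
  80 + 60 + 60 anchors and 80 free neurons mirror the real
  193-anchored / 86-free partition at comparable size.
* **Wiring**: each ordered pair is wired chemically with probability
  `chem_fraction · exp(−d/λ)` and each unordered pair electrically
  with probability `(1−chem_fraction) · exp(−d/λ)`. Defaults
  `chem_fraction = 0.75` (chemical connections dominate real
  connectomes by roughly that ratio) and `λ = 0.2 mm` (connectivity is
  strongly local: dense within a cluster, sparse across the body).
* **Multiplicities**: shifted-geometric with mean `count_mean = 2` — a
  low-variance choice reflecting the fairly even spread of synapse
  counts over connections, which is also why count-weighted optima
  barely differ from unit-weighted ones; the variance regime is
  configurable through `count_mean`.

Everything derives from `cfg$seed` via a scoped RNG
(`withr::with_seed`), so instances are bit-reproducible and the global
RNG state is untouched.

Because wiring probability decays with distance in the generating
process, the generated ("real") layout is automatically economical
relative to a random relocation of its interneurons — the
optimal ≤ real ≤ random-mean ordering emerges rather than being
imposed. What the generator does **not** emulate: the real degree
distribution and its hubs, left/right neuron pairing and body
symmetry, the correlation between connection multiplicity and
distance, and 3D structure. Consequently the synthetic relative
reductions (roughly 5–10% under the defaults) are smaller than the
~35% seen on the real connectome, where many tail interneurons are
wired almost exclusively to the head; passing tests demonstrate solver
correctness and pipeline invariants, not that any particular real
reduction value is recovered.

`plant_sq_l2_optimum()` builds parameter-recovery instances: it
replaces the free positions with the exact solution of the quadratic
stationarity system, so the planted layout *is* the squared-cost
optimum and a downstream solve must recover it (the suite checks
max error ≤ 1e-6 mm over 50 random instances — in practice the sparse
solve reproduces it to machine precision). Planting is specific to the
squared cost; under any other cost the planted layout is merely
feasible and the reduction is nonnegative.

## Numerical conventions and test scale

Accumulation order in `total_wiring_length()` is fixed, so repeated
evaluations are bit-identical. Anchored rows of a solution are
bit-identical to their inputs, and the reported objective is
recomputed from the final layout (asserted to 1e-9 relative). Solver
tolerances and caps quoted above are all arguments with those
defaults.

Grid-search oracles in the test suite are multi-resolution exhaustive
searches (full 2k-dimensional grids for up to two free nodes, cyclic
per-node grids beyond), agreeing with the solvers to 1e-3 — a check of
the solvers by an independent method, not of the grid by the solvers.
The Monte-Carlo baseline is calibrated against 2D numerical
integration of the mean distance from a uniform point of the unit
square to its corner (within 3 standard errors at 1e5 draws). Unit
tests run on instances of roughly 40–280 neurons with 5–30 free; the
invariant suite uses a 125-neuron instance with 1000 null draws and
the planted-recovery sweep uses fifty 38-neuron instances — sizes
chosen so the full suite completes in a few minutes on a laptop while
still exercising every code path at connectome-like shape.

## Limitations

Straight-line cell-body distance is the entire cost model: no neurite
routing, no geodesic or along-body distances, no account of synapse
count per wire beyond the weighting schemes. The 2D projection means
the minimal-distance constraint is physically optional (distinct cells
can legitimately coincide in projection). Functional classification of
neurons is taken at face value; displacement outliers are flagged
geometrically, and any interpretation of *why* an interneuron resists
its optimal position (e.g. an unrecognized sensory role) is outside
the package's scope.
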