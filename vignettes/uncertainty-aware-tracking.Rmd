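---
title: "Model-driven, uncertainty-aware cell tracking: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-driven, uncertainty-aware cell tracking: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uatrack)
```

# The problem

Microfluidic live-cell imaging records 2D monolayer microcolonies of
rod-shaped bacteria over many generations. Turning per-frame segmentations
into cell lineage trees (CLTs) — bifurcated forests whose nodes are cell
detections and whose edges are frame-to-frame identities, with a 2-child node
marking a division — requires linking detections across frames. At short
imaging intervals this is nearly trivial; at "bio-safe" frame rates, chosen
to limit phototoxicity, cells move, grow and divide appreciably between
frames and naive nearest-neighbour linking collapses. `uatrack` addresses
this with three ingredients: explicit statistical models of cell behaviour,
exact combinatorial selection of frame-to-frame assignments, and a particle
filter that keeps a distribution over whole-lineage hypotheses.

# Assignment models

Between frame $t$ and $t+1$, four assignment types exist: appearance (0
sources, 1 target), disappearance (1, 0), migration (1, 1) and division
(1, 2). Appearance and disappearance absorb cells crossing the field-of-view
boundary and segmentation artifacts; they carry constant log-penalties
$\lambda_{\mathrm{appear}} = \lambda_{\mathrm{disappear}} = -20$ by default,
chosen to be clearly worse than any plausible migration score so that linking
wins whenever it is credible.

Migration and division candidates are scored by a joint log-likelihood built
as the *sum* of univariate log-densities. Independence of the factors is the
modelling assumption: each univariate model captures one observable, and the
composition is deliberately modular so configurations can switch models on
and off. The factors are:

* **Position.** Half-normal density on
  $\lVert \mathbf{x}_{\mathrm{obs}} - \hat{\mathbf{x}} \rVert$ with scale
  $\sigma_{\mathrm{move}} \sqrt{\Delta t}$. The $\sqrt{\Delta t}$ scaling
  treats undirected cell jostling as diffusive; it is the standard physical
  choice when the literature only states that parameters are "adjusted to
  the interval", and it is configurable.
* **Area.** Normal density on the ratio $a_{\mathrm{obs}} / \hat{a}$ around 1
  with scale $\sigma_{\mathrm{area}}$ (relative, hence dimensionless). For
  divisions the two daughter areas are summed first.
* **Orientation (O).** Orientations are *axial* — a segmented rod has no
  head or tail — so every angle difference is the minimal axial difference in
  $[0, \pi/2]$ and a 180° flip costs nothing. For migrations the rotation
  angle is scored around 0; for divisions the inter-daughter angle is scored
  around $\mu_{\mathrm{div}}$ (default 0, aligned "snapping" daughters).
* **Division distance (DD).** Half-normal on the daughter centre-to-centre
  distance, scale $\sigma_{\mathrm{div}} = 8$ px: daughters of a genuine
  division are empirically adjacent.
* **Growth (G).** Normal on the raw growth factor
  $a_{\mathrm{obs}} / a_{\mathrm{src}}$ around the colony-level mean
  $e^{\mu \Delta t}$. The colony rate $\mu$ needs segmentation only: it is
  the OLS slope of log total area against physical time
  (`estimate_colony_growth_rate()`), so the G model injects population-level
  knowledge without requiring tracked history.

Scores of different dimensions are mixed in one sum; they are comparable
only within one frame pair, which is all the optimiser needs. No
normalisation across assignment types is attempted beyond the $\lambda$
penalties.

## Prediction: NN vs FO

The baseline NN configuration predicts zero motion and zero growth
($\hat{\mathbf{x}} = \mathbf{x}$, $\hat a = a$). The first-order (FO) model
is *self-learning*: each cell's velocity
$\mathbf{v} = (\mathbf{x}_t - \mathbf{x}_{\mathrm{parent}})/\Delta t$ and
growth factor $g = a_t / a_{\mathrm{parent}}$ are read off its own lineage
history within the current hypothesis, and the prediction is
$\hat{\mathbf{x}} = \mathbf{x} + \mathbf{v}\Delta t$, $\hat a = a \cdot g$.
Two design choices matter here:

* **Daughters reference half the mother's area.** A division halves area; if
  the growth feature naively used $a_{\mathrm{parent}}$, every newborn would
  appear to have shrunk 2-fold and FO's area prediction would be wrong for a
  frame. The growth factor of a division daughter therefore uses
  $a_{\mathrm{parent}}/2$ as the reference. The factor is clipped to
  $[0.5, 4]$ to contain segmentation artifacts.
* **Roots use colony priors.** A cell without history gets
  $\mathbf{v} = (0,0)$ and $g = e^{\mu \Delta t}$ — the colony-level prior is
  the only information available.
* **Newborn velocity includes the division offset.** A daughter's velocity is
  computed from its own parent edge like any other cell's, so it includes the
  ±(division distance)/2 placement offset (~4 px by default). This is a
  deliberate simplification; its consequence is that first-order position
  residuals of a few px are *normal* in the frame after a division, and
  $\sigma_{\mathrm{move}}$ should not be set far below the division offset
  even in low-noise data.

The six named configurations are `NN`, `FO`, `FO+O`, `FO+G`, `FO+DD` and the
composite `FO+G+O+DD` (`make_config()`).

# Exact frame-to-frame selection

Candidates are filtered before scoring: migrations for targets within radius
$r_{\max} = 40\sqrt{\Delta t}$ px of the source, divisions for target pairs
both within $r_{\max}$ and mutually closer than $d_{\mathrm{div,max}}$
(default $r_{\max}$), plus one appearance per target and one disappearance
per source — the unary candidates guarantee that a feasible cover always
exists.

Selection is the canonical exact-cover integer program: one binary variable
per candidate, one equality constraint per source and per target, objective
the summed log-scores. No MILP library is required: `solve_optimal()` is an
exact depth-first branch and bound with an admissible bound (per remaining
source, its best candidate score; per uncovered target,
$\max(\lambda_{\mathrm{appear}}, 0)$), written in C++. Two refinements keep
worst cases bounded:

* **Dominance pruning.** A migration or division scoring strictly worse than
  replacing it with disappear + appear(s) can never be part of an optimal
  cover (the replacement is always feasible and strictly better), so such
  candidates are dropped up front. This is exact for the optimum *including*
  tie-breaking (only strict domination prunes). It is also what makes the
  collapse regime cheap: when a model family stops explaining the data —
  e.g. NN at long intervals, where every area ratio is far from 1 — most
  candidates become dominated and the problem shrinks to the unary ones.
* **Node cap.** A deterministic cap (5×10⁶ expansions, configurable) bounds
  pathological flat-score instances; hitting it raises a warning and returns
  the best cover found. All acceptance-scale instances solve exactly.

Ties are broken toward fewer appear+disappear events, then toward the
lexicographically smallest candidate set, making results fully
deterministic. `k_best_covers()` re-solves with exclusion constraints
forbidding each previously returned cover; consequently only
non-strictly-dominated covers are enumerable, which is also the sensible
hypothesis set to sample from. `enumerate_bruteforce()` (guarded to 8×8) is
an independent recursive enumeration used as the test oracle.

# The particle filter

A particle is one CLT hypothesis with a cumulative log-weight (the exact sum
of all selected assignment scores since frame 0 — a bookkeeping invariant
the tests check). `run_tracking()` initialises N particles as singleton-root
forests on frame 0 and then, per frame pair and per particle: harvests
history features *from that particle's own forest* (each hypothesis learns
from its own past), generates and scores candidates, computes the k best
covers, and samples one with probability $\propto e^{s - s_{\max}}$ (softmax
at temperature 1 — the minimal faithful choice for "sampling from the most
likely extensions"; k is exposed). The offspring population is resampled
systematically using the per-step score increments, which makes resampling
weights uniform afterwards, while cumulative weights are kept for the MAP
estimate. The pre-resampling maximum-cumulative-weight particle is stored
aside so resampling can never discard the MAP hypothesis; ties resolve to
the lowest particle index.

With `n_particles = 1, k = 1` the filter degenerates exactly to greedy
per-frame-pair optimal assignment (no RNG is consumed), a property the
acceptance tests verify against independent chaining of `solve_optimal()`.
`edge_marginals()` reports, per lineage edge, the fraction of particles
containing it — the edge-level readout of tracking uncertainty.

# The colony simulator

`simulate_colony()` is the package's stated world: a single founder cell;
per base step (default 1 min) each cell multiplies its area by
$e^{(\mu + \varepsilon)\Delta t}$ with $\varepsilon \sim N(0, 0.02)$,
random-walks with scale $1.5\sqrt{\Delta t}$ px, and diffuses its axial
orientation ($0.05\sqrt{\Delta t}$ rad). A cell divides on exceeding its
personal log-normally jittered area threshold (200 px², log-sd 0.1): two
equal daughters are placed $\pm 4$ px along the mother axis and their axes
rotate away by $\pm N(0.15, 0.15)$ rad, giving a mean inter-daughter
"snapping" angle of 0.3 rad. Optional detection dropout truncates
ground-truth tracks exactly as segmentation misses do.

The defaults are a desk-scale compression of a multi-hour experiment: a
colony rate of 0.05/min over 60 frames yields ~300 detections and ~13
divisions in under a second, while preserving what makes tracking hard — the
ratio of per-interval displacement and growth to cell spacing and division
frequency. At factor 1 tracking is near-trivial and by factors 16–25 the
nearest-neighbour baseline collapses, qualitatively mirroring real
low-frame-rate behaviour. The simulator deliberately omits cell-cell
mechanics (no pushing; crowding is approximated by the random walk), mask
rendering, and fluorescence — the scorers only consume point features, so a
green test establishes correctness of the tracking machinery on colonies
with realistic *statistics*, not robustness to segmentation noise or
contact-driven motion of real images.

`subsample_dataset()` keeps every f-th frame, renumbers frames, scales
$\Delta t$, and composes ground-truth edges across the gap. A cell with two
surviving descendants becomes a composed division. With more than two (two
or more divisions inside one gap) the truth is not representable as a
bifurcation: the convention here is that the gap division closest to the
later kept frame defines the daughter pair and the remaining descendants
become appearances, counted in the dataset's `unresolved` field.

## Degenerate symmetric worlds

With *all* noise terms zero the simulator becomes perfectly symmetric:
divisions synchronise, the deterministic $\pm$ mean division rotations
commute, and cousin cells can coincide in area and orientation at sub-pixel
separations. On such coincident pairs the optimal cover is genuinely
ambiguous (and, because newborn velocities carry the division offset, can
strictly favour the swapped pairing), so exact ground-truth recovery is a
property of zero-noise colonies *without* such collisions. The canonical
zero-noise fixture used in the tests (40 frames, 3 divisions) has none; the
multi-hypothesis filter run on longer symmetric worlds correctly *spreads*
its particles over the coinciding alternatives instead of pretending
certainty — which is the point of the paradigm.

# Metrics

`division_f1()` matches predicted against reference divisions greedily by
frame distance within a tolerance (default 0; with identity detection
correspondence a 0-tolerance match is the same dividing detection).
`lnk_score()` is an AOGM-style edge-operation cost: with weights
$w_{EA} = 1.5$ (reference edge missing), $w_{ED} = 1$ (spurious predicted
edge), $w_{EC} = 1$ (shared edge with mismatched migration/division
semantics),

$$\mathrm{LNK} = 1 - \frac{\min(\mathrm{cost}(\mathrm{pred}),\,
\mathrm{cost}(\varnothing))}{\mathrm{cost}(\varnothing)},
\qquad \mathrm{cost}(\varnothing) = w_{EA}\,\lvert E_{\mathrm{ref}}\rvert.$$

The weights follow the published edge-weight convention of the Cell Tracking
Challenge ecosystem and are configurable, since external implementations may
differ in constants. Both metrics depend only on edge sets, never on track
labels.

# Numerical and interface choices

* Frames always index the *processed* series; the physical interval
  $\Delta t$ is a model parameter. Coordinates are 0-based pixel centres,
  x = column, y = row.
* Scores use log-densities throughout; covers are selected on raw log-score
  sums (no exponentiation in the objective); softmax weights are shifted by
  the maximum before exponentiation.
* Floating-point ties in the optimiser use a 1e-9 margin; determinism under
  a fixed seed is bitwise (the CLI round-trips are compared by checksum in
  the tests).
* Detection CSVs serialise floats with 12 significant digits; CTC track
  files use the `L B E P` dialect with labels assigned in (begin frame,
  root id) order. Because detections are points, not masks, fixtures carry a
  `ctc_label` column pairing detections with tracks — without it a CTC file
  alone cannot reconstruct edges.
* Divisions into more than two daughters within one interval are not
  modelled (candidates are capped at two targets); merging (2→1) and
  frame-skipping assignments are out of scope.

# Known limitations

* The particle filter's sampling distribution (softmax over k-best) and
  per-step systematic resampling are one concrete choice within the
  multi-hypothesis paradigm; both are exposed as parameters rather than
  claimed optimal.
* Features are computed per particle, never averaged across the posterior.
* The simulator's lack of contact mechanics means spatial crowding is
  understated at high density; conclusions about *relative* model quality
  (e.g. the composite configuration dominating NN under sub-sampling) are
  the intended read-out, not absolute scores.
* The branch-and-bound node cap makes worst-case runtime bounded at the cost
  of a (warned, deterministic) possibly suboptimal cover on adversarial
  flat-score instances; no acceptance-scale workload hits it except the NN
  configuration deep in its collapse regime.
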