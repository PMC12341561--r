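---
title: "deltadyn: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{deltadyn: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(deltadyn)
```

This vignette is the package's own account of the science it
implements: the composite model, the training protocol, the trajectory
machinery, and every place where a numerical or design decision had to
be made.

## The composite energy model

The deployed potential is a three-term sum

$$E = E_\mathrm{baseline} + E_\mathrm{NN} + E_\mathrm{disp},$$

and all derivative properties are sums of the terms' derivatives.  The
baseline is a pluggable calculator contract (`eval_structure()`):
anything that returns an energy and an analytical gradient — and
optionally partial charges and a dipole, which the composite result
inherits unchanged — can stand in.  The package ships analytic
surrogates (a pairwise Morse form, `morse_baseline()`, deliberately
dispersion-free like a tight-binding baseline with its dispersion term
removed, and a harmonic `spring_model()`); production semi-empirical
backends would implement the same contract.  The dispersion term is a
damped pairwise $-C_6/r^6$ sum with rational damping
$E = -\sum_{i<j} C_6^{ij}/(r_{ij}^6 + r_{0,ij}^6)$, smooth everywhere
and asymptotically exact, with geometric-mean $C_6$ and arithmetic-mean
$r_0$ combination rules.

The NN term is an ensemble (default 8 members) of per-element
feed-forward networks over atomic environment vectors (AEVs).  A member's
molecular energy is the sum of atomic network outputs plus per-element
self-energy offsets; the reported correction is the member mean, and the
member *population* standard deviation, converted to kcal/mol, is the
uncertainty.  A prediction is flagged unreliable above a threshold of
0.36 kcal/mol by default.  Three conventions deserve a note:

* **Population vs sample standard deviation.**  The uncertainty uses the
  population convention (`ddof = 0`), the convention documented for the
  predecessor methods of this family; it is what `ensemble_uncertainty()`
  implements and tests assert (two members 1 kcal/mol apart give 0.5).
* **Total-energy threshold.**  The reliability threshold is applied to
  the uncertainty of the *total* energy, not a per-atom-normalised one;
  the choice is configurable via the `threshold` argument.
* **Reaction energies.**  For relative energies the per-member relative
  energy is formed *first* (member alignment matters — member $m$ of
  every species must come from the same trained model), then the spread
  is taken across members (`relative_energy_uncertainty()`).

## Descriptors and their exact derivatives

The AEV follows the familiar radial/angular symmetry-function layout:
radial shells $\sum_j e^{-\eta_R (R_{ij}-R_s)^2} f_C(R_{ij})$ grouped by
neighbour element and angular terms
$2^{1-\zeta}\sum_{j<k}(1+\cos(\theta_{ijk}-\theta_s))^\zeta
e^{-\eta_A(\bar R-R_s^A)^2} f_C(R_{ij}) f_C(R_{ik})$ grouped by
unordered element pair, with the smooth cosine cutoff
$f_C = \tfrac12\cos(\pi r/R_c)+\tfrac12$.  Defaults follow the standard
grid (16 radial shifts to 5.2 Å, 8 angular shifts × 4 radial shifts),
**except that the angular cutoff is 4.0 Å** rather than the customary
3.5 Å, for a better description of longer-range neighbour shells.  The
angular shift grid itself is left unchanged (0.90–2.85 Å); nothing in
the method description requires moving it with the cutoff, and the grid
remains fully configurable.

Angular sums iterate unordered pairs $j<k$ with the $2^{1-\zeta}$
prefactor, which fixes the double-counting ambiguity of the angular
term.  Two numerical choices:

* the angle is evaluated as $\theta = \arccos(0.95\,\cos\theta)$ — the
  customary regularisation of this descriptor family — so that first
  and second derivatives stay finite at collinear geometries;
* neighbour lists are recomputed on every call; systems here are small
  and correctness wins over caching.

First derivatives (`aev_jacobian()`) and second derivatives are fully
analytical.  The second-derivative path never materialises the rank-3
descriptor Hessian: the network Hessian needs only
$\sum_{a,d} W_{ad}\,\nabla^2 G_{ad}$ for a weight matrix $W$ given by
the network input-gradients, so `aev_weighted_hessian()` accumulates
the contraction directly, term by term, from closed-form second
derivatives of $(r_1, r_2, \cos\theta)$.

## The network term: GELU and analytical Hessians

Hidden layers use the exact GELU activation $x\,\Phi(x)$ (chosen for
its smooth higher-order derivatives, which matter when the network must
deliver Hessians), with closed-form first and second derivatives
($\Phi + x\phi$ and $\phi\,(2 - x^2)$).  The engine provides

* batched reverse-mode gradients with respect to inputs and parameters,
* forward-over-reverse duals giving the exact mixed second derivative
  $\partial^2 E/\partial\theta\,\partial x$ contracted with a direction
  — this is what makes force-loss training exact rather than
  approximate, and
* a layerwise recursion for the exact input Hessian, used by
  `nn_hessian()`.

The composite Hessian (`composite_hessian()`) therefore mixes central
finite differences of the baseline and dispersion *analytical
gradients* (default step 0.01 Bohr ≈ 5.29×10⁻³ Å, configurable) with
the fully analytical network Hessian, and symmetrises the sum as
$(H+H^\mathsf{T})/2$.  The finite-difference step is a standard
quantum-chemistry choice; its truncation error (∼10⁻⁴ Hartree/Å² on the
Morse surrogate) dominates the Hessian error budget, which is why
closed-form comparisons in the tests use a smaller step.

Networks are initialised with a **zero output layer**: an untrained
correction predicts exactly the self-energy baseline fitted by linear
regression on element counts.  That is the natural origin for a delta
model — the model starts from "no correction" rather than from noise —
and it makes constant-delta fits exact from epoch zero.

## Two-stage training

`train_delta_ensemble()` fits the base stage on
$\Delta E$ (and optionally $\Delta F$) between the high level and the
baseline, with loss $w_E\,\mathrm{MSE}(E) + w_F\,\mathrm{MSE}(F)$,
full-batch Adam, an exponential learning-rate decay and early stopping
on validation energy MAE.  Defaults: $w_E = 1$, $w_F = 0.1$ for the
base stage.  Ensemble diversity comes from per-member initialisation
seeds *and* per-member train/validation splits; given the configuration
seed, training is bit-reproducible.

`transfer_learn()` continues training on a higher-level delta dataset
with the **first and third** weight-bearing hidden layers frozen
(indices configurable; "first and third" is read as the first and third
weight-bearing layers of each per-element network, matching predecessor
practice) and, by default, an **energy-only** loss — the higher-level
stage is described in terms of energy differences, and high-level
forces are typically unavailable.  The freeze is enforced by skipping
the optimiser update, so frozen parameters are bit-identical before and
after, which the tests assert exactly.

`calibrate_threshold()` implements the scan calibration: points sorted
by uncertainty, cumulative MAE compared with the target; the returned
threshold is the uncertainty of the *last point whose inclusion still
meets the target*, `+Inf` when everything does, and the smallest
uncertainty (flagged degenerate) when nothing does.

## Optimisation and harmonic analysis

`minimize()` is BFGS with an Armijo backtracking line search (energy
non-increasing across accepted steps).  `find_saddle()` is a
partitioned rational-function / eigenvector-following optimiser:
maximise along the lowest Hessian eigenvector with the standard 2×2
shift, minimise along the rest with the RFO shift, capped by a trust
radius (default 0.1 Å).  The exact Hessian is recomputed every 5 steps
(configurable) and carried between recomputations by the Bofill
(SR1/PSB blend) update.  Convergence is on the largest absolute
gradient component (default 4.5×10⁻⁴ Hartree/Å, a common
quantum-chemistry default).  A converged saddle is re-characterised
with a fresh Hessian and **must** have exactly one imaginary frequency
— the transition-state acceptance rule; anything else raises a
`wrong_order_error` rather than returning silently.

`normal_modes()` mass-weights the Hessian, optionally projects out
rigid translations and rotations (Eckart-style orthonormal basis, rank
detected by QR so linear molecules lose 5 modes, bent ones 6), and
reports $\tilde\nu = \mathrm{sign}(\lambda)\sqrt{|\lambda|}/(2\pi c)$
with imaginary modes as negative numbers.  Analytic low-dimensional
surfaces skip the projection — their coordinates are not Cartesian
triples.  All unit constants derive from four CODATA values declared
once in `dd_units()`.

## Quasi-classical trajectories

`sample_initial_conditions()` draws, for every real mode of an index-1
saddle, a quantum number from the geometric distribution
$P(n) \propto e^{-n h\nu_i/kT}$, assigns the mode energy
$(n_i + \tfrac12) h\nu_i$ — exactly the zero-point energy in the
$T \to 0$ limit — and a uniform random phase, then transforms
mass-weighted displacements and velocities back to Cartesians.  The
imaginary mode gets zero displacement and a classical Boltzmann
momentum by default (configurable to be excluded): because every
initial condition is propagated both forward and backward with opposite
velocities, the sign convention of the imaginary-mode momentum is
immaterial, and its magnitude convention is the one genuinely open
choice of the protocol.  The default sampling temperature is 298.15 K
(standard conditions; the protocol itself is temperature-agnostic).

`propagate()` is plain velocity Verlet, NVE, no thermostat — the
protocol is downhill dynamics from the saddle.  One force evaluation
per step; the initial gradient is computed once per initial condition
and shared by the forward/backward pair, so a campaign of $N$ paired
segments of horizon $T$ at step $dt$ costs exactly $N \cdot 2 \cdot
T/dt$ propagation evaluations (`plan_evaluations()`), e.g. 10,000,000
for 1000 paired 500 fs segments at 0.1 fs.  `combine()` stitches the
pair onto a signed time axis (backward frames reversed onto negative
times, the shared frame kept once, backward velocities negated).

**Classification.**  Molecular outcomes are defined by bond events
(formed below / broken above a distance threshold; default formation
call 1.6 Å for C–C-type bonds).  A species is *present* when all its
events hold continuously for a persistence window (default 50 fs) —
bond distances near a post-TS ridge oscillate for a while, so a
debouncing window is necessary; sub-window spikes are ignored.  A
combined trajectory containing the reactant and exactly one product is
reactive; reactant only, product only, and ambiguous cases get the
labels `reactant-only`, `nonreactive` and `undetermined` (never an
exception).  First-formation times per bond give the inter-bond time
gaps that `outcome_statistics()` aggregates, alongside counts, the
"1 : x" ratio reporting form, and percentile bootstrap intervals over
trajectory resampling.

## The synthetic fixtures: what they emulate, and what not

`make_two_level_task()` emulates the two-stage data situation: a cheap
low level (pairwise Morse surrogate), a "DFT-like" high level = low +
a smooth pairwise Gaussian perturbation (amplitude 0.02 Hartree at
1.8 Å, width 0.5 Å — a bonding-scale, descriptor-learnable feature),
and a "CC-like" transfer level adding a second, smaller perturbation
(0.006 Hartree at 2.3 Å).  Deltas equal the perturbations *by
construction*, so the learning target is known exactly.

`make_bifurcating_surface()` is a 2D analytic surface with the
topology of a post-transition-state bifurcation:

$$V = A\left((x/q)^2-1\right)^2 + k\left((y^2-c(x))^2 - c(x)^2\right)
      + \varepsilon y, \qquad c(x) = c_\mathrm{max}\tanh((x-x_0)/w).$$

The $\tanh$ keeps the cross-valley term bounded on both sides;
subtracting $c^2$ makes the $y=0$ ridge follow the bare quartic, which
provably avoids spurious stationary points along it.  The surface has a
reactant basin, an index-1 ambimodal saddle at the barrier top, a
valley-ridge inflection at $x_0 > 0$ (after the saddle), two product
wells (unequal for $\varepsilon \ne 0$, with P2 the deeper), and an
index-1 saddle interconverting the products.  All five stationary
points are located at generation time by a dense grid scan with Newton
refinement and stored in a catalog; parameter sets that break the
topology raise a generation error.  Defaults (barrier 0.02 Hartree
≈ 12.5 kcal/mol, wells ∼0.9 Å off-ridge) give vibrational periods of
tens of fs, so 250–500 fs horizons resolve the chemistry.

Two deliberate departures from molecular reality follow from the
dimensionality, and they bound what passing tests can show.  First, a
2-DOF conservative system cannot dissipate the reaction energy, so
trajectories never settle permanently into a product well; the
surface classifier (`classify_basin()`) therefore labels by the *first
persistent entry* into a product region, per trajectory half — the
dynamical commitment — rather than by terminal residence.  The
molecular, bond-based `classify()` is unaffected.  Second, the surface
runs the dynamics machinery directly on its two coordinates (the
engine is dimension-agnostic) rather than through an embedded
four-atom Cartesian construction; the Cartesian path (descriptors,
Hessians, projections) is exercised separately by the molecular
surrogates, and a fused end-to-end Cartesian trajectory test would add
cost without adding coverage.  These fixtures establish correctness of
the machinery, not chemical accuracy for any real system — the real
pericyclic chemistry, real baselines and published trained weights are
all outside this package's scope.

## Problem sizes and empirical checks

The test suite and the acceptance script run everything at desk scale,
chosen so the full pipeline stays within minutes on one CPU: the
two-level task uses 700 frames (500 train / 200 held out) with an
8-member ensemble of small networks (hidden layout 12–8) on a reduced
descriptor grid, repeated over 20 seeds for the learning-advantage
check; trajectory checks use 50 paired segments for the
energy-conservation comparison and 500 paired trajectories for the
branching statistics.  Energy conservation is compared across time
steps 1.0 vs 0.1 fs (the coarse step must be worse essentially always)
and 1.0 vs 0.5 fs for the $O(dt^2)$ factor: halving the step should
cut the per-trajectory total-energy standard deviation by roughly 4
(band 3–5).  The fourfold band belongs to *halving*; across a tenfold
step change the expected factor is ∼100, so the two comparisons are
kept separate.

## Known limitations

* No periodic systems, no charge-dependent or spin-polarised network
  terms, no excited states.
* The surrogates are caricatures: the Morse baseline has no electronic
  structure beyond fixed electronegativity-derived charges.
* Training is full-batch and CPU-bound; it is built for method study at
  synthetic scale, not for the real multi-million-point datasets.
* `rmsd_kabsch()` assumes matched atom ordering; no graph matching is
  attempted.
* No intrinsic-reaction-coordinate following and no constrained
  optimisation.
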