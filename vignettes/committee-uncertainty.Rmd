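---
title: "Committee force uncertainties: aggregation, calibration, and active learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Committee force uncertainties: aggregation, calibration, and active learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(forceuq)
```

## The statistical model

A committee of $N_C$ independently trained interatomic potentials yields,
for every structure $i$, atom $j$ and direction $k$, member predictions
$\hat f_{ij}^{k,l}$ ($l = 1,\dots,N_C$) of the force component
$f_{ij}^k$. The committee's prediction is the member mean
$\hat f_{ij}^k$; its spread,

$$ s_{ij}^k = \sqrt{\tfrac{1}{N_C-1}\sum_l
   \bigl(\hat f_{ij}^{k,l}-\hat f_{ij}^k\bigr)^2}, $$

is the raw epistemic uncertainty signal, and
$e_{ij}^k = |\hat f_{ij}^k - f_{ij}^k|$ the per-component absolute error.
All quantities are in eV/Å.

The central assumption is that member predictions scatter approximately
as Gaussians around their mean. Under it, and when model variance is the
only error source, the committee mean is itself a Gaussian draw with
standard deviation $\sigma/\sqrt{N_C}$, so its expected absolute error is
$\sigma\sqrt{2/(\pi N_C)}$ — but *one* prediction is *one* draw: a
single $e_{ij}^k$ carries no information about its own $s_{ij}^k$ beyond
an inequality (large errors require large spread, not conversely).
Averaging over many components restores the correlation. The package
therefore aggregates:

* **per structure**: $e_i$ and $s_i$, the means over all $3N_j$
  components (`structure_aggregate()`);
* **locally**: $e_{ij}^{\mathrm{local}}$ and $s_{ij}^{\mathrm{local}}$,
  the means over the components of all atoms within $r_\mathrm{cut}$ of
  atom $j$, including $j$ (`local_aggregate()`), giving $N_j$ spatially
  resolved values per structure;
* **per atom**: the plain sum (for maps) or mean over the three
  directions (`per_atom_scalar()`).

Aggregated error and uncertainty are then proportional,
$e \approx \alpha\, s$, with $\alpha = \sqrt{2/(\pi N_C)}$ in the
variance-only limit ($\approx 0.25$ for $N_C = 10$) and larger values in
the presence of model bias. `uq_calibrate()` fits $\alpha$ — nothing
more is needed; no isotonic or temperature recalibration is performed —
and `predict()` converts uncertainties to expected absolute errors.

### Exact finite-committee expectations

Two small-sample effects matter when *checking* the theory numerically.
The sample standard deviation underestimates $\sigma$,
$E[s] = c_4(N_C)\,\sigma$ (`c4_factor()`), and $E[\sigma/s] > 1$. Hence
the mean *aggregated* ratio converges to
$\sqrt{2/(\pi N_C)}/c_4(N_C)$ (0.2594 at $N_C=10$) and the mean
*individual* ratio to $\sqrt{2/(\pi N_C)}\,E[\sigma/s]$ (0.2761 at
$N_C=10$; divergent at $N_C=2$). `expected_ratio()` provides both closed
forms, and the test suite compares simulations against them rather than
against the rounded 0.25, whose difference from the exact expectation
exceeds Monte Carlo noise at realistic sample sizes. `committee_std()`
consequently keeps the plain $N_C-1$ estimator as its only default; the
$c_4$ correction is an opt-in flag, since any constant factor is absorbed
by the $\alpha$ fit anyway.

## The Monte Carlo validation experiment

`ratio_experiment()` builds the variance-only benchmark: for every
$(i,j,k)$ a ground-truth spread $\sigma_{ij}^k$ is drawn from a
configurable distribution, then $N_C$ member predictions from
$\mathcal N(0, \sigma_{ij}^k)$, with the target fixed at zero. Defaults
follow the benchmark conditions: $N_C = 10$, $N_i = 100$, $N_j = 1000$,
$\sigma$ from an inverse-Gamma distribution. The inverse-Gamma parameters
are not pinned down by the theory (the concentration result is
distribution-free, which the suite verifies against uniform, truncated
normal and constant spreads); shape 3 and scale 1 were chosen once for
strictly positive support with finite mean and variance. A single seeded
generator drives all draws in a fixed (structure; component; member)
order, so runs are bitwise reproducible; non-positive draws from the
truncated normal are redrawn and counted. The benchmark run (3 million
components, 30 million Gaussians) streams structure by structure and
completes in well under a minute on one CPU core.

```{r}
r <- ratio_experiment(n_c = 10, n_i = 50, n_j = 500, seed = 1)
r
c(expected_aggregated = expected_ratio(10, "aggregated"),
  expected_individual = expected_ratio(10, "individual"))
```

The aggregated histogram is narrow (IQR two orders of magnitude below
the individual one at $N_j = 1000$), which is the whole point: the
per-structure — and, below, the per-neighborhood — uncertainty is a
quantitative error estimate even though the per-component one is not.

## Neighbor shells and numerical choices

`build_neighbor_shells()` uses Euclidean distances along non-periodic
directions and nearest-image distances along periodic ones. For
orthogonal cells the per-axis fractional wrap is exact; for triclinic
cells the wrap is followed by a scan over the $3^3$ surrounding replica
shifts, which reproduces a brute-force all-replica search exactly (the
suite fuzzes 200 cells against an independent replica oracle). If
$r_\mathrm{cut}$ exceeds half the shortest perpendicular cell width the
minimum image is ambiguous as a *neighbor* notion; the package warns and
switches to the exact replica scan for the distances.

The shell boundary is inclusive ($\le r_\mathrm{cut}$) and every atom is
its own neighbor, so $r_\mathrm{cut} = 0$ degrades gracefully to the
self-shell and local aggregation never divides by zero. Shell atoms are
weighted equally — the local aggregate is a plain mean over components,
not a smooth kernel. As $r_\mathrm{cut}$ reaches the maximum pairwise
distance every local value equals the per-structure value identically
(same summation, tolerance $10^{-12}$ relative in the tests). The
default $r_\mathrm{cut} = 4$ Å is the radius used for the
active-learning selection and is recorded in all outputs; it trades
locality against the number of components averaged (the correlation
strengthens with the shell size).

## Calibration and sparsification

`uq_calibrate()` supports two estimators of $\alpha$: the mean ratio
$\overline{e/s}$ (default, matching how a ratio histogram is summarized)
and the least-squares slope through the origin. Items with $s = 0$ are
excluded and counted. The practical protocol — fit on a 20% calibration
split (`calibration_split()`, deterministic first-$k$ or seeded random),
predict the held-out 80% — is exercised in the tests with planted
proportionality $e = \alpha_0 s$ times 10% multiplicative noise, where
the held-out mean absolute deviation of $\alpha s$ stays well below 15%
of the held-out mean error for $\alpha_0 \in \{0.5, 1, 1.5\}$.

`sparsification()` removes the highest-uncertainty (or, for the oracle,
highest-error) items first over a default grid of 100 removal fractions;
the retained-set MAE at fraction $f$ uses the
$\lceil (1-f)\,n \rceil$ smallest items with stable index tie-breaks,
and the reported area is the plain trapezoidal integral between the two
curves. That area scales linearly with the error magnitude (and is blind
to a rescaling of the uncertainties, which does not change their
ordering); comparisons across data sets should therefore normalize by
the full-set MAE if absolute scales differ.

One caveat the variance-only analysis makes precise: at the *atomic*
level the realized error and the estimated spread are statistically
independent given $\sigma$, so ordering atoms of a homogeneous
population by atomic uncertainty finds the atoms with the largest
realized errors only at chance level. Local aggregation, not a better
per-atom estimator, is what makes spatial error maps work.

## The synthetic-data generator

`make_fixtures()` emulates the committee structure of real predictions:
random periodic configurations, a smooth sinusoidal ground-truth force
field, members drawn as the truth plus Gaussian noise with a constant
background spread $\sigma_0$, an optional spherical *variance hot-spot*
(spread multiplied by a factor inside a ball — a locally poorly-learned
region) and an optional *bias* shift applied identically to all members
(invisible to the spread, as real model bias is). Reference forces are
the exact truth. What it deliberately does not emulate: correlated
members, non-Gaussian error tails, forces from an actual Hamiltonian,
and bias that co-varies with variance the way trained ensembles show.
Passing tests therefore demonstrate the statistical machinery —
aggregation, calibration, detection — under the stated assumptions, not
the accuracy of any particular trained potential.

`synthetic_water_box()` provides the geometry fixture for the
active-learning pipeline: rejection-sampled oxygens (minimum O–O
separation 2.2 Å), two hydrogens per oxygen at 0.97 Å with the water
bond angle, everything wrapped into a cubic periodic cell so molecules
straddle the boundary.

## Active-learning geometry

`select_frames()` partitions a trajectory into `n_segments` (default 10)
evenly sized segments — the remainder goes to the last — and picks per
segment the frame with the highest maximum local uncertainty (or atomic
uncertainty, or a seeded random frame), with the center atom given by
the argmax atom; ties resolve to the earliest frame and lowest index, so
selection is deterministic given (trajectory, strategy, seed).

`extract_subbox()` cuts a small cell around the selected center: the
center plus the $n-1$ nearest same-species atoms (nearest-image metric),
each with its nearest companion atoms assigned greedily nearest-first
and exclusively, so no atom is duplicated when two centers compete. The
new cubic edge defaults to the density-preserving
$l_\mathrm{new} = l_\mathrm{orig}\,(N_\mathrm{kept}/N_\mathrm{orig})^{1/3}$
(configurable, since other conventions are defensible). Selected atoms
are unwrapped hierarchically — centers to the image nearest the central
atom, companions to the image nearest their owner — which guarantees
intact molecules; positions are not re-wrapped into the new cell.
Non-cubic source cells are rejected. The core-freezing radius
$0.8\,l_\mathrm{new}/2$ is measured from the single central atom (the
protocol's phrasing admits a multi-center reading; the single-center one
is implemented).

`relax_border()` heals the cut boundary: freeze the core, pad the cell
edge by 2 Å, run 5 quasi-Newton (L-BFGS-B) iterations on the free atoms,
shrink by 0.2 Å, and repeat until the original edge returns — ten stages
at the defaults, with the iteration count a fixed protocol parameter
rather than a convergence criterion. The calculator is a plain R
callback returning energy and forces, so any potential (or a toy
harmonic model, as in the tests) can drive the relaxation; non-finite
energies or forces abort with the stage context. `al_round()` composes
the three steps and logs per-pick failures without aborting the round;
its outputs are structures ready for external ab initio labeling —
labeling and retraining are outside the package's scope, as is running
MD.

## Problem sizes and limitations

The test suite runs the benchmark experiment at its full size
($N_C = 10$, $N_i = 100$, $N_j = 1000$), the committee-size law at
$N_i = 60$, $N_j = 300$, the distribution-invariance comparison at
$N_i = 80$, $N_j = 400$, neighbor-shell fuzzing on 200 cells of up to
100 atoms, hot-spot detection on a single 600-atom cell, and the water
pipeline on 128 molecules — sizes at which every check completes in
seconds while keeping Monte Carlo standard errors far below the effects
being tested.

Known limitations: energies are not treated (the statistics here are
force-based); neighbor search is the $O(N^2)$ pairwise scan, adequate to
a few thousand atoms but not linked-cell fast; no species-dependent
cutoffs; no member weighting or correlated-member models; the extended
XYZ dialect covers `Lattice`/`Properties`/`pbc` with per-member
`forces_<l>` columns but not every key in the wild.
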