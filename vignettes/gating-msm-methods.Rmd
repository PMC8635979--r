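---
title: "Methods: seeded Markov state models of pentamer gating"
author: "pentagate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seeded Markov state models of pentamer gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `pentagate`, the
assumptions behind them, the tunable parameters and their defaults, the
numerical choices, and what the synthetic validation does and does not
demonstrate about real trajectory data.

## The modeling problem

A pentameric ligand-gated ion channel interconverts between closed and
open pore conformations on microsecond timescales. Single unbiased
simulations started from experimental structures stay trapped in one
free-energy well, so the sampling strategy modeled here is: (1) generate
coarse-grained structures interspersed along the closed–open transition,
(2) treat them as seeds for many independent unbiased trajectories, and
(3) recombine the swarm statistically with a Markov state model, which
needs only *local* equilibration at the lag timescale, not global
equilibrium sampling. Stationary reweighting by the MSM then yields
equilibrium populations, transition rates, and free-energy landscapes that
none of the individual trajectories contains on its own.

## Pathway seeding by biased Brownian dynamics

The channel is reduced to one bead per residue (Cα) and modeled as an
elastic network: harmonic springs between all bead pairs within a 12 Å
cutoff inside a subunit or 8 Å across subunits, force constant
10 kcal·mol⁻¹·Å⁻², rest lengths equal to the build-time distances. The
shorter inter-subunit cutoff keeps interfaces compliant relative to the
subunit cores, which is where gating motion happens.

The transition is driven by overdamped Langevin dynamics,

\[ \Delta x = F\,\Delta t/\gamma + \sqrt{2\,k_BT\,\Delta t/\gamma}\;\eta, \]

with two force terms: the elastic network, and a harmonic bias applied each
step to the 10% of *all* bead pairs whose current internal distance
deviates most from the target structure's, pulling those distances toward
the target values. Biasing the full internal-distance set (rather than
only network edges) is deliberate: target contacts that do not exist in
the start-structure network must still be driven, or the endpoint could
never be reached. Network rest lengths are refreshed to the current
geometry every 50 steps, so the network preserves local structure while
the bias progressively transforms it — without the refresh the springs
anchor the walk to the start conformation and the target tolerance is
unreachable.

Integrator constants are reduced units chosen for stability rather than
realism: `dt = 0.002`, `friction = 1`, `kT = 0.1` kcal/mol, with the drift
displacement capped at 0.05 Å per step. Convergence is declared when the
all-pairs internal-distance RMS to the target falls below 0.5 Å — below
the coordinate uncertainty of a Cα trace. The transition progress
coordinate is this internal-distance RMS, normalized to 0 at the start
value and 1 at convergence and made non-decreasing by a running maximum;
it is the driving objective itself, which makes seed spacing meaningful
even when Cartesian RMSD is not monotone. Seeds are taken at equal
progress spacing, endpoints included, half from the forward and half from
the reverse run (the split between directions is an even one by
construction). All stochastic stages accept one seed and derive
deterministic substreams, so ensembles are bit-reproducible.

## Symmetry-aware featurization

Features are interatomic distances declared by within-subunit bead (or
residue) index and a subunit *role*: `self`, `principal+1`, `principal+2`,
`complementary-1`, `complementary-2`, resolved cyclically (mod 5) against a
reference subunit. The orientation convention is fixed once: the principal
(+) direction is counterclockwise viewed from the extracellular side.
Scoring the same feature list against all five reference subunits turns
one pentamer trajectory into five — each copy describing how one subunit
moves relative to all others. Pooling the copies (a) multiplies the
effective sampling of single-subunit motions by five and (b) makes every
pooled estimate exactly invariant under cyclic relabeling of the subunits,
which the test suite verifies both for C5-symmetric frames (zero
between-copy variance) and for downstream MSM populations (< 0.5
percentage points under relabeling). The default feature list emphasizes
transmembrane-domain bead pairs within a subunit and between principal-side
neighbors, the regions whose motions dominate the slow gating coordinate;
the list is fully configurable because no canonical residue-pair set
exists for an arbitrary topology.

## tICA

Time-lagged independent component analysis solves
\(C_\tau v = \lambda C_0 v\) with \(C_0\) the mean-free instantaneous
covariance and \(C_\tau\) the lagged covariance symmetrized as
\((C_\tau + C_\tau^{\mathsf T})/2\), the standard estimator under a
detailed-balance assumption. Both are pooled over all trajectories and all
five rotation copies of a condition. The default lag is 20 ns.

Numerics: \(C_0\) is eigendecomposed and directions with eigenvalue below
`1e-8 · trace(C0)/F` are discarded before whitening — the rotation copies
induce exact collinearities, so this regularization is structural, not
cosmetic. Eigenvalues are clamped to \([-1, 1]\) (estimates may exceed 1 by
rounding; a genuine excess triggers a stationarity warning). Projections
are scaled by \(\lambda_i\) when kinetic mapping is on, so Euclidean
distance in projection space approximates kinetic distance — the right
metric for the k-means discretization that follows.

Dimension selection follows the rule of keeping only slow components whose
marginal is *not* a single Gaussian: a 1- versus 2-component univariate
Gaussian mixture is fitted (unequal variances) and the dimension is kept
when the 2-component BIC wins by at least 10 — a decisive margin on the
usual evidence scales. At least two dimensions are always retained so a
2D landscape exists; if nothing passes, the two slowest components are
kept by fallback.

## Reversible MSM

Frames are discretized by k-means in the retained tICA space (k-means++
style restarts, best of `nstart` by inertia, fixed recorded seed,
nearest-center ties to the lowest index). For large frame counts the
centers are fitted on an evenly spaced subsample and all frames are then
assigned; this is standard practice and changes nothing statistically at
the sizes used here. Transition counts use a sliding window at lag τ
(maximal data use; the counting mode is configurable), and estimation is
restricted to the largest strongly connected component of the count graph
— reversible estimation is undefined off it, and excluded frames are
counted and reported rather than silently dropped.

The transition matrix is the maximum-likelihood reversible estimator,
obtained by fixed-point iteration on unnormalized symmetric flows
\(x_{ij}\):

\[ x_{ij} \leftarrow \frac{c_{ij} + c_{ji}}{c_i/x_i + c_j/x_j}, \]

iterated until the relative log-likelihood change is below `1e-13`; the
stationary distribution is the normalized row sum of the converged flows
and detailed balance holds to machine precision by construction. The test
suite checks the converged log-likelihood against a generic constrained
optimizer to 1e-8 on random count matrices. The spectrum is computed via
the symmetric similarity transform \(D_\pi^{1/2} T D_\pi^{-1/2}\), which
guarantees real eigenvalues for reversible matrices.

Validation follows standard MSM practice: implied timescales
\(t_i(\tau) = -\tau/\ln\lambda_i(\tau)\) must be flat in τ (bootstrap
confidence bands over trajectories are available), and Chapman–Kolmogorov
tests compare \(T(\tau)^k\) against re-estimation at lag \(k\tau\) on
macrostate sets, with bootstrap errors; lags where re-estimation is
impossible are flagged, not dropped. The suite includes a deliberately
non-Markovian observable (a hidden three-state chain lumped to two
symbols) to confirm the test has power, not merely that it accepts.

## Macrostates, populations, MFPTs, landscapes

PCCA+ coarse-grains the MSM: the top \(m\) right eigenvectors span a
simplex whose vertices are maximally metastable sets; vertices are found
by the inner-simplex construction (iterative farthest point with
orthogonal deflation), memberships are the barycentric coordinates clipped
to \([0,1]\) and row-renormalized, and crisp states take the arg-max
membership with ties to the lower index (the assignment rule must be fixed
somehow; arg-max is the convention used throughout). Two-state models
capture the closed/open split; four- or five-state models resolve
intermediates, with the count a user choice guided by the number of
landscape minima. The open-like macrostate is identified from the data as
the one with the larger mean of the first feature (a pore-expansion-like
distance in the default generator), never from the ground-truth labels.

MFPTs solve \(m_i = \tau + \sum_j T_{ij} m_j\) with \(m = 0\) on the
target and are averaged over the source set with stationary weights, in
microseconds. Free-energy landscapes weight each frame by
\(\pi_{s}/n_{s}\) (stationary probability of its microstate over the
frames observed there), bin the first two tICA coordinates (default
80×80), and set \(\Delta G = -k_BT \ln(\rho/\rho_{max})\) with
kT = 0.5962 kcal/mol (300 K) by default; the minimum over populated bins
is exactly zero and empty bins are masked, never assigned \(-kT\ln 0\).
Barrier heights are read from the stationary-weighted 1D profile along the
first coordinate — the macrostate-dominated minima are located, and the
maximum of the profile between them, measured from the deeper minimum, is
the barrier. A 1D convention must be chosen; the first tICA coordinate is
the one that separates the metastable states.

Hyperparameters follow an elbow rule rather than variational scoring: the
pipeline is run over a grid of cluster counts (and lags), the open-state
population recorded, and the smallest cluster count beyond which that
population changes by less than 0.01 between successive grid points is
selected; with no flat region the largest count is returned with a
warning.

## Structural observables and symmetry

All observables operate on labeled bead coordinates and are invariant
under rigid-body motion of the frame. The pore axis is not assumed to be
the laboratory z-axis: it is the covariance eigenvector of a reference
selection whose eigenvalue is most separated from the other two (for a
C5-symmetric ring stack the two in-plane variances are degenerate and the
axial one is the odd one out); isotropic selections are rejected as
degenerate. Pore radii (M2 spread, 9′, −2′) are perpendicular distances of
per-subunit selection centroids to this axis. Interface distances resolve
roles cyclically (principal M2 to complementary M1, the β1–β10 pair, the
proton-sensor pair). The M1 kink is the angle at the middle bead of a
three-bead selection (180° = straight). ECD twist is the mean signed
azimuthal offset between each subunit's ECD and TMD centroids about the
pore axis, relative to a reference frame. Pore hydration counts water
oxygens inside an axis-aligned cylinder (default radius 5 Å, axial bounds
the TMD span, boundaries closed; hydrated means strictly more than 20
waters — the cylinder definition is configurable because no canonical pore
region exists for an arbitrary topology).

Subunit symmetry is quantified as pairwise RMSD between homologous atoms
of the 5 neighboring and 5 opposing subunit pairs, after *per-pair*
optimal superposition (Kabsch). Per-pair, rather than whole-channel,
superposition isolates internal conformational asymmetry from the rigid
placement of subunits around the ring; with whole-channel superposition a
perfectly rigid but tilted subunit would masquerade as asymmetry.

## The synthetic generator: what it emulates, and what it does not

`default_kinetics()` defines four microstates in two metastable pairs
(closed: 1–2, open: 3–4) with intra-pair exchange 0.1 and total inter-pair
probability 0.005 per 20 ns step — a two-basin system with a ~2 µs slowest
relaxation and 4 µs basin-to-basin MFPTs, the regime of interest for
gating. Emissions are state means replicated over five homologous feature
blocks plus iid Gaussian noise (sd 0.2 against a basin separation of 2),
mimicking the block structure of per-subunit distance features. The
standard study size is 50 trajectories × 20,000 steps; reduced sizes are
used in unit tests where only correctness, not statistical precision, is
at stake.

What passing recovery tests shows: the estimator chain — covariances,
generalized eigenproblem, discretization, reversible MLE, PCCA+, MFPT
solve, reweighted landscapes — is implemented correctly and recovers known
thermodynamics and kinetics from finite, non-equilibrium-started samples.
What it does not show: that real molecular features are Gaussian about
state means (they are not; emissions here have no within-state dynamics,
no anharmonicity, no slow non-Markovian memory), that five-fold block
symmetry is exact in solvated simulations (lipid and water environments
break it), or that the free-energy barrier from toy emissions is
physically meaningful — with discrete-state Gaussian emissions the
landscape between basins is populated only by Gaussian tails, so the
apparent barrier reflects the sampling floor of the histogram rather than
a transition-state free energy. Barrier estimates are meaningful when the
projected density between minima is genuinely sampled, as in the
continuous double-well tests.

## Degenerate inputs and edge rules

Reducible transition matrices are rejected with the disconnected sets
named. All-constant features are absorbed by the C0 regularization and
flagged. A tICA spectrum with no eigenvalue above 1e-6 raises "no slow
process". Empty landscape bins are masked; a landscape whose macrostates
dominate no bins, or whose minima are adjacent, raises an error rather
than reporting a sham barrier. Waters exactly on the hydration cylinder
boundary are counted (closed boundary). Non-converged pathway runs return
the partial ensemble with a warning flag. k-means ties and PCCA+ membership
ties both break toward the lower index, and every stochastic routine takes
an explicit seed, so all results are reproducible bit-for-bit.

## Known limitations

* Featurization is Cα/bead-level; side-chain contacts (e.g. true salt
  bridges) are only proxied by backbone distances.
* The reversible MLE provides point estimates; there is no Bayesian
  posterior sampling of transition matrices, so MFPT uncertainties come
  from trajectory bootstrap only.
* PCCA+ uses the inner-simplex construction without the subsequent
  objective refinement; for strongly metastable systems (the intended use)
  the refinement changes assignments negligibly.
* The symmetry expansion is defined for pentamers; other stoichiometries
  would need the role algebra generalized.
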