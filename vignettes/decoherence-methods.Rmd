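---
title: "Surface hopping with projected-force-momentum decoherence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface hopping with projected-force-momentum decoherence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(surfhop)
```

## The problem

Fewest-switches trajectory surface hopping (TSH) propagates classical nuclei
on one "active" adiabatic electronic surface while integrating the electronic
Schrödinger equation along the trajectory; stochastic hops between surfaces
follow the electronic population flux.  Because a classical trajectory has no
nuclear wave function, the off-diagonal electronic density matrix elements
$\rho_{ij}(t) = c_i(t)c_j^*(t)$ never feel the decay of the nuclear overlap
between wave packets travelling on different surfaces: bare TSH is
*overcoherent*, which distorts both coherence observables and, through the
hopping algorithm, the populations themselves.

`surfhop` implements a family of *decoherence corrections* that damp the
inactive-state coefficients with a first-order estimate of the
overlap-decay rate $k_{ia}$, and validates them against an exact multi-state
grid propagator on one-dimensional analytic diabatic models.

## Decoherence rates

All rates damp an inactive coefficient per electronic substep,
$c_i \leftarrow c_i e^{-k_{ia}\,\delta t}$, with the active coefficient
rescaled to restore the norm (`apply_decoherence()`).

* **EDC** (`edc_rate()`): $k = |E_{ia}|\,T/(T + C)$, the energy-based
  correction with the recommended $C = 0.1$ hartree.  It vanishes at rest and
  approaches the potential-energy gap at high kinetic energy — by
  construction it is fast whenever the gap is large, independent of the
  actual wave-packet separation.
* **FM** (`fm_rate_1d()`): for one nuclear dimension, the frozen-Gaussian
  overlap-decay rate
  $k = \tfrac{\sigma^2}{2}\bigl(p_{ij}f_{ij} +
  |p_{ij}|\sqrt{f_{ij}^2 + 1/(\mu^2\sigma^6)}\bigr)$
  built from the *differences* of per-surface momenta and forces.  The width
  $\sigma$ (bohr) is taken from the sampled initial ensemble.
* **PFM** (`pfm_rate()`): the multidimensional generalization
  $k = \tfrac{\pi^2}{8\omega}|P^v_{ij}||F^v_{ij}| +
  |P^v_{ij}|\sqrt{\pi^2 N_D\,\omega/8}$,
  which needs only *trajectory-velocity-projected* (TVP) quantities: the
  projection of each surface's mass-weighted force onto the direction of the
  trajectory velocity is computable from energies alone
  ($F^v_j = -\dot E_j / |\dot Q|$, `tvp_force()`), so no inactive-surface
  gradients are ever required.  The common frequency $\omega$ is the
  geometric mean of the normal-mode frequencies (`width_parameters()`), which
  preserves the volume of the variance ellipsoid; it may also be set freely.
  The $2/\pi$ angle average (`cos_angle_average()`) converts projected
  magnitudes into full-vector magnitudes under an isotropic-angle assumption.

The mode-resolved rate (`fm_rate_normal_modes()`) is retained as the
reference form: tests verify at machine precision that the 1-D rate is its
single-mode special case under $\dot q = p/\sqrt{\mu}$,
$\ddot q = f/\sqrt{\mu}$, $\omega = 1/(2\mu\sigma^2)$, and by brute force
(10^4 random instances) that the common-frequency expression bounds it from
above.

## Auxiliary momenta, births, deaths and injection

Each electronic state carries one scalar auxiliary momentum
(`aux_momentum_update()`).  The active state's momentum is propagated with
its TVP force, kept continuous across hops, and rescaled by the same
isotropic factor $\sqrt{1 - \Delta E/T}$ as the velocities.  Inactive states
with population at or above the threshold $\eta$ (default $10^{-4}$)
propagate independently; below the threshold they are slaved to the
energy-rescaled active value $P_a\sqrt{\max(0, 1 - E_{ia}/T)}$.  A
population crossing below $\eta$ is treated as complete decoherence (the
residual amplitude is collapsed onto the active state); a population rising
above $\eta$ is a wave-packet *birth* that starts propagating from the
slaved value.

Without further care, an inactive momentum propagated since an early birth
misrepresents population that arrives later through another coupling region
(the *momentum history problem*).  The *momentum injection* variants
(FMi/PFMi) blend energy-rescaled active momentum into the inactive momentum
in proportion to every population gain,
$P_i \leftarrow P_i(1 - \Delta\rho/\rho_{ii}) +
(\Delta\rho/\rho_{ii})\,P_a\sqrt{\max(0,1-E_{ia}/T)}$.
The acceptance suite demonstrates the practical consequence on the
three-state surrogate: with injection the ensembles for
$\eta \in \{10^{-3},10^{-4},10^{-5}\}$ agree within their 95% confidence
intervals, while FM without injection drifts away at $\eta = 10^{-5}$.

## The propagator

One nuclear step of `run_trajectory()` (compiled core, with an R reference
implementation that reproduces it to ~1e-12; both consume R's RNG with one
uniform draw per substep, so runs are exactly reproducible from a seed):

1. Velocity-Verlet half-kick and drift with the active-surface
   Hellmann-Feynman force; the midpoint velocity is the TVP reference.
2. Eigendecomposition of $V(R)$ at the new geometry; eigenvector sign
   continuity by overlap with the previous frame.
3. TVP auxiliary forces from the forward energy differences, zeroed when the
   reference speed is below $\kappa = 10^{-9}$.
4. Local diabatization: the per-step transfer matrix is the polar factor of
   the state-overlap matrix (for analytic models the overlap is orthogonal
   to machine precision, so the residual coupling $\tilde K$ is negligible
   and all interstate mixing flows through the diabatized potential
   $\tilde V = U^T \mathrm{diag}(E)\, U$).
5. 51 electronic RK4 substeps on
   $i\dot{\tilde c} = (\tilde V - i\tilde K)\tilde c$ with the endpoint
   matrices interpolated linearly (two nodes per step; a spline through two
   points degenerates to a line).  The step-mean diagonal energy is
   subtracted first — a pure global-phase gauge that reduces RK4 phase error
   without touching populations or coherences.
6. Per substep: transform to the adiabatic frame with the interpolated
   cumulative $U$; hop probabilities by the density-flux rule
   (`hop_probabilities()`; the classic fewest-switches probability from the
   finite-difference coupling is available as `hop_scheme = "fssh"` for
   cross-checks); frustration test $E_a + T \ge E_k$ with linearly
   interpolated energies and the midpoint kinetic energy; decoherence
   damping with rates evaluated once per nuclear step from step-start
   quantities (recomputed if the active state changes mid-step).
7. Second Velocity-Verlet half-kick; if the active state changed, isotropic
   velocity rescaling with the exact start/end total-energy difference, so
   the post-hop total energy equals the pre-hop value to machine precision.
   Frustrated hops leave the velocity untouched (no reversal).
8. Auxiliary momentum update, then threshold collapse of populations that
   fell below $\eta$ during the step.

Two numerical details matter near *sharp* avoided crossings (per-step
electronic rotations that are not small):

* the linearly interpolated cumulative $U$ is far from orthogonal mid-step;
  damping in that distorted frame and transforming back with $U^T$ leaks
  real population.  Whenever the per-step rotation exceeds a small bound the
  interpolated matrix is re-orthogonalized by its polar factor, which
  restores exact norm consistency (and, in testing on the three-state
  surrogate, restores agreement with the exact propagator that the naive
  interpolation destroys);
* if the end-of-step rescaling radicand turns out negative despite the
  substep frustration test (an interpolation edge case), the hop is treated
  as frustrated and the active surface reverted.

## Model zoo and initial conditions

The analytic diabatic models play the role that molecular applications play
in production codes:

* `avoided_crossing_2s` — two repulsive diabats (reduced mass 2000 m_e) with
  constant coupling 0.002 hartree; a minimum-uncertainty Gaussian
  ($x_0 = 2.3$ bohr, $\sigma = 0.224$ bohr) released on the upper diabat
  splits at the crossing near 3.3 bohr with roughly even branching.  Chosen
  so one passage completes within 35 fs and the exact grid solution is cheap.
* `ibr_surrogate_3s` — a heavy-diatomic photodissociation surrogate: bound
  Morse ground state, a quasi-bound and a repulsive-then-flat excited diabat
  crossing near 6.8 bohr (well away from the Franck-Condon point at
  4.666 bohr), constant couplings ($1.5\times10^{-3}$ between the excited
  states, mimicking a constant spin-orbit-type coupling).  The reduced mass
  (89380 m_e) and ground-state frequency ($1.173\times10^{-3}$ hartree) give
  a sampled bond-length width $\sigma = 6.906\times10^{-2}$ bohr.  The
  diabatic promotion of the ground-state wave function produces a small
  (~0.6%) initial occupation of the other adiabatic excited state because
  the coupling is constant — visible as weak early coherence oscillations.
* `tully3_sloped` — two sloped linear diabats with a Gaussian coupling, a
  sloped-crossing topology.
* `lvc_nd` — a three-mode, two-state linear vibronic coupling model in
  dimensionless normal-mode coordinates (unit masses), the multidimensional
  test bed for the PFM machinery.

Initial conditions are zero-temperature Wigner samples: analytic Gaussians
for harmonic cases (`harmonic_wigner_sample()`, mass-weighted variances
$1/2\omega$ and $\omega/2$), or rejection sampling from the numerically
exact gridded Wigner transform of the Fourier-grid ground state
(`grid_wigner_sample()`), disregarding cells below the floor $10^{-10}$.
Only ground states (positive Wigner functions) are supported; sign-weighted
sampling of negative Wigner regions is out of scope.  Initial electronic
coefficients are stated in the diabatic basis (complex phases allowed) and
transformed with $W^T(R_0)$ at each sampled geometry; the initial active
surface is drawn with probabilities $|c_j(0)|^2$.

What the models do *not* emulate: anharmonic multi-dimensional sampling,
geometry-dependent couplings of real molecules (except `tully3_sloped`),
finite temperature, and any ab initio electronic structure.  Passing tests
therefore demonstrate the correctness and internal behaviour of the
algorithms under controlled conditions, not quantitative accuracy for any
specific molecule.

## Ensembles, filtering, balancing

`run_ensemble()` seeds trajectory $\nu$ with `base_seed` $+\ \nu$, making
every trajectory independent and the ensemble independent of execution
order.  `filter_and_balance()` removes trajectories whose total energy
drifts more than $E_D$ (default 1.0 eV) from its initial value, then — when
an initial superposition populated several surfaces — stochastically removes
trajectories started on the *less* failure-prone surfaces until the
time-zero active fractions match the original ones to within half a
trajectory, so that exclusion does not bias the branching statistics.
`ensemble_averages()` reports $\rho_{ij}(t)$, active fractions $\Pi_j(t)$,
the internal-consistency gap $\max_j|\rho_{jj}-\Pi_j|$, normal-approximation
95% confidence intervals, the $t=0$ total-energy distribution, and (on
request) observable expectations with the full electronic wave function,
$\langle O\rangle = \langle\sum_{ij} c_i^* c_j O_{ij}(R)\rangle$.

## The exact reference

`split_operator_propagate()` integrates the coupled diabatic amplitudes on
an equidistant grid with symmetric Strang splitting; the static potential
propagator is diagonalized pointwise once per run, the kinetic step uses the
FFT.  The default grid for the surrogate emulates 1024 points on
[3.5, 11] bohr at 0.01 fs, but each preset carries a grid wide enough that
nothing reaches the (hard-wall, effectively periodic) boundary within its
default horizon; an edge-amplitude monitor warns at $10^{-6}$.  Initial
superpositions are built by copying the ground-state nuclear function onto
several diabats with complex weights.  `grid_observables()` projects
pointwise into the adiabatic basis (with sign continuity along the grid) and
integrates $\rho_{ij}(t) = \int \tilde\chi_i \tilde\chi_j^*\,dx$.

## Problem sizes and tolerances used in the shipped tests

The test suite runs 2000 trajectories for the oracle-equivalence and
threshold-robustness checks (the quantum branching is matched to within
0.05), 200–300 for the coherence phenomenology (confidence-interval
separated ordering EDC fastest, then PFMi, then pure dephasing), and
10^4–10^5 random draws for the algebraic properties.  The
threshold-robustness experiment propagates the surrogate for 100 fs, by
which time both wave packets have left the coupling regions and the
branching has plateaued.  Tolerances follow the honest error bounds of the
integrators: Strang splitting and Velocity-Verlet are second order (energy
bounded by $(\omega\Delta t)^2/8$ on harmonic motion), the electronic RK4 is
fourth order, and all structural identities (norms, unitarity, trace,
Cauchy-Schwarz) are asserted at 1e-10 or tighter.

## Known limitations

* The exact reference is one-dimensional; multidimensional dynamics is
  validated by structural properties (zero-coupling invariance, norm and
  energy conservation, coherence phenomenology), not against a
  multidimensional grid solution.
* Isotropic velocity rescaling only; no rescaling along nonadiabatic
  coupling vectors and no velocity reversal at frustrated hops.
* One auxiliary momentum per inactive state; the injection blend is an
  average over notional sub-packets, not a multi-packet bookkeeping.
* The density-flux hopping probability is a documented reconstruction (loss
  fraction of the active density distributed over the gaining states); the
  classic fewest-switches expression is available as a cross-check option.
```r
m <- build_model("avoided_crossing_2s")
res <- tsh_simulation(m, n = 500, variant = "fmi", seed = 1)
summary(res)
plot(res)
```
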