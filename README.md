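# surfhop

Fewest-switches trajectory surface hopping with projected-force-momentum
decoherence, validated against exact quantum dynamics on analytic model
Hamiltonians.

## The problem

Trajectory surface hopping (TSH) is the workhorse of nonadiabatic molecular
dynamics: classical nuclei ride one "active" adiabatic potential surface,
the electronic Schrödinger equation is integrated along the trajectory, and
stochastic hops between surfaces follow the electronic population flux.
A classical trajectory, however, carries no nuclear wave function, so the
electronic coherences ρ_ij = c_i c_j* never feel the decay of the nuclear
overlap between wave packets separating on different surfaces — bare TSH is
*overcoherent*, which corrupts coherence observables and, through the
hopping, the populations themselves.

`surfhop` is for method developers and teaching/benchmark studies of
electronic decoherence in TSH.  It implements:

* **decoherence rates** damping the inactive coefficients,
  c_i ← c_i e^(−k_ia δt) with the active coefficient rescaled to unit norm:

  | variant | rate | needs |
  |---|---|---|
  | `edc` | k = \|E_ia\| · T/(T + C) | C (default 0.1 hartree) |
  | `fm`/`fmi` (1-D) | k = (σ²/2)(p_ij f_ij + \|p_ij\| √(f_ij² + 1/(μ²σ⁶))) | packet width σ, reduced mass μ |
  | `pfm`/`pfmi` (multi-D) | k = (π²/8ω)\|P_ij\|\|F_ij\| + \|P_ij\|√(π² N_D ω/8) | common frequency ω, mode count N_D |

  The FM/PFM momentum and force differences come from per-state *auxiliary*
  momenta driven by trajectory-velocity-projected forces −Ė_j/|Q̇| —
  no inactive-surface gradients are required.  The `fmi`/`pfmi` variants add
  *momentum injection*: whenever an inactive population grows, energy-rescaled
  active-surface momentum is blended in, which removes the sensitivity to the
  population threshold η (default 1e-4) that plain FM/PFM retains.
* a full **fewest-switches propagator** (compiled core + an R reference
  engine agreeing to ~1e-12): Velocity-Verlet nuclei, local-diabatization
  electronic propagation with 51 RK4 substeps per nuclear step, density-flux
  hopping, isotropic velocity rescaling, frustrated hops without velocity
  reversal;
* an exact **split-operator grid propagator** for 1-D multi-state models
  (the quantum reference), with Fourier-grid ground states and numerical
  **Wigner sampling** of initial conditions, including initial coherent
  electronic superpositions with complex phases;
* **ensemble analytics**: energy-drift filtering with stochastic rebalancing
  of the initial-surface fractions, averaged density matrices with 95%
  confidence intervals, fractions of active trajectories, and the
  internal-consistency gap max_j |ρ_jj − Π_j|;
* four analytic diabatic **model presets** (`avoided_crossing_2s`,
  `ibr_surrogate_3s`, `tully3_sloped`, `lvc_nd`) standing in for the
  photochemistry applications such methods target.

See `vignettes/decoherence-methods.Rmd` for the full account of the models,
algorithms and numerical choices.

## Worked example

Release a Gaussian wave packet on the upper diabat of the two-state avoided
crossing, run 500 FMi trajectories, and compare with the exact grid
propagation:

```r
library(surfhop)
m   <- build_model("avoided_crossing_2s")
res <- tsh_simulation(m, n = 500, variant = "fmi", seed = 1)
summary(res)
#> <tsh_ensemble> 500 trajectories, 2 states, t up to 35.000 fs (deco = fmi)
#>   final adiabatic populations: 0.4279, 0.5721
#>   final active fractions:      0.4260, 0.5740
#>   internal-consistency gap: max 0.0187, time-avg 0.0053
#>   counts: run 500, valid 500, balanced 500
#>   initial total energy: 0.024102 +- 0.005768 hartree

wf   <- initial_wavefunction(m)
obs  <- grid_observables(split_operator_propagate(wf, m, fs_to_au(0.01),
                                                  3500), m)
cmpr <- compare_to_grid(res, obs)
cat(sprintf("max |TSH - quantum| population deviation: %.4f\n",
            cmpr$max_dev))
#> max |TSH - quantum| adiabatic population deviation: 0.0344
```

The wave packet splits at the crossing into a ~43/57 branching; the
surface-hopping ensemble with FMi decoherence tracks the exact adiabatic
populations to within a few percent and is internally consistent (the
averaged quantum populations agree with the fractions of trajectories on
each surface).  `plot(res)` draws the population and coherence traces.

A command-line front end is installed at `inst/exec/surfhop`
(`sample` / `run` / `quantum` / `analyze` / `compare` subcommands, YAML
configs; see `inst/extdata/avoided_crossing_fmi.yml` and `?cli_main`).

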