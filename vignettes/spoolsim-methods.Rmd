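---
title: "Modeling sperm chromatin spooling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sperm chromatin spooling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

During spermiogenesis, the haploid genome is repacked from nucleosomal
chromatin into an ultracompact, liquid-crystalline arrangement of thick
protamine-bound fibers, while the nucleus itself elongates from a sphere
into a needle. `spoolsim` models this as the interplay of three
ingredients:

1. **The chromatin fiber** — a single bead-spring polymer of `N_m`
   monomers of diameter `sigma` = 30 nm (about 12-15 kbp each). Bonds
   are harmonic with stiffness `k_chrom` = 15 eps/sigma^2; excluded
   volume between non-contiguous monomers is a *soft* repulsion of
   finite barrier `eps_chrom` = 5 eps,
   `U(r) = eps_chrom [1 + (r/sigma)^12 (6 r^2/sigma^2 - 7)]` for
   `r < sigma`. The finite barrier (together with the finite bond
   stiffness) lets strands occasionally cross — a deliberate emulation
   of moderate topoisomerase activity that makes large-scale
   reorganization reachable on simulation timescales. Bending is the
   standard angular potential `U = k_bend (1 - cos theta)`, with `theta`
   the deviation from collinearity of a monomer triplet; in the stiff
   regime this gives a persistence length `l_p = k_bend sigma / kB T`,
   so the terminal stiffness `k_bend` = 50 eps corresponds to
   `l_p` = 1.5 um.

2. **The nuclear envelope** — a polymerized elastic shell: `N_v`
   vertices on a sphere of radius `R`, joined by harmonic springs along
   the edges of the Delaunay triangulation (computed as the convex hull
   of the vertex lattice), with stiffness `k_memb` = 2500 eps/sigma^2
   (about 11 mN/m in SI units) and topology fixed for the whole
   simulation, mimicking the cross-linked lamina. Unconnected vertex
   pairs repel through a truncated-shifted Lennard-Jones potential of
   radius `r0`; monomer-vertex pairs repel with radius
   `Sigma = r0 + sigma`, which closes the mesh to the chain.

3. **The unit system** — `sigma` is the length unit, `eps = kB T` at
   293 K the energy unit, monomer mass `m` = 1 and `tau =
   sigma sqrt(m/eps)` the time unit. `to_si()` converts (the force unit
   is ~0.135 pN, so the maximal polar force 2e5 eps/sigma is ~27 nN).

The full-scale parameterization simulates `N_m` = 10,000 monomers — a
fraction `f` = 10% of the genome — in an envelope of radius
`R = R_round f^(1/3)` = 0.7 um that preserves the chromatin
concentration of the 1.5-um round-spermatid nucleus, with `N_v` = 5560
vertices and rest length `r0 = (8 pi R^2 / sqrt(3) N_v)^(1/2)` = 36 nm.

## The developmental protocols

* **Relaxation**: the flexible (`k_bend` = 0) chain is grown as a dense
  self-avoiding walk and relaxed until its radial density is flat.
* **Uniform rigidification**: `k_bend` ramps linearly from 0 to its
  terminal value on every triplet — the null model of a genome-wide,
  spatially homogeneous histone-to-protamine transition. It yields a
  disordered "yarn ball" with wall accumulation.
* **Nucleated rigidification**: motivated by the centrally nucleated,
  spreading pattern of H4 acetylation, monomers within
  `d_nucleation` = 150 nm of the nucleus center are tagged first (about
  2% of the chain), their triplets ramp to full stiffness, then each
  rigid domain grows by `N_spread` = 10 monomers per side and the cycle
  repeats; domains merge on collision and untagged triplets stay at
  exactly zero stiffness. A triplet is treated as tagged when all three
  of its monomers are tagged, which keeps the "untagged triplets stay
  soft" rule exact. This pathway produces the ordered *spool*: strong
  local alignment winding around a common axis, with near-zero bulk
  nematic order because the winding directions cancel globally.
* **Elongation**: two antipodal pole vertices are selected along the
  stretch axis; the pole receives an outward force `F`, each of its
  topological neighbors `F/2`, antisymmetrically at the other pole, and
  `F` ramps linearly to `F_max` over ~50 increments. Because an
  irregular triangulation gives the two poles different neighbor counts
  (degrees 5-7), the prescribed pattern can leave a net resultant of
  order `F`; the assembled force field subtracts it uniformly over all
  vertices (~`F/N_v` per vertex) so the nucleus does not drift.
* **Twist**: a single geometric transformation rotating particles
  about the long axis by `twist_total (z - z_min)/(z_max - z_min)`
  (total 10 pi), followed by relaxation. `apply_twist()` implements the
  literal field over all particles; the reduced-scale pipeline applies
  it to the chromatin only (`particles = "chain"`) — the envelope is
  axisymmetric about the twist axis, so rotating its material points
  leaves the confinement geometry unchanged while loading the coarse
  spring mesh with shear it cannot absorb (see Limitations) — and
  settles the torsional shock at reduced `dt` before relaxing normally.
* **Decondensation**: all external forces are released and the envelope
  recovers towards its spherical elastic reference state; the aspect
  ratio trace is recorded.

## Scaled-down study conditions

The published protocol runs O(10^10) total MD steps at `N_m` = 10,000 on
GPUs; that scale is not reproduced here. Instead every quantitative
study in the tests and the acceptance script uses a reduced system with
the governing dimensionless groups preserved:

| group | meaning | value |
|---|---|---|
| `N_m (pi/6) sigma^3 / V` | chain volume fraction | 0.10 |
| `l_p / R` | stiffness vs confinement | 2.14 |
| `d_nucleation / R` | nucleation geometry | 0.214 |
| `F_max / (k_memb R)` | polar force vs shell elasticity | 3.43 |

The canonical reduced profile (`scaled_params(sim_params(), n_m = 1000,
n_v = 560)`) therefore uses `R` = 10.8 sigma, `k_bend_max` = 23.2 eps,
`d_nucleation` = 2.3 sigma and `F_max` = 9.3e4 eps/sigma. The force
scaling follows from the shell's force/extension response, which is
proportional to its 2D elastic modulus (~`k_memb`) times its size.
Protocol step counts (see `default_schedules()`) total a few 1e6 steps;
convergence is always asserted on observables — density flatness after
relaxation, the alignment plateau along the force ramp — never on step
counts.

One artifact of the reduction is geometric: the monomer-vertex
exclusion `Sigma = r0 + sigma` is proportionally fatter at a coarser
mesh (`Sigma/R` = 0.25 at `N_v` = 560 vs 0.09 at full scale), so
monomer centers only reach ~`R - Sigma`. Radial density profiles of
reduced systems are therefore normalized by this *accessible radius*
(`accessible_radius()`); bulk/surface alignment keeps the standard
`0.85 R` threshold, which at reduced scale simply classifies almost all
bonds as bulk.

## Numerical choices

* **Integrator**: BAOAB-splitting Langevin at `kT` = 1, `gamma` =
  1/tau, `dt` = 0.005 tau (the stiffest spring gives `omega dt` =
  0.25; the step-size guard refuses `dt > 1/sqrt(k_max)`). With
  `gamma` = 0 the scheme reduces to velocity Verlet and conserves
  energy to < 1e-4 relative over 1e4 steps, which is tested.
* **Determinism**: one counter-derived xoshiro256++ stream per
  `md_run()` call, seeded from `params$seed` and the state's call
  counter; identical states and seeds give bitwise-identical
  trajectories.
* **Neighbor search**: per-interaction-class Verlet lists (chain-chain,
  vertex-vertex, monomer-vertex) over linked-cell grids, skin 0.7
  sigma, rebuilt when any particle moves half a skin; equality with the
  brute-force O(N^2) evaluation is tested to 1e-10.
* **Force capping**: the Lennard-Jones magnitude is frozen below
  `0.05 x` its exclusion radius to guard against overflow from rare
  pathological overlaps; cap events are counted and reported.
* **Velocity ceiling during forced stages**: at the upper end of the
  force ramp the pole mesh is strongly stretched and a monomer can
  slip deep into a vertex's exclusion zone, receiving a kick that
  would otherwise run away within one step. Forced protocol stages
  therefore clamp particle speeds at 30 sigma/tau (~17x thermal), a
  safety valve in the spirit of limited-displacement integrators; clamp
  events are counted, and equilibrium observables are unaffected in
  unforced stages where the clamp never engages.
* **Envelope rest lengths**: a single rest length `r0` applied to a
  quasi-uniform lattice whose realized edge lengths spread ~10-15%
  leaves the shell frustrated, and it visibly wrinkles and deflates at
  `kT`. Each spring therefore rests at its initial-state edge length
  (mean equal to the nominal `r0` within ~1%), which keeps the relaxed
  shell within ~0.5% of its nominal radius; the literal uniform-`r0`
  variant remains available (`system_state(envelope_rest =
  "uniform")`).
* **Vertex lattice**: a deterministic Fibonacci spiral, evened out by
  Laplacian smoothing on the sphere against the running triangulation
  (`relax_sphere_lattice()`); deterministic placement keeps the
  topology seed-independent.
* **Nucleus center**: the instantaneous envelope centroid, well defined
  under fluctuations and drift.
* **Twist application point**: by default the twist is applied at the
  end of the force ramp (it can be applied at any elongation level by
  truncating the pipeline), and it is purely geometric — no sustained
  torque is modeled, matching the geometric reading of the published
  protocol.

## Quantification

* **3D order**: the Landau-de Gennes Q-tensor
  `Q = <(3 t t' - I)/2>` over normalized bond vectors; the alignment
  parameter is `alpha = 2(lambda3 - lambda2)/3` of its ascending
  eigenvalues, which is 0 for both isotropic and planar-degenerate
  distributions (hence ~0 for an ideal spool, whose winding directions
  span a plane of the shell at each point) and 1 for uniaxial order.
  `local_alignment()` partitions the nucleus into equal-volume shells
  subdivided into octant sectors — the sector resolution is what makes
  a spool's *local* order visible while its pooled shell average
  cancels. `bulk_surface_alignment()` pools bonds below/above `0.85 R`.
  Empty elements are skipped and empty shells reported as missing, not
  as zero.
* **Density**: monomer counts in equal-volume shells normalized by the
  mean concentration; monomers beyond the nominal radius count in the
  outermost shell so the volume-weighted mean is exactly 1.
* **Persistence length**: tangent-tangent correlations over frames,
  exponential fit against contour separation on the window where the
  correlation exceeds `e^-2`; a rigid-rod-like window (less than half
  a decade of decay) is flagged unreliable. The contour scale is the
  *realized* mean bond length — at backbone stiffness 15 eps/sigma^2
  the 3D harmonic bonds stretch to ~1.13 sigma at `kT`, and ignoring
  this understates `l_p` by ~12%. Because the large-lag correlations
  of a single stiff chain are dominated by one slow whole-chain
  bending mode, the parameter-recovery study pools a dozen replicas
  initialized directly from the Boltzmann bond-angle distribution and
  fits lags up to 40 bonds, recovering the nominal 1.5 um within a
  few percent.
* **2D image order**: gradients from a cubic B-spline interpolation
  model (recursive prefilter, spline derivative kernel), structure
  tensor smoothed with a Gaussian window of 4 px, orientation from the
  minor eigenvector, weights = coherence x energy with pixels below 1%
  of the maximal energy excluded as background. The angular
  distribution `P(theta)` (180 bins over an axial period) feeds the 2D
  nematic order parameter `S2d`, the largest eigenvalue of
  `int P(theta) (2 t t' - I) dtheta`.

## What the synthetic fixtures do and do not show

`make_ideal_spool()`, `make_axial_bundle()`, `make_twisted_bundle()`
and `make_random_coil()` have closed-form orientation statistics, and
`render_section()` turns any configuration into a micrograph-like image
(disk splatting at 6 px per fiber diameter, Gaussian PSF, Gaussian
noise). They validate the analysis stack end to end: stripe and bundle
orientations are recovered within one histogram bin, isotropic controls
give `S2d` < 0.1, and rendering then analyzing closes the
simulation-to-image loop. They are *not* realistic electron
micrographs: contrast formation, staining heterogeneity, sectioning
artifacts and detector noise are absent, so passing these tests
validates the pipeline's mathematics, not its robustness to real TEM
imagery.

## Known limitations

* No hydrodynamics, no nucleoplasmic crowders, no electrostatics, and
  no chiral (cholesteric) interaction — twist enters only geometrically.
* The envelope cannot remodel its topology; pores and lamina turnover
  are out of scope.
* At the upper end of the force ramp the pole mesh opens wider than the
  monomer-vertex exclusion diameter, so confinement near the pole tips
  is imperfect at full force — a property shared by the model's
  parameterization at any scale, handled numerically by the velocity
  ceiling.
* **The torsional field needs the chain gauge at reduced scale.**
  Applying the literal all-particle 10 pi field instantaneously tears
  the coarse, pole-stretched mesh (the shear deposited per spring
  exceeds what the network can absorb), while incremental application
  lets the torsion elastically unwind between increments — nothing
  pins it azimuthally, and the untwisting time shrinks with system
  size. Twisting the chromatin alone (equivalent confinement, see the
  protocol section) followed by a reduced-`dt` settling phase is
  stable and reproduces the lateral compaction: the transverse
  gyration radius of the fiber drops by ~8% over the relaxation
  window, against ~1% for a no-twist control evolved over identical
  step counts. The imprinted chirality itself still decays within
  ~1e4 steps, so the compaction at this scale is a modest, transient
  remnant of the full-scale effect.
* Reduced systems reproduce regimes (through the dimensionless groups
  above), not trajectories; quantitative observables carry finite-size
  noise of order a few percent.
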