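---
title: "krigwater: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{krigwater: model, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`krigwater` builds a machine-learned force field for water in which every
atomic property — the three atomic energies that sum to the intramolecular
potential, and the 3 × 9 real spherical multipole components that drive the
intermolecular electrostatics — is an independent kriging (Gaussian process
regression) model over the monomer's internal coordinates. This vignette
records the model, the assumptions behind it, and the numerical decisions a
maintainer would want to know about.

## The model

**Features.** A water monomer has three internal degrees of freedom, so the
feature vector is simply `(r₁, r₂, θ)`: the two O–H bond lengths (Å) and
the H–O–H angle (radians, converted to degrees only at I/O boundaries).
This set is complete and exactly rotation/translation invariant, which the
test suite verifies directly by applying random rigid motions. General
atomic local-frame feature machinery for larger molecules is deliberately
out of scope.

**Kriging.** Each property is modelled as
`Y(f) = μ + Σⱼ aⱼ exp(−Σₕ θₕ |fₕ,ⱼ − fₕ|^pₕ)` with a constant trend.
The absolute value in the kernel keeps it well defined for non-even
exponents. Hyperparameters are fitted by maximising the standard
concentrated log-likelihood
`−(N/2)·ln σ̂² − ½·ln det R` (with the trend mean and process variance
eliminated analytically) using global-best particle swarm optimisation over
`log₁₀ θₕ ∈ [−3, 3]` and, when requested, `pₕ ∈ [0.5, 2]`. Swarm settings
(40 particles, 300 iterations, inertia 0.72, cognitive/social 1.49) are
conventional; a stagnation rule (stop after 60 iterations without
improvement of the global best) is this package's own addition and only
shortens runs whose optimum has already been located. A constant response
short-circuits to `μ = y₁`, all weights zero, with the likelihood capped at
a large finite value (the degenerate `σ̂² = 0` case).

**Electrostatics.** Moments are trained in body-fixed local frames so they
are pure functions of the features; at evaluation time they are rotated to
the laboratory frame and contracted with interaction tensors. The pair
energy sums `Q_{l_A m_A} T Q_{l_B m_B}` over the rank pairs admitted by the
truncation rule `L = l_A + l_B + 1`: charge–charge at L = 1; plus
charge–dipole at L = 2; plus charge–quadrupole, dipole–dipole and their
mirror terms at L = 3. The tensors are implemented through the exact
Cartesian equivalents (charge, dipole vector, traceless quadrupole) of the
Racah-normalised real spherical components, with fixed linear maps between
the two representations; the rank-2 rotation goes through the Cartesian
round trip rather than hand-coded Wigner matrices. Tests validate the
tensors against point-charge-array limits (a dipole as a ±q pair, a
quadrupole as a linear three-charge array) with the expected O(d²)
convergence.

**Local axis frames.** The frame convention (nothing in the interface
depends on it, but reproducibility does): oxygen — x along the H–O–H
bisector, z along (O→H1) × (O→H2), y completing the right-handed set;
hydrogen — x from H toward O, z normal to the molecular plane. The frames
are smooth functions of the positions away from collinearity, and their
analytic position-derivatives enter the force evaluation. Because the
monomer is planar, all moment components odd in the local z axis vanish,
which makes the sign ambiguity of the plane normal immaterial.

**Forces.** Forces are fully analytic: the kriging feature-space gradient
(requires all `pₕ = 2`; other exponents make the predictor non-smooth at
training points and are rejected), chained through the Wilson B-matrix of
the features; the Cartesian derivatives of the interaction tensors; and the
moment-derivative terms, which split into a frame-rotation part (present
even with frozen moments — it transmits torques) and a
feature-polarization part (the geometry dependence of the kriged moments).
Every term is checked against central finite differences, and the total
force sums to zero to machine precision because every ingredient is
translation invariant.

## The surrogate labelling oracle

The generator emulates the *statistical shape* of a quantum labelling
pipeline, not its physics:

* an intramolecular PES
  `E = Morse(r₁) + Morse(r₂) + ½k_θΔθ² + k_rr Δr₁Δr₂ + k_rθ(Δr₁+Δr₂)Δθ`
  with its minimum exactly at r = 0.9619 Å, θ = 105.05°. Defaults
  (D = 494 kJ/mol, a = 2.28 Å⁻¹, k_θ = 420 kJ/mol/rad²,
  k_rr = −100 kJ/mol/Å², k_rθ = 70 kJ/mol/Å/rad) give water-like
  frequencies with the bend far below the stretches and the asymmetric
  stretch above the symmetric one (k_rr < 0);
* a smooth per-atom partition (oxygen takes the bend plus half of each
  Morse and coupling term; each hydrogen half its own Morse term and a
  symmetric share of the couplings) that sums *exactly* to the molecular
  energy and swaps correctly under H-exchange. Any smooth partition with
  these properties exercises the machinery equally well; no claim is made
  that it equals a quantum-topological partition;
* geometry-dependent local-frame moments around a mean hydrogen charge of
  0.55 e (so q_O ≈ −1.1 e), with hydrogen-exchange covariance and zero
  z-odd components; charge noise with a default scale chosen so that about
  5 % of configurations exceed the 0.001 e net-charge filter; and
  log-normal per-atom integration errors L(Ω) placing roughly 10 % of
  configurations above the tighter 0.00005 Ha threshold.

Energies carry **no** noise, so energy-model quality reflects pure
interpolation error. What passing tests therefore show is that the
sampling–filtering–training–simulation machinery is correct and
well-conditioned on a smooth, low-dimensional, water-like surface; they say
nothing about basis-set effects, partition noise correlations, or any other
feature of real quantum labels.

## Numerical choices

* **Nugget.** The kernel matrix is a correlation matrix (unit diagonal), so
  the regulariser is an absolute jitter, 1e-8 by default, escalated by
  factors of 10 to at most 1e-6 on Cholesky failure (with a warning). A
  variance-scaled nugget was rejected: for small-variance moment components
  it collapses toward machine precision, the maximum-likelihood optimum
  then sits at near-singular correlation matrices with kriging weights of
  order 1e10, and prediction roundoff (≈ machine epsilon × the weight
  scale) contaminates forces and energy conservation. The absolute nugget
  bounds the weights — hence the roundoff of predictions and analytic
  gradients — uniformly across properties of any scale. The price is that
  training-point residuals are `−nugget·aⱼ` rather than strictly zero;
  the interpolation tests assert exactly that identity.
* **Sampling distribution.** The per-mode displacement amplitudes are
  uniform, scaled (via a linearised estimate with a 25 % overshoot) so the
  20 % constraint is active, with rejection of violating candidates.
  Uniform-in-constraint is a stand-in choice — the sampling temperature is
  genuinely open — and maximises coverage of the allowed box.
* **Normal modes.** Central-difference Hessian (step 1e-4 Å),
  mass-weighted with O = 15.999 u, H = 1.008 u; the six near-zero
  rigid-body eigenvalues are discarded and a seed whose gradient norm
  exceeds 1e-6 kJ/mol/Å is rejected as non-stationary.
* **Units.** Å, fs, u, kJ/mol, e and radians internally. With this set the
  acceleration prefactor is exactly 1e-4 (kJ/mol and u share Avogadro's
  number), and the Coulomb factor is 1389.35457644 kJ mol⁻¹ Å e⁻².
* **Cutoffs.** The Lennard-Jones potential is shifted to zero at its 10 Å
  cutoff; the force uses the unshifted derivative, accepting a tiny force
  discontinuity there. The 30 Å direct-space electrostatic cutoff has no
  switching: by design it exceeds any simulated cluster's diameter, so it
  never truncates in intended use. Energy-conservation checks use a bound,
  hydrogen-bonded dimer start (`water_dimer_state()`) for exactly this
  reason — a dissociating pair that drifts across the cutoff would see a
  spurious discontinuity that says nothing about the integrator.
* **Rigid mode.** Internal geometry is frozen by a mass-weighted Kabsch
  reset to the equilibrium template each step, with the positional
  correction fed back into the velocities; local moments are predicted
  once and reused (global moments still rotate with each molecule, so
  orientation torques survive). Temperature accounting switches to
  6 N_mol − 3 degrees of freedom.
* **RDF normalisation.** A cluster has no box density, so the ideal-gas
  reference uses the uniform "gyration sphere" (radius √(5/3)·R_g per
  frame) *including* the exact finite-sphere pair-distance factor
  γ(r) = 1 − 3r/(4R) + r³/(16R³); an ideal gas then gives g(r) = 1 at
  every r, and the flat-RDF invariant holds genuinely rather than only for
  r ≪ R. Peak positions are independent of the convention; heights are
  not, and the convention is recorded in every result object.
* **Histogram modes.** The mode is the centre of the maximum-count bin;
  ties break toward smaller values.
* **Finite-difference verification.** Gradient checks compare against
  central differences at step 1e-5 Å. For the kriging models the reference
  difference is accumulated per training point (weights × kernel
  differences) to avoid cancellation across the large weights, and errors
  are measured relative to the force scale of the test set, since a
  per-configuration ratio is ill-defined where the true gradient passes
  through zero.
* **Degenerate inputs.** Collinear geometries, O–H bonds below 0.3 Å,
  non-orthogonal rotation matrices, local-frame moments passed where
  global ones are required, missing labels, oversized training requests and
  non-finite forces all raise immediate, specific errors; an MD energy
  blow-up truncates the trajectory at the last good frame with a warning.

## Problem sizes

The test suite and the reproduction script use ensembles of a few hundred
to 2 500 configurations, training sets of 20–250 points, clusters of 1–25
molecules, a 10 ps NVE dimer run at dt = 0.1 fs and thermostatted cluster
runs of a few ps at dt = 1 fs. These sizes were chosen so the full
monomer-to-cluster workflow — including its slowest invariant checks —
runs comfortably on a single CPU while still exercising every code path at
physically meaningful scale; larger clusters (the `run_simulation()`
default menu extends to 216 molecules) and longer trajectories use the
same code unchanged.

## Known limitations

* Free-space clusters only: no Ewald summation, no periodic boundaries.
* Moments to rank 2 and interactions to L = 3; higher ranks would need
  additional tensors and rotation machinery.
* The Lennard-Jones parameters are taken as given (lightly tuned for
  cluster stability), not optimised against the electrostatics — cluster
  structure is therefore expected to be over-bound relative to real water,
  and RDF peak *heights* depend on the cluster normalisation convention.
* The surrogate oracle is not a quantum-chemistry replacement; conclusions
  about real water require real labels.
* Kriging exponents other than 2 disable analytic forces (and hence MD);
  exponent optimisation is available for model-quality studies only.
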