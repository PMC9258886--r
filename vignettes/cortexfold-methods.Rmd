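---
title: "cortexfold: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cortexfold: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cortexfold)
```

This vignette is the package's own account of the science it implements:
the coupled neuronal-migration / volumetric-growth model, the parameters
that matter, the numerical machinery, and the choices we made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The model

### Kinematics and elasticity

The tissue deforms with gradient **F**, multiplicatively decomposed into a
stress-free growth part and an elastic part, **F** = **F**ᵉ**F**ᵍ, with
J = JᵉJᵍ. Growth is transversely isotropic about the referential radial
glial fiber direction **N** (a unit vector, fixed in the reference
configuration; its deformed image n = **F N** is derived output):

$$\mathbf{F}^g = \vartheta^{\parallel}(c)\,\mathbf{N}\otimes\mathbf{N} +
  \vartheta^{\perp}(c)\,(\mathbf{I}-\mathbf{N}\otimes\mathbf{N}),\qquad
  \vartheta^{\parallel} = 1 + k^{\parallel} c,\quad
  \vartheta^{\perp} = 1 + k^{\perp} c,$$

where $c=\sum_{i=1}^{3}c_i$ is the **total** spatial neuron density
(μm⁻³). The linear coupling does not saturate; we implement it verbatim
and rely on the dilution feedback (below) for boundedness. Stress follows
the compressible neo-Hookean energy
$\psi = \tfrac{\mu}{2}(\operatorname{tr}\mathbf{C}^e - 3 - 2\ln J^e) +
\tfrac{L}{2}\ln^2 J^e$ with Cauchy stress
$\mathbf{T} = \tfrac{1}{J^e}\left[\mu \mathbf{B}^e +
(L\ln J^e - \mu)\mathbf{I}\right]$; only elastic deformation induces
stress, and the test suite verifies the closed-form stress against central
finite differences of the energy at 100 random states.

### Cell-density balance

Each cohort obeys, in referential (fixed-mesh) form,
$\dot c_{0i} = F^c_i + \operatorname{Div}\mathbf{Q}_i$ with
$c_{0i} = J c_i$, $F^c_i = J f^c_i$, $\mathbf{Q}_i = J\mathbf{F}^{-1}
\mathbf{q}_i$, and the spatial flux

$$\mathbf{q}_i = -c_i\,\hat H\!\left(\tfrac{c_i-c_0}{c_0};\alpha_c\right)
  \hat v_i(r)\,\frac{\mathbf{n}}{\lVert\mathbf{n}\rVert} + D\,
  \operatorname{grad} c_i .$$

The activation argument is the *normalized* excess density
$(c_i-c_0)/c_0$: with the dimensionless sensitivity $\alpha_c = 0.1$ an
unnormalized argument (densities of order 10⁻⁵ μm⁻³) would pin the
logistic at ½ everywhere, whereas the normalized form spans its sigmoid
over roughly 0–40 threshold units, which is the physically meaningful
range.

All spatial profiles are functions of the **referential** radius: the
destination radii δᵢᵛ = 191.6–222.7 μm lie below R₀ = 239 μm, i.e. they
are material positions, and the neurogenic-zone profile is written in
material coordinates from the outset. The neurogenic profile
$\tilde G^x(r) = \hat H(\delta^x - r;\alpha_G)$ is ≈1 *inside* the
ventricular zone (r < 0.2 R₀) and decays outside it; the velocity profile
$\hat v_i(r) = v_i\hat H(\delta_i^v - r;\alpha_v) - 0.5\,v_i$ is
+vᵢ/2 well inside the destination, exactly zero there, and −vᵢ/2 beyond,
so cells are herded toward the destination from both sides (the negative
branch is retrograde advection, implemented literally). Smoothing
parameters α_G, α_v, α_k, α_μ carry units μm⁻¹ (transition width ~1/α);
α_c alone is dimensionless. This is the only unit assignment under which
every transition width is physically sensible.

### Parameters

Every model constant is held by `model_parameters()`, whose defaults are
the calibrated ferret set: threshold c₀ = 10⁻⁶ μm⁻³, α_c = 0.1,
R₀ = 239 μm, δˣ = 0.2 R₀, α_G = 0.05 μm⁻¹, birth days (0, 3, 6) with
temporal half-width ε = 2 d, α_v = 0.05 μm⁻¹, growth/stiffness transitions
at 0.93 R₀ with α_k = α_μ = 1 μm⁻¹, μ_s = 1 kPa, ν = 0.45, L_s = 9.3 kPa,
β_μ = 3, β_k = 1, Gᶜ = 1.41×10⁻⁵ μm⁻³ d⁻¹, vᵢ = 1472.2 μm/d,
δᵛ = (191.6, 210.7, 222.7) μm, D = 31612.6 μm² d⁻¹, k_s = 202950 μm³,
τ = 27 d. Two deliberate conventions: L(r) scales with the shear-modulus
profile (spatially uniform Poisson ratio — the minimal assumption given
that only ν and L_s are specified), and L_s keeps its printed value
9.3 kPa even though 2μν/(1−2ν) with μ_s = 1 kPa, ν = 0.45 gives 9.0 kPa;
we prefer fidelity to the stated constant over internal rederivation, and
nothing downstream is sensitive to the 3 % difference.

## 2. Numerics

### Geometries

*Bar.* The calibration geometry is a bar of length R₀ with unit
cross-section, 60 brick elements by default, one end fixed and the long
faces on symmetry conditions, so the solution is 1-D along the length and
tangential growth is switched off (k⊥ = 0). Mechanical equilibrium then
admits the closed form Fᵉ = I (homogeneous growth of a laterally
constrained bar is stress-free), which the Newton solver reproduces to
round-off — a strong regression anchor.

*Half disc.* The folding geometry is a plane half disc meshed in a
butterfly layout (a structured half-square core plus body-fitted rings, so
no element degenerates at the center), with 4-node quadrilaterals and
2×2 Gauss quadrature. Two mesh decisions matter:

* the outer rings are graded toward the surface so the stiff cortical film
  (outer ~7 % of the radius) holds about three element layers — an
  unresolved film cannot bend, and the buckling instability is silently
  suppressed;
* the core/ring balance is constrained (0.4 m ≤ n_r ≤ 1.3 m) because
  degenerate layouts (two rings, or a nine-node arc) pass element-count
  targets while being useless for folding.

The out-of-plane direction carries **zero elastic strain** (Fᵉ₃₃ = 1): the
thickness simply follows the growth stretch. Enforcing total plane strain
instead (F₃₃ = 1) would compress three-dimensional growth elastically by
1/ϑ⊥ ≈ 1/3 and distort the in-plane energetics beyond recognition.

### Elements and solver

Displacement elements with analytic consistent tangent (verified against
finite differences of the assembled residual to ~10⁻⁷ relative). At
ν = 0.45 the ratio L/μ ≈ 9 makes fully integrated quads lock
volumetrically; the volumetric energy term L ln Jᵉ is therefore integrated
through an element-mean (B-bar) gradient operator, the isochoric and
ground terms at the full 2×2 points. Without this treatment the tangent
stays positive definite up to tangential film-growth mismatches of 2.6 —
i.e. the discretization never buckles; with it the bifurcation appears
where a film-on-substrate estimate predicts it (mismatch ≈ 1.3 at
stiffness ratio 3). Nonlinear solves use full Newton (relative residual
10⁻⁸, 25 iterations), warm-started from the previous step, with
growth-increment halving (up to 32 substeps) on failure.

### Transport discretization

Backward Euler in time (default Δt = 0.05 d; halved automatically on
solver failure), linear elements on the fixed reference mesh, activation
nonlinearity by two Picard sweeps, and optimal exponential-fitting
streamline upwinding (ξ = coth Pe − 1/Pe) that vanishes at small cell
Péclet number — diffusion-only runs are unpolluted, which the
heat-equation oracle in the suite checks at 1 % L². Zero-flux boundaries
are natural in the weak form, and because the shape functions partition
unity the discrete scheme conserves cell number *exactly* up to the linear
solver: the conservation test holds to 10⁻⁶ per step with advection and
diffusion active. Negative densities from the transport operator are
clipped to zero and the clipped mass is logged; on the default run it is
orders of magnitude below the 0.1 % budget.

### Coupling

The time loop is staggered: advance densities (using the previous step's
deformation for J and n), update the growth state from the total density,
re-solve equilibrium. The spatial density driving growth is the
referential density diluted by the *growth* volume, c = c₀/Jᵍ, solved
pointwise by damped fixed-point iteration (for the bar this is exact,
since Jᵉ = 1 there). Using the full mechanical J instead couples the lag
of the staggered scheme to elastic compression: an element squeezed by a
growing neighbor sees its apparent density rise and grows harder — a
spurious positive feedback that blows up at coarse Δt. Excluding the
elastic volume change (|Jᵉ−1| is a few percent before buckling) removes
the instability at the cost of a second-order modeling approximation.

Buckling needs a trigger: the outer-surface nodes are perturbed radially
by deterministic uniform white noise of amplitude 10⁻³ R₀ from a fixed,
documented seed, so symmetry breaking is reproducible and two runs of the
same configuration are bitwise identical.

## 3. Calibration

The genome is {Gᶜ, vᵢ, δ₁ᵛ, δ₂ᵛ, δ₃ᵛ, D, k_s}. Bounds for Gᶜ, vᵢ and D
are the literature ranges (10⁻⁶–1.5×10⁻⁵ μm⁻³d⁻¹, 230–4752 μm/d,
25000–35000 μm²/d). No published range exists for the destinations or the
growth parameter; we use δᵛ ∈ [0.6, 0.98] R₀ (destinations must lie in the
cortical-plate side of the material domain) and k_s ∈ [10⁵, 3.2×10⁵] μm³
(bracketing the calibrated value with a log-width comparable to the D
range). These were fixed once, before any recovery experiment.

The GA itself is a standard real-coded design — the published account
specifies only "10 genomes per generation" and a convergence-by-plateau
idea — so the operators are ours: elitism of 1, tournament size 2, BLX-0.5
blend crossover (p = 0.9), per-gene Gaussian mutation (p = 0.2, sd = 10 %
of range), bounds clipping, destination genes kept sorted, ≤40
generations, convergence when the best objective improves by <10⁻³ over
10 generations. Forward evaluations are cached by genome; a failed forward
run scores 10⁶ and is logged. An `expand_bounds` option widens the
initial-population ranges by 50–125 % to reproduce the robustness
experiment.

Three modes: `three_cohort` (8 density terms, w₁ = 11/8, w₂ = 11/3),
`leave_out_t3` (the last timepoint withheld for validation; weights
unchanged), and `single_cohort` (one cohort, single destination, fit to
summed densities; w₁ = 11/3 so the three density terms and three length
terms stay balanced in the same way). In single-cohort mode the Gᶜ upper
bound is raised to 5×10⁻⁵ μm⁻³d⁻¹: one cohort must supply the production
of three, so the per-cohort literature cap cannot apply — and the suite
checks the recovered single-cohort Gᶜ indeed exceeds the three-cohort
truth.

Profiles are resampled to 60 points on the normalized domain before norms
are taken (the published account is silent on the grid; 60 matches the
element count of the bar).

## 4. The synthetic-data generator

`generate_profile_dataset()` runs the bar forward model at the generating
parameters (the calibrated defaults unless overridden), samples the 8
(cohort, timepoint) profiles at days 8.5 / 16.5 / 27 — the midpoints of
the reported imaging-age ranges mapped onto the 0–27 d simulation window —
and the 3 domain lengths, then applies measurement noise. The default
noise model is Poisson counting on the neuron number per profile bin
(ROI width 451 μm ≈ ten subcell widths, section thickness 50 μm), which is
the measurement actually performed on micrographs; a multiplicative
Gaussian option exists for stress tests. The cohort-3/timepoint-1 pair is
intentionally absent, mirroring the eight-profile layout of the study
design. `generate_neuron_table()` inverts the profiling workflow
(inhomogeneous Poisson sample along the ROI), and the round trip
profile → points → subcell binning → profile closes within three standard
errors per bin.

What the generator does *not* emulate: GFP-positive fiber artifacts
(bright non-neuronal streaks that real counting must ignore), optical
effects, section-to-section variability, or tissue shrinkage. Passing
recovery tests on these data therefore demonstrates the *inverse
machinery* — identifiability of the seven parameters from clean model
output — not robustness to real imaging pathology.

## 5. Problem sizes used by the tests

The suite runs the bar at its production resolution (60 elements,
Δt = 0.05 d; results are unchanged at 240 elements and Δt = 0.01 d).
GA recovery uses Δt = 0.1 d for both the data generator and the forward
model, 10 genomes and 30 generations; all seven parameters come back
within 8.5 % of the truth, comfortably inside the 15 % (25 % for D)
acceptance bands. The folding sweep runs at ~640 elements with Δt = 0.1 d
and early termination one day after onset; the onset orderings are
identical at ~1150 elements.

## 6. Known limitations and open discrepancies

* **Domain-length magnitude.** With the calibrated default parameters the
  bar grows from 239 μm to ≈758/744/746 μm at days 8.5/16.5/27
  (mesh- and timestep-converged). The experimental ROI lengths it is
  natural to compare with are 1390/1997/2390 μm — a *rising* trajectory.
  Two structural facts prevent the model as specified from reproducing
  that: (i) total labeled-neuron production
  Gᶜ·∫G̃ˣ·Σᵢ∫G̃ᵗᵢ·J̄ ≈ 1.4×10⁻² μm⁻² falls an order of magnitude short of
  the ≈10⁻¹ μm⁻² needed for a mean stretch of 10, because advection
  (~736 μm/d) drains the ventricular zone in under a day, keeping its
  volume amplification J̄ near 1.2; and (ii) ~85 % of the Lorentzian birth
  pulses are spent by day 8.5, so every parameterization we scanned
  (Gᶜ ×2–10, k_s ×2–10, vᵢ/4, ε = 4) yields a flat-to-declining length
  after the first timepoint, never a rising one. We implement the
  equations faithfully and report the computed lengths as they are.
* **Default-parameter folding.** The same production shortfall leaves the
  default half-disc film at ~18 % hoop compression, below the ~25 %
  critical strain of a stiffness-ratio-3 film, so the default
  configuration does not buckle within 27 d. Stronger production (e.g.
  Gᶜ ×3) folds around day 10; larger β_μ or β_k fold progressively
  earlier, and those orderings are exactly the qualitative trends the
  sweep tests assert.
* **Wavelength vs stiffness ratio.** Because stiffer-cortex runs buckle
  *earlier* (with less accumulated growth and arc length), the normalized
  wavelength measured at each run's own onset frame mildly decreases with
  β_μ in our sweeps, and the discrete mode number locks at k = 8 or 12 on
  these meshes. The wavelength decrease with β_k is robust.
* **Self-contact** after deep folding is not modeled; runs are meaningful
  up to and modestly past onset. The one-eighth-sphere 3-D configuration
  is out of scope.
* The growth law ϑ = 1 + k c is linear and unbounded; boundedness in
  practice comes entirely from dilution (c = c₀/Jᵍ).
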