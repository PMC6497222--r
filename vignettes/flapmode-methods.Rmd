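---
title: "Modal effective mass analysis of running bipeds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modal effective mass analysis of running bipeds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flapmode)
```

## The physical model

`flapmode` treats a running biped as a star-topology lumped vibrating
structure. The body is one point mass; each appendage (wing, leg, tail,
neck/head) is another, attached to the body by a linear spring that stands
in for the joint's muscles, tendons and ligaments. Leg masses are
additionally connected to the ground through foot springs, which is where
running enters: the feet prescribe a periodic vertical displacement, so
the system is base-excited through the leg DOFs. Every mass moves only
vertically.

This is deliberately the coarsest model that can answer the question
*which whole-body oscillations can running excite*. The vertical-only
restriction is motivated by finer (finite-element) analyses of the same
animal geometry, in which lateral effective masses are negligible; rolling
of the torso, 3-D joint kinematics, soft-tissue viscoelasticity and
aerodynamic loads are all outside this model (see *Limitations*).

The packaged fixture is the seven-DOF *Caudipteryx* model: masses
(2.4, 0.5, 0.5, 0.2, 0.2, 0.5, 0.7) kg for (body, wings, legs, tail,
neck/head), joint stiffnesses 200 N/m per wing, 650 N/m per leg, 800 N/m
each for tail and neck, and 1000 N/m per foot spring. These stiffnesses
are stored as the fixture's named constants; they are the unique star
assembly consistent with the model's published stiffness matrix (body
diagonal 3300 = 200+200+650+650+800+800, leg diagonal 1650 = 650+1000).
Assembly follows the standard pattern for springs between DOF pairs: each
body–appendage spring adds `k` to both diagonals and `−k` to the
off-diagonals; ground springs add only to the leg diagonal. Non-star
couplings are rejected rather than silently accepted, because the
assembly pattern (and the symmetry-pair bookkeeping built on it) is
defined only for star models.

## Modal analysis and effective mass

With diagonal positive-definite **M**, the generalized eigenproblem
`K φ = ω² M φ` is whitened to the symmetric ordinary problem
`M^(-1/2) K M^(-1/2)` and solved with a symmetric eigensolver. This
guarantees a real, non-negative spectrum for positive semidefinite **K**
and **M**-orthonormal eigenvectors at machine precision; no unsymmetric
inversion `M⁻¹K` is ever formed. Rigid-body modes of ungrounded models
come out as ω = 0 and are reported, not dropped. Eigenvalues within
`1e-9` (relative) of zero are clipped to zero to absorb roundoff.

Mode shapes are mass-normalized (`φᵀMφ = 1`) and signed so the
largest-magnitude component is positive. The sign of a participation
factor is normalization-dependent, so tables report |Γ|.

For an influence vector **r** — the rigid-body displacement pattern of the
base motion, all-ones for uniform vertical ground displacement — the
participation factor is `Γᵢ = φᵢᵀ M r` (generalized mass is 1 under mass
normalization) and the effective mass `m_eff,i = Γᵢ²`. Completeness,
`Σ m_eff = rᵀ M r`, is checked by the pipeline at `1e-8` relative and is
the package's strongest internal consistency test: it holds for any
influence vector, and equals total mass for **r** = 1.

### Mode classification

Each left/right appendage pair contributes a symmetry verdict per mode:
*symmetric* if the two components agree within `1e-6` of the mode's
largest component, *antisymmetric* if they negate, *mixed* otherwise;
components below the tolerance are neutral. A mode is *excitable* when
its effective mass exceeds a threshold, defaulting to 5% of total mass —
on the fixture this cleanly separates the one dominant mode (93% of total
mass) from the rest, and leaves truly inert (Γ = 0) modes inert under any
reasonable threshold. A *flapping* mode is an excitable mode whose wing
pair moves in phase with amplitude exceeding the body's.

Nearly degenerate eigenvalue clusters (relative gap `< 1e-6`) of symmetric
models are rotated, via an SVD of their projection onto the antisymmetric
subspace, so that each column lies in the symmetric or antisymmetric
subspace before labeling; this makes classification stable when, e.g.,
two identical wing pairs produce coincident antisymmetric eigenvalues.
Degenerate clusters that still defy the split are labeled *mixed*.

## From frequency to running speed

Footfall forcing at running speed `v` repeats every stride, so the
default mapping is `v = f × stride_length` with stride = 2 × step. This
convention is the one consistent with the fixture's published
frequency–speed pairs; the alternative step-rate convention (left and
right feet as separate excitation events) is selectable via
`gait_params(excitation = "step")`. The Froude number `Fr = v²/(g·h)`
bounds plausible running: `froude_max_speed()` returns
`√(Fr_max · g · h)`. The fixture uses Fr_max = 17 and hip height
0.384 m (back-solved so the ceiling lands on the model's nominal 8 m/s
maximum running speed; hip height is a required user input in general).
Allometric mass estimation from bone measurements is intentionally not
implemented — total mass is a direct input.

## Damped forced response

Natural modes are computed undamped. The package quantifies why that is
legitimate: with modal ratio ζ the damped frequency is `ω√(1−ζ²)`, a
0.5% shift at ζ = 0.1, and FRF peak locations drift under 1% for
ζ ≤ 0.1. Damping matters only for amplitudes.

* **Damping spec.** Default is uniform modal ζ = 0.05 — a conservative
  value for joint soft tissue, safely inside the "small damping" regime.
  A Rayleigh option (`C = αM + βK`, implied `ζᵢ = α/2ωᵢ + βωᵢ/2`) exists
  for users needing a physical damping matrix.
* **FRF.** Base displacement of amplitude `u` enters as force `k_ground·u`
  at each leg DOF (in phase, or sign-split left/right for alternating
  footfalls); the steady state is the direct complex solve
  `(K − w²M + iwC)X = F₀` per grid frequency. Zero damping in any mode is
  refused — the resonant response would be unbounded.
* **Time integration.** Newmark average acceleration (β = 1/4, γ = 1/2),
  implicit and unconditionally stable, with the effective stiffness
  factorized once (Cholesky). The step defaults to 1/60 of the shortest
  period present and steps coarser than 1/50 are refused; records must
  cover ≥ 20 forcing cycles, and the first half of every record is
  discarded as transient before amplitudes are measured. The footfall
  waveform is a pure sinusoid by default, with a raised-cosine pulse train
  (duty 0.4) as a more footfall-like option; the choice is recorded in
  the output metadata.
* **Sinusoid-sum waveforms.** Measured flapping-angle traces are commonly
  summarized as `Σ aⱼ sin(ωⱼt + pⱼ)`. Fitting uses variable projection:
  only the frequencies are optimized numerically (Nelder–Mead from
  multiple starts seeded by distinct periodogram peaks plus random
  jitter, seeded explicitly, default seed 0), while amplitudes and phases
  are recovered by linear least squares on the sin/cos basis for every
  candidate frequency set. Non-convergence returns the best candidate
  with a warning flag rather than failing.

## Interval uncertainty

Fossil-derived inputs are ranges, not numbers. `interval_box()` carries
intervals for segment masses, joint stiffnesses, a global mass scale and
step length; `interval_modal_bounds()` propagates them two ways and
reports both:

* **Vertex enumeration** evaluates all `2^p` box corners (refused for
  p > 16). For frequencies monotone in each parameter over the box — true
  of the physical ranges treated here, and cross-checked by the sampling
  pass — the corner extrema are outer bounds.
* **Seeded uniform sampling** (default 2000 points) gives inner bounds;
  an inner bound escaping the vertex interval flags non-monotonicity.

Across the box, modes are matched to the nominal model's modes by
mass-weighted shape overlap (greedy assignment on |Φᵀ M Φ_nom|), not by
raw eigenvalue order, so crossing branches do not scramble intervals.
Speed intervals are the exact positive-interval product of frequency and
stride intervals. Nominal values are always contained, and boxes nest:
a sub-box's intervals lie inside its parent's.

## Synthetic model families

The generators exist so every stage is testable without external data:

* `caudipteryx_model()` is the canonical fixture, also shipped as a YAML
  config that round-trips bit-exactly (numerics serialized at up to 17
  significant digits).
* `generate_scaled_model()` rescales all segment masses proportionally
  (2–10 kg is the family of interest), holding stiffness fixed, so every
  frequency obeys `ω ∝ 1/√c` exactly — the analytic law the scaling study
  asserts. Part-by-part mass redistributions of the original scaled
  family are not published, so proportional scaling is a declared
  stand-in: only the monotone trend (heavier ⇒ lower flapping frequency
  and speed) is asserted, never specific endpoint frequencies.
* `generate_random_model()` draws mirror-symmetric star models (first
  pair grounded legs, further pairs wings, optional tail/neck) with
  log-uniform stiffnesses to cover decades evenly; fully determined by
  its seed.

What the generators emulate is the *structure* of the problem — star
topology, left/right symmetry, grounded legs, realistic mass/stiffness
decades. What they do not emulate: measured anatomical mass
distributions, nonlinear joints, ground contact intermittency. Passing
property tests therefore demonstrates correctness of the mechanics and
bookkeeping, not fidelity of any particular animal reconstruction beyond
the packaged fixture.

## Numerical choices and test scale

Tolerances: stiffness symmetry must hold to `1e-9` relative (hard
failure); mass-orthonormality and K-diagonalization are asserted at
`1e-8`; completeness at `1e-10` relative; the exact mass-scaling law at
`1e-10`. The property suite runs 100 random models for
orthogonality/completeness/symmetry sweeps, 20 random boxes for interval
nesting, and characteristic-polynomial cross-checks at n ≤ 4 (the
polynomial is interpolated in a scaled eigenvalue variable for
conditioning, then rooted independently of the eigensolver). Forced-
response cross-checks integrate ~40 drive cycles at 1/60-period steps;
these sizes keep the whole suite under a minute on one core while leaving
each statistical check far from its tolerance boundary.

## Limitations

* Vertical DOFs only; no torso pitch/roll, no lateral motion.
* Linear springs and viscous damping; no contact, impact or muscle
  activation dynamics.
* The damped eigenproblem is never solved; damping enters only through
  modal ratios or Rayleigh coefficients.
* Interval bounds are guaranteed outer bounds only under per-parameter
  monotonicity (checked empirically by the sampling pass), not by
  rigorous global optimization.
* Aerodynamics of feathered wings — lift, drag, added mass — are entirely
  out of scope; the model speaks to excitation of flapping motion, not to
  flight.
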