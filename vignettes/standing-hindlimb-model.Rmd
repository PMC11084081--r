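---
title: "Static optimization of muscle forces in the standing equine hindlimb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static optimization of muscle forces in the standing equine hindlimb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equistand)
```

## The model

`equistand` estimates the forces of the muscles and patellar ligaments of
the proximal equine hindlimb in square standing, and turns them into a
femoral load case for finite-element analysis. The chain of reasoning is
classical inverse statics followed by static optimization:

1. **External loads.** In square standing, the only external forces are
   gravity and the ground reaction. Each hindlimb carries a fraction
   (default 20%) of body weight as a vertical ground reaction force (GRF)
   at the center of the hoof, and the limb itself is split into five
   subunits — thigh, crus, metatarsus, hind pastern, hind hoof — each with
   a mass fraction of body mass and a center of mass.

2. **Net joint moments.** For each joint (coxofemoral, femorotibial,
   femoropatellar) the net moment is the sum of `(p − c) × F` over every
   external force `F` applied at `p` distal to that joint with center of
   rotation `c`. The femoropatellar moment is set to zero: the patella
   carries no appreciable gravitational load. These moments are what the
   musculature must cancel for the limb to stand still.

3. **Moment-balance system.** Every muscle and patellar ligament is a line
   actuator: one to three attachment points, a unit line of action, a
   physiological cross-sectional area (PCSA), and a maximum isometric
   force. Its moment coefficient about a spanned joint is the weighted sum
   of `τ × r̂` over its attachment points (`τ` = lever arm from the joint
   center, `r̂` = unit direction). Stacking three rows per joint gives
   `A F = M` with one column per actuator — more unknowns than equations.

4. **Static optimization.** The redundancy is resolved by minimizing
   `U = Σ (F_i / PCSA_i)³` subject to `A F = M` and physiological box
   bounds. The cubic PCSA-normalized cost is a standard
   efficiency/endurance criterion: it penalizes muscle *stress*, so large
   muscles take proportionally more load and extreme stresses are avoided.

5. **Contact forces and the FEA handoff.** Joint contact force is the sum
   of the intersegmental force at the joint and the muscle forces crossing
   it. Femur-attached actuators with solved forces above 100 N become the
   FEA load case, each force uniformly distributed over a labeled
   attachment area, with the condylar supports as boundary conditions.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `body_mass` | 514 | kg | subject mass; scales GRF and gravity loads |
| `fraction` | 0.2 | — | hindlimb share of body weight in square standing |
| `g` | 9.81 | m/s² | gravitational acceleration |
| segment mass fractions | `nauwelaerts_defaults()` | — | thigh 0.035, crus 0.015, metatarsus 0.0035, pastern 0.0015, hoof 0.002 of body mass |
| `tonus` | 0.01 | — | lower force bound as a fraction of maximum isometric force (resting muscle tonus) |
| `sdf_fraction` | 0.9 | — | GRF fraction as the superficial digital flexor's floor (passive hock-stabilizing apparatus) |
| `threshold` | 100 | N | femoral load-case cutoff; roughly 10 kg-force, below which loads do not materially change femoral stresses |
| `sigma0` | 3e5 | Pa | nominal maximum isometric muscle stress, used only to scale the solver's internal activation variables |

The segment mass fractions deserve a note: published equine segment-inertia
tables report the hindlimb subunits at a few percent of body mass, dominated
by the thigh. The shipped defaults are such order-of-magnitude values,
normalized to a plausible total hindlimb mass share (~5.7%), and are an
editable configuration rather than a constant — any study-specific table
can be passed through the `segments` data.frame. All inverse-statics
operations are exact in whatever fractions are supplied.

The coordinate convention is a single right-handed frame in meters with +z
vertically up and gravity along −z; `g` is configurable. Joint-span sets
are explicit input data rather than inferred from geometry: which muscles
produce moments at which joints is an anatomical judgement (attachments
*and* lines of action), and silent inference would be error-prone.

## The solver

The cost `U` is strictly convex for `F ≥ 0` (the tonus floors keep muscle
forces positive, so no modulus is needed despite the odd exponent), which
makes any KKT point the unique global optimum. `solve_forces()` works in
dimensionless activations `a_i = F_i / (PCSA_i · σ₀)` so the cubic is
well-conditioned, row-normalizes the equality constraints, and then:

- runs an **augmented Lagrangian** over the equalities with box-constrained
  L-BFGS-B inner solves, starting from the midpoint of the bounds
  (deterministic — no random restarts);
- **polishes** the iterate with damped Newton steps on the reduced KKT
  system of the free (non-bound-active) activations, which drives the
  stationarity and feasibility residuals to machine precision;
- certifies the result with `kkt_residual()`: equality multipliers are
  fitted by least squares on the free coordinates and the gradient is
  projected onto the feasible directions at the bounds; the relative norm
  of that projection is reported alongside the solution.

Tolerances: relative constraint feasibility 1e−8 and relative optimality
(KKT) 1e−8; convergence is declared only with both. In practice the polish
reaches ~1e−15 on both. If the moment targets are unreachable within the
bounds, the solver reports `converged = FALSE` with the minimal-residual
iterate as an infeasibility certificate rather than silently returning a
poor fit.

Degenerate inputs are handled explicitly: all-zero constraint rows with
nonzero targets are reported as structurally infeasible; duplicated
actuators (identical columns and PCSA) split the force equally because the
cost is strictly convex in each coordinate; actuators spanning no listed
joint simply contribute zero columns.

An independent **brute-force oracle** (`brute_force_oracle()`, ≤ 4
actuators) provides the cross-check in the test suite: grid points over the
force box are projected onto the constraint subspace, and candidates are
refined by exact 1-D convex minimization along nullspace directions
(cyclic passes, with a penalized simplex search first when the nullspace
has more than one dimension). The two paths share no code and agree to
well within 0.1% in objective on every tested instance.

## The synthetic-limb generator

Subject-specific geometry (attachment coordinates from a full 3-D skeletal
model) is external input data; to make every stage testable on its own,
`generate_limb()` builds seeded synthetic instances with the same
*structure*:

- a three-joint serial chain (coxofemoral → femorotibial → femoropatellar)
  with the five standard segments and a hoof contact point;
- `n_actuators` line actuators with lever arms drawn in 0.02–0.15 m about
  each spanned joint, PCSA in 5–50 cm², and maximum forces
  `PCSA · 3e5 Pa` ≈ 150–1500 N — the force scale of real equine hindlimb
  muscles (10²–10³ N); about 15% are ligaments (zero lower bound), and a
  share of actuators span two adjacent joints;
- in the default **reference mode**, reference forces `F_ref` are drawn
  strictly inside the bounds and the moment targets are set to
  `A · F_ref`. This guarantees feasibility by construction and provides the
  testable certificate `U(F_opt) ≤ U(F_ref)`. Moments derived instead from
  the synthetic gravity loads could be unreachable under the tonus floors,
  which is why that is a separate **gravity mode**, used for the
  inverse-statics tests. In reference mode the femoropatellar rows of
  `A F_ref` are generally nonzero; the femoropatellar-zero rule applies to
  gravitationally derived moments only.

The joint spacing of the synthetic chain is compressed (~0.1 m) relative
to a real hindlimb so that a two-joint actuator can sit within lever-arm
range of both joints; no anatomical realism is claimed, and none is needed
for what the tests establish. What passing tests show is that the
*machinery* — moment assembly, bounds, solver, certificates, serialization
— is correct on problems of the right shape, scale and redundancy. They do
not validate the anatomical inputs (attachment coordinates, PCSA tables,
span sets) that a real analysis stands or falls with.

Determinism: the generator seeds R's Mersenne-Twister (inversion normals)
locally and restores the caller's RNG state, so the same seed yields the
identical instance on any platform.

## Design choices on genuinely open points

- **Cross-product order.** The moment of a unit force along `r̂` applied at
  lever `τ` is `τ × r̂`; printed conventions sometimes reverse the factors.
  The package uses `τ × r̂` everywhere and computes net moments with the
  same convention, so the equality system is internally consistent; the
  overall sign convention cancels out of the solution.
- **Lever-arm side.** For an actuator crossing a joint, the attachment on
  the segment distal to that joint carries the lever arm. The default is
  the insertion-side point(s); `origin_side_joints` overrides this per
  (actuator, joint) when the origin is the distal attachment.
- **Multi-point insertions.** A broad insertion (e.g. the tensor fasciae
  latae, approximated by three points) is one actuator whose single force
  magnitude is split across attachment points by stated weight fractions
  (default equal); the moment coefficient is the weight-averaged cross
  product.
- **Direction overrides.** Curved muscles (biceps femoris,
  semitendinosus, semimembranosus) use a near-insertion direction instead
  of the origin–insertion chord; this is a per-actuator `dx,dy,dz` field,
  normalized on use.
- **Ligaments in the cost.** The patellar ligaments carry an effective
  area in the PCSA slot so they participate in the objective, and a zero
  lower bound (they cannot be actively recruited). This is an explicit
  modeling assumption; the lateral patellar ligament solving to zero force
  is consistent with it.
- **Contact-force directions.** The muscle term of a joint's contact force
  uses each actuator's single global line of action (not a per-joint-side
  direction); with the single-line actuator model there is only one
  direction available, and the choice is documented rather than silent.
- **"Exceeds 100 N"** is read strictly: a force of exactly 100.0 N is
  excluded from the load case.
- **Safety factors** are rounded half away from zero to one decimal,
  matching how such ratios are printed in engineering reports (base R's
  banker's rounding would turn 4.95 into 4.9).
- **Patellofemoral center.** For standing, the femoropatellar articulation
  is reduced to a single contact point supplied as a landmark; the package
  does not attempt to construct it from surface geometry.

## Problem sizes used in the checks

The packaged checks run the solver-vs-oracle comparison on 50 seeded
instances of 2–4 actuators (half of them one-joint four-actuator instances
with a genuinely redundant nullspace) and the feasibility/recovery study on
200 seeded 20-actuator limbs; these sizes exercise determined, redundant
and bound-active regimes while keeping a full run in tens of seconds. The
same quantities are recomputed by `scripts/acceptance.R`.

## Known limitations

- Static analysis only: no inertial terms, no gait, no recovery-from-
  anesthesia peak loads. The standing assumption is the design case for
  primary implant stability, not an envelope of worst-case loading.
- Static optimization cancels antagonistic co-contraction by construction,
  so joint contact forces are systematically *underestimated*; downstream
  implant design should apply safety margins accordingly.
- Attachment sites are single points (or three weighted points) and lines
  of action are straight; no wrapping surfaces or via points, and no
  moment arms from tendon excursion.
- The stifle's patellar locking mechanism is not modeled; muscles attached
  to the patella compensate for it in the optimization, which can inflate
  their solved forces relative to EMG evidence.
- Reproducing subject-specific published force tables requires the
  corresponding geometry and load inputs (attachment coordinates, segment
  masses, PCSA values); the package ships the machinery and a reference
  force table, not those proprietary inputs.
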