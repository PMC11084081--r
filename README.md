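# equistand

Static musculoskeletal analysis of the proximal equine hindlimb in square
standing: inverse-statics net joint moments, cubic-cost static optimization
of the redundant muscle forces, joint contact force estimation, and export
of femoral load cases for downstream finite-element analysis (FEA).

## The problem

Femoral fracture fixation in adult horses demands implants that survive the
loads of standing during recovery, yet the in vivo loading of the equine
femur is essentially unmeasured. A tractable surrogate is a static model of
the standing hindlimb: the ground reaction force (each hindlimb carries
about 20% of body weight at the hoof center) and the gravity loads of the
limb segments (thigh, crus, metatarsus, hind pastern, hind hoof) produce
net moments at the coxofemoral (hip), femorotibial (stifle) and
femoropatellar joints that the muscles must cancel:

```
M_joint = sum over forces distal to the joint of (p - c_joint) x F
```

Each muscle or patellar ligament is a line actuator with attachment points,
a unit line of action `r̂`, and a moment coefficient `tau x r̂` per joint it
spans (`tau` = lever arm from the joint's center of rotation). Stacking the
three joints gives an underdetermined linear system in the force
magnitudes `F`:

```
A F = M,    A[3j:3j+3, i] = sum_k w_k (tau_ik x r̂_i)
```

The redundancy is resolved by minimizing the cubic cost normalized by
physiological cross-sectional area (PCSA), a standard efficiency criterion
that penalizes high muscle stress:

```
min U = sum_i (F_i / PCSA_i)^3
s.t.  A F = M,   lower_i <= F_i <= upper_i
```

with physiological bounds: upper = maximum isometric force, lower = 1% of
it (resting tonus); the superficial digital flexor gets a floor of 90% of
the ground reaction force (hock-stabilizing mechanism); ligaments have a
lower bound of zero. Joint contact forces follow as the sum of the
intersegmental force and the muscle forces crossing the joint; muscles that
attach to the femur and exceed 100 N, distributed uniformly over labeled
attachment areas, form the FEA load case together with condylar boundary
conditions (medial condyle fixed, lateral condyle constrained
proximodistally and anteroposteriorly).

`U` is strictly convex over the nonnegative orthant, so the KKT point the
solver returns is the global optimum; the package certifies it with a
projected-gradient residual and cross-checks it against an independent
brute-force oracle in the test suite.

## Worked example

```r
library(equistand)

# a seeded synthetic limb: 3-joint chain, 20 actuators, feasible targets
inst <- generate_limb(seed = 42, n_actuators = 20)
an   <- standing_analysis(inst$geometry, inst$loads,
                          moments = inst$moments, bounds = inst$bounds)

an$solution$status
#> [1] "converged"
an$solution$moment_residual_rel
#> [1] 1.351932e-16
an$contacts
#>            joint         fx        fy        fz magnitude_N
#> 1    coxofemoral -699.28042 -215.6724 1748.6616   1895.6068
#> 2   femorotibial   91.72847 -792.7214  600.9766    998.9966
#> 3 femoropatellar -277.26996 -821.9567  103.9549    873.6693
```

The solution satisfies moment balance to machine precision and its cubic
cost never exceeds that of the feasible reference forces the generator
built the targets from. Contact magnitudes are in newtons; for a 514 kg
horse the standing ground reaction is `ground_reaction(514, 0.2)` =
1008.5 N per hindlimb.

Reporting on a published solved force table:

```r
ref <- standing_forces_reference()
group_sum(ref, quadriceps_heads())
#> [1] 951
safety_factor(-1074, -348)   # implant compressive safety factor
#> [1] 3.1
nrow(select_femoral_loads(ref, threshold = 100))  # muscles handed to FEA
#> [1] 8
```

## What it does not do

No CT segmentation, meshing, or finite-element solving: the package ends at
the load-case handoff (JSON + CSV). No dynamics — standing statics only.
Static optimization cancels antagonistic co-contraction, so joint contact
forces are conservative (under)estimates.
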