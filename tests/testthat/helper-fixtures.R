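# Shared fixtures: tiny hand-checkable geometries and rigid-motion helpers.

# One actuator pulling straight down at a lever of 0.1 m from a single
# spanned joint at the origin (two other joints present but unspanned).
single_actuator_geometry <- function(direction = c(0, 0, -1),
                                     lever = c(0.1, 0, 0)) {
  limb_geometry(
    joints = data.frame(name = c("coxofemoral", "femorotibial",
                                 "femoropatellar"),
                        x = c(0, 0.5, 0.6), y = 0, z = c(0, -0.4, -0.35)),
    actuators = data.frame(
      name = "solo", kind = "muscle",
      ox = lever[1] - direction[1], oy = lever[2] - direction[2],
      oz = lever[3] - direction[3],
      ix = lever[1], iy = lever[2], iz = lever[3],
      pcsa_m2 = 1e-3, fmax_N = 300, fmin_N = 3,
      spans = "coxofemoral", attaches_femur = TRUE, area_label = "a1"),
    segments = data.frame(name = "thigh", mass_fraction = 0.035,
                          x = 0.1, y = 0, z = -0.2),
    body_mass = 514, hoof_contact = c(0.1, 0, -1))
}

# Three actuators about one joint, hand-checkable cross products.
toy_three_actuator_geometry <- function() {
  limb_geometry(
    joints = data.frame(name = c("coxofemoral", "femorotibial",
                                 "femoropatellar"),
                        x = c(0, 1, 1.2), y = 0, z = c(0, -0.5, -0.45)),
    actuators = data.frame(
      name = c("a", "b", "c"),
      kind = "muscle",
      ox = c(0.10, 0.00, 0.05), oy = c(0, 0.08, 0.02),
      oz = c(0.50, 0.40, 0.60),
      ix = c(0.10, 0.00, 0.05), iy = c(0, 0.08, 0.02),
      iz = c(0.05, -0.03, 0.04),
      pcsa_m2 = c(2e-3, 1e-3, 3e-3),
      fmax_N = c(600, 300, 900),
      fmin_N = c(6, 3, 9),
      spans = "coxofemoral",
      attaches_femur = c(TRUE, FALSE, TRUE),
      area_label = c("a1", "a2", "a3")),
    segments = data.frame(name = "thigh", mass_fraction = 0.035,
                          x = 0.2, y = 0, z = -0.2),
    body_mass = 514, hoof_contact = c(0.05, 0, -1))
}

# Independent cross product via the determinant cofactor formula (kept
# deliberately distinct from the package's implementation).
cross_oracle <- function(a, b) {
  c(det(matrix(c(a[2], a[3], b[2], b[3]), 2)),
    -det(matrix(c(a[1], a[3], b[1], b[3]), 2)),
    det(matrix(c(a[1], a[2], b[1], b[2]), 2)))
}

# Deterministic random rotation matrix (QR with positive diagonal, det +1).
random_rotation <- function(seed) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_points <- function(df, cols, R, t) {
  p <- as.matrix(df[, cols])
  p <- p %*% t(R) + matrix(t, nrow(p), 3, byrow = TRUE)
  df[, cols] <- p
  df
}

# Apply the rigid motion x -> R x + t to a geometry (free direction vectors
# rotate without translating).
transform_geometry <- function(geom, R, t = c(0, 0, 0)) {
  g <- geom
  g$joints <- rigid_points(g$joints, c("x", "y", "z"), R, t)
  g$segments <- rigid_points(g$segments, c("x", "y", "z"), R, t)
  a <- g$actuators
  a <- rigid_points(a, c("ox", "oy", "oz"), R, t)
  a <- rigid_points(a, c("ix", "iy", "iz"), R, t)
  for (pts in list(c("p2x", "p2y", "p2z"), c("p3x", "p3y", "p3z"))) {
    has <- !is.na(a[[pts[1]]])
    if (any(has)) a[has, pts] <- rigid_points(a[has, pts, drop = FALSE],
                                              pts, R, t)[, pts]
  }
  has_d <- !is.na(a$dx)
  if (any(has_d)) {
    d <- as.matrix(a[has_d, c("dx", "dy", "dz")]) %*% t(R)
    a[has_d, c("dx", "dy", "dz")] <- d
  }
  g$actuators <- a
  g$hoof_contact <- drop(R %*% geom$hoof_contact) + t
  g
}

transform_loads <- function(loads, R, t = c(0, 0, 0)) {
  segs <- loads$segment_forces
  segs <- rigid_points(segs, c("x", "y", "z"), R, t)
  f <- as.matrix(segs[, c("fx", "fy", "fz")]) %*% t(R)
  segs[, c("fx", "fy", "fz")] <- f
  external_loads(grf = drop(R %*% loads$grf),
                 grf_point = drop(R %*% loads$grf_point) + t,
                 segment_forces = segs)
}

# Small instance with genuine redundancy: all actuators about one joint
# (3 constraint rows, n columns), so for n = 4 the nullspace is nonempty
# and the cubic cost actually selects among feasible distributions.
redundant_instance <- function(seed, n = 4L) {
  set.seed(seed)
  joints <- data.frame(name = c("coxofemoral", "femorotibial",
                                "femoropatellar"),
                       x = c(0, 0.4, 0.5), y = 0, z = c(0, -0.3, -0.25))
  rows <- lapply(seq_len(n), function(i) {
    p <- runif(3, -0.1, 0.1)
    repeat {
      v <- runif(3, -1, 1)
      if (sqrt(sum(v^2)) > 0.1) break
    }
    o <- p + 0.25 * v / sqrt(sum(v^2))
    pcsa <- runif(1, 5e-4, 5e-3)
    data.frame(name = sprintf("r_%02d", i), kind = "muscle",
               ox = o[1], oy = o[2], oz = o[3],
               ix = p[1], iy = p[2], iz = p[3],
               pcsa_m2 = pcsa, fmax_N = 3e5 * pcsa,
               fmin_N = 0.01 * 3e5 * pcsa,
               spans = "coxofemoral", attaches_femur = TRUE,
               area_label = sprintf("ar_%02d", i))
  })
  geom <- limb_geometry(joints, do.call(rbind, rows),
                        data.frame(name = "thigh", mass_fraction = 0.035,
                                   x = 0.1, y = 0, z = -0.2),
                        body_mass = 514, hoof_contact = c(0.1, 0, -1))
  bounds <- default_bounds(geom$actuators, grf_magnitude = 0)
  f_ref <- bounds$lower + runif(n, 0.1, 0.9) * (bounds$upper - bounds$lower)
  names(f_ref) <- geom$actuators$name
  A <- assemble_system(geom)$A
  M <- matrix(drop(A %*% f_ref), nrow = 3,
              dimnames = list(c("x", "y", "z"), joints$name))
  list(geometry = geom, bounds = bounds, reference_forces = f_ref,
       moments = net_moments(M, source = "reference"))
}

pcsa_of <- function(geom) {
  stats::setNames(geom$actuators$pcsa_m2, geom$actuators$name)
}

solve_instance <- function(inst, control = list()) {
  sys <- assemble_system(inst$geometry)
  solve_forces(sys, inst$moments, pcsa_of(inst$geometry), inst$bounds,
               control)
}
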