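test_that("default bounds implement tonus, maxima, ligament and SDF rules", {
  acts <- data.frame(
    name = c("M. gluteus medius", "M. superficial digital flexor",
             "Lig. patellae laterale"),
    kind = c("muscle", "muscle", "ligament"),
    fmax_N = c(100, 5000, 800),
    fmin_N = NA_real_)
  b <- default_bounds(acts, grf_magnitude = 1008.5)
  expect_equal(b$lower, c(1, 0.9 * 1008.5, 0))
  expect_equal(b$upper, c(100, 5000, 800))
  expect_equal(b$provenance, c("tonus", "sdf_grf", "ligament"))

  # explicit fmin overrides with provenance "custom"
  acts$fmin_N[1] <- 40
  b2 <- default_bounds(acts, grf_magnitude = 1008.5)
  expect_equal(b2$lower[1], 40)
  expect_equal(b2$provenance[1], "custom")

  # rule-induced lower above the maximum is an infeasible-bound error
  acts3 <- data.frame(name = "M. superficial digital flexor",
                      kind = "muscle", fmax_N = 500, fmin_N = NA_real_)
  expect_error(default_bounds(acts3, grf_magnitude = 1008.5),
               "infeasible bounds.*superficial digital flexor")
})

test_that("a fully determined single-actuator system solves exactly", {
  geom <- single_actuator_geometry()
  sys <- assemble_system(geom)
  # coefficient block for unit force; pick F_target inside the bounds
  F_target <- 120
  M <- drop(sys$A %*% F_target)
  bounds <- default_bounds(geom$actuators, grf_magnitude = 0)
  sol <- solve_forces(sys, M, pcsa_of(geom), bounds)
  expect_true(sol$converged)
  expect_equal(unname(sol$forces), F_target, tolerance = 1e-9)
  expect_equal(sol$objective, (F_target / 1e-3)^3, tolerance = 1e-9)
  expect_lt(sol$kkt, 1e-8)
})

test_that("solver matches the brute-force oracle on a printed toy fixture", {
  geom <- toy_three_actuator_geometry()
  sys <- assemble_system(geom)
  bounds <- default_bounds(geom$actuators, grf_magnitude = 0)
  # target built from a feasible interior reference force
  f_ref <- c(200, 100, 400)
  M <- drop(sys$A %*% f_ref)
  sol <- solve_forces(sys, M, pcsa_of(geom), bounds)
  ora <- brute_force_oracle(sys, M, pcsa_of(geom), bounds)
  expect_true(sol$converged)
  expect_equal(ora$status, "ok")
  expect_lt(abs(sol$objective - ora$objective) / abs(ora$objective), 1e-3)
  expect_lte(sol$objective, sum((f_ref / geom$actuators$pcsa_m2)^3) + 1e-6)
})

test_that("infeasible targets yield a minimal-residual report, not a bogus fit", {
  geom <- single_actuator_geometry()
  sys <- assemble_system(geom)
  M <- drop(sys$A %*% 1e5)  # far above fmax = 300 N
  bounds <- default_bounds(geom$actuators, grf_magnitude = 0)
  sol <- solve_forces(sys, M, pcsa_of(geom), bounds)
  expect_false(sol$converged)
  expect_match(sol$status, "infeasible")
  # minimal-residual certificate: force pinned at the upper bound
  expect_equal(unname(sol$forces), 300, tolerance = 1e-6)
  ora <- brute_force_oracle(sys, M, pcsa_of(geom), bounds)
  expect_equal(ora$status, "infeasible")
})

test_that("scaling all PCSA leaves the argmin unchanged and scales the cost", {
  inst <- generate_limb(104, 12)
  sys <- assemble_system(inst$geometry)
  pcsa <- pcsa_of(inst$geometry)
  sol1 <- solve_forces(sys, inst$moments, pcsa, inst$bounds)
  c_scale <- 3
  sol2 <- solve_forces(sys, inst$moments, c_scale * pcsa, inst$bounds)
  expect_true(sol1$converged && sol2$converged)
  expect_equal(sol2$forces, sol1$forces, tolerance = 1e-6)
  expect_equal(sol2$objective, sol1$objective / c_scale^3,
               tolerance = 1e-6)
})

test_that("duplicated actuators split the force equally", {
  geom <- single_actuator_geometry()
  a <- geom$actuators
  a2 <- rbind(a, a)
  a2$name <- c("twin1", "twin2")
  geom2 <- limb_geometry(geom$joints, a2, geom$segments, geom$body_mass,
                         geom$hoof_contact)
  sys <- assemble_system(geom2)
  M <- drop(assemble_system(geom)$A %*% 200)
  bounds <- default_bounds(geom2$actuators, grf_magnitude = 0)
  sol <- solve_forces(sys, M, pcsa_of(geom2), bounds)
  expect_true(sol$converged)
  expect_equal(sol$forces[["twin1"]], sol$forces[["twin2"]],
               tolerance = 1e-6)
  expect_equal(sol$forces[["twin1"]] + sol$forces[["twin2"]], 200,
               tolerance = 1e-6)
})

test_that("tightening bounds behaves monotonically", {
  inst <- generate_limb(222, 10)
  sys <- assemble_system(inst$geometry)
  pcsa <- pcsa_of(inst$geometry)
  sol <- solve_forces(sys, inst$moments, pcsa, inst$bounds)
  expect_true(sol$converged)

  free_i <- which(sol$active_bounds == "free")[1]
  expect_false(is.na(free_i))
  b2 <- inst$bounds
  # raise an inactive lower bound to just below the solved force
  b2$lower[free_i] <- (b2$lower[free_i] + sol$forces[free_i]) / 2
  sol2 <- solve_forces(sys, inst$moments, pcsa, b2)
  expect_equal(sol2$forces, sol$forces, tolerance = 1e-5)

  lower_i <- which(sol$active_bounds == "lower")[1]
  if (!is.na(lower_i)) {
    b3 <- inst$bounds
    b3$lower[lower_i] <- b3$lower[lower_i] +
      0.2 * (b3$upper[lower_i] - b3$lower[lower_i])
    sol3 <- solve_forces(sys, inst$moments, pcsa, b3)
    if (sol3$converged) {
      expect_gte(sol3$objective, sol$objective * (1 - 1e-9))
    }
  }
})

test_that("the KKT residual is (near) zero at the optimum and larger elsewhere", {
  # 15 actuators against 9 constraint rows: genuinely redundant, so the
  # reference point is feasible but not stationary
  inst <- generate_limb(42, 15)
  sys <- assemble_system(inst$geometry)
  pcsa <- pcsa_of(inst$geometry)
  sol <- solve_forces(sys, inst$moments, pcsa, inst$bounds)
  expect_true(sol$converged)
  r_opt <- kkt_residual(sol, sys, pcsa, inst$bounds)
  expect_lt(r_opt, 1e-8)

  # feasible (reference) but non-optimal point
  fake <- structure(list(forces = inst$reference_forces),
                    class = "force_solution")
  r_ref <- kkt_residual(fake, sys, pcsa, inst$bounds)
  expect_gt(r_ref, r_opt)
  expect_gt(r_ref, 1e-4)
})

test_that("analytic single-actuator solutions have zero KKT residual", {
  geom <- single_actuator_geometry()
  sys <- assemble_system(geom)
  M <- drop(sys$A %*% 150)
  bounds <- default_bounds(geom$actuators, grf_magnitude = 0)
  sol <- solve_forces(sys, M, pcsa_of(geom), bounds)
  expect_lt(kkt_residual(sol, sys, pcsa_of(geom), bounds), 1e-10)
})
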