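test_that("lever arms are attachment minus joint center", {
  expect_equal(lever_arm(c(0.1, 0, 0), c(0, 0, 0)), c(0.1, 0, 0))
  expect_equal(lever_arm(c(0.3, -0.2, 1), c(0.3, -0.2, 1)), c(0, 0, 0))
  t <- c(5, -2, 9)
  expect_equal(lever_arm(c(0.1, 0.2, 0.3) + t, c(0, 0, 0) + t),
               lever_arm(c(0.1, 0.2, 0.3), c(0, 0, 0)))
})

test_that("moment coefficients are weighted lever-cross-direction sums", {
  act <- data.frame(name = "m", kind = "muscle",
                    ox = 0.1, oy = 0, oz = 1, ix = 0.1, iy = 0, iz = 0,
                    dx = 0, dy = 0, dz = -1,
                    pcsa_m2 = 1e-3, fmax_N = 300,
                    spans = "coxofemoral", attaches_femur = TRUE,
                    area_label = "a")
  # tau = (0.1, 0, 0), rhat = (0, 0, -1) -> tau x rhat = (0, 0.1, 0)
  expect_equal(moment_coefficient(act, "coxofemoral", c(0, 0, 0)),
               c(0, 0.1, 0))
  # reversing the direction negates the coefficient
  act2 <- act; act2$dz <- 1
  expect_equal(moment_coefficient(act2, "coxofemoral", c(0, 0, 0)),
               -moment_coefficient(act, "coxofemoral", c(0, 0, 0)))
  # direction parallel to the lever arm gives zero
  act3 <- act; act3$dx <- 1; act3$dz <- 0
  expect_equal(moment_coefficient(act3, "coxofemoral", c(0, 0, 0)),
               c(0, 0, 0))
  # unspanned joint gives the zero vector
  expect_equal(moment_coefficient(act, "femorotibial", c(1, 0, 0)),
               c(0, 0, 0))
})

test_that("multi-point attachments use the stated weight split", {
  act <- data.frame(name = "tfl", kind = "muscle",
                    ox = 0, oy = 0, oz = 1, ix = 0.1, iy = 0, iz = 0,
                    dx = 0, dy = 0, dz = -1,
                    p2x = 0.2, p2y = 0, p2z = 0,
                    p3x = 0.3, p3y = 0, p3z = 0,
                    w1 = 0.5, w2 = 0.25, w3 = 0.25,
                    pcsa_m2 = 1e-3, fmax_N = 300,
                    spans = "coxofemoral", attaches_femur = TRUE,
                    area_label = "a")
  got <- moment_coefficient(act, "coxofemoral", c(0, 0, 0))
  want <- 0.5 * cross_oracle(c(0.1, 0, 0), c(0, 0, -1)) +
    0.25 * cross_oracle(c(0.2, 0, 0), c(0, 0, -1)) +
    0.25 * cross_oracle(c(0.3, 0, 0), c(0, 0, -1))
  expect_equal(got, want)
})

test_that("origin-side joints use the origin attachment point", {
  act <- data.frame(name = "m", kind = "muscle",
                    ox = 0.25, oy = 0.1, oz = 0.9,
                    ix = 0.1, iy = 0, iz = 0,
                    pcsa_m2 = 1e-3, fmax_N = 300,
                    spans = "coxofemoral;femorotibial",
                    origin_side_joints = "coxofemoral",
                    attaches_femur = TRUE, area_label = "a")
  rhat <- effective_direction(act)
  cj <- c(0.05, 0, 1)
  expect_equal(moment_coefficient(act, "coxofemoral", cj),
               cross_oracle(c(0.25, 0.1, 0.9) - cj, rhat))
  ck <- c(0, 0, 0.1)
  expect_equal(moment_coefficient(act, "femorotibial", ck),
               cross_oracle(c(0.1, 0, 0) - ck, rhat))
})

test_that("the assembled system matches independent cross products", {
  geom <- toy_three_actuator_geometry()
  sys <- assemble_system(geom)
  expect_equal(dim(sys$A), c(9L, 3L))
  acts <- geom$actuators
  hip <- as.numeric(geom$joints[1, c("x", "y", "z")])
  for (i in 1:3) {
    tau <- c(acts$ix[i], acts$iy[i], acts$iz[i]) - hip
    v <- c(acts$ix[i] - acts$ox[i], acts$iy[i] - acts$oy[i],
           acts$iz[i] - acts$oz[i])
    rhat <- v / sqrt(sum(v^2))
    expect_equal(sys$A[1:3, i], cross_oracle(tau, rhat),
                 ignore_attr = TRUE)
  }
  # rows of unspanned joints are zero
  expect_equal(max(abs(sys$A[4:9, ])), 0)
})

test_that("single-actuator systems have one nonzero 3-block", {
  geom <- single_actuator_geometry()
  sys <- assemble_system(geom)
  expect_equal(dim(sys$A), c(9L, 1L))
  expect_gt(max(abs(sys$A[1:3, 1])), 0)
  expect_equal(max(abs(sys$A[4:9, 1])), 0)
})

test_that("permuting actuators permutes columns identically", {
  geom <- generate_limb(3, 9)$geometry
  sys <- assemble_system(geom)
  perm <- c(5, 1, 9, 2, 8, 3, 7, 4, 6)
  geom2 <- limb_geometry(geom$joints, geom$actuators[perm, ],
                         geom$segments, geom$body_mass, geom$hoof_contact)
  sys2 <- assemble_system(geom2)
  expect_equal(sys2$A, sys$A[, perm], ignore_attr = TRUE)
})

test_that("system blocks rotate with the geometry and scale with coordinates", {
  geom <- generate_limb(8, 7)$geometry
  sys <- assemble_system(geom)
  R <- random_rotation(101)
  sysR <- assemble_system(transform_geometry(geom, R))
  for (b in 1:3) {
    rows <- (3 * (b - 1) + 1):(3 * b)
    expect_equal(sysR$A[rows, ], R %*% sys$A[rows, ], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }

  # scaling all coordinates scales lever arms but not directions
  s <- 2.5
  g <- geom
  for (cols in list(c("x", "y", "z"))) {
    g$joints[, cols] <- s * g$joints[, cols]
    g$segments[, cols] <- s * g$segments[, cols]
  }
  for (cols in c("ox", "oy", "oz", "ix", "iy", "iz")) {
    g$actuators[[cols]] <- s * g$actuators[[cols]]
  }
  g$hoof_contact <- s * g$hoof_contact
  sysS <- assemble_system(g)
  expect_equal(sysS$A, s * sys$A, tolerance = 1e-10)
})

test_that("zero columns arise exactly for non-spanning or centered actuators", {
  geom <- toy_three_actuator_geometry()
  a <- geom$actuators
  a$spans[2] <- ""  # spans nothing
  hip <- as.numeric(geom$joints[1, c("x", "y", "z")])
  a$ix[3] <- hip[1]; a$iy[3] <- hip[2]; a$iz[3] <- hip[3]  # at the center
  geom2 <- limb_geometry(geom$joints, a, geom$segments, geom$body_mass,
                         geom$hoof_contact)
  A <- assemble_system(geom2)$A
  expect_equal(max(abs(A[, 2])), 0)
  expect_equal(max(abs(A[, 3])), 0)
  expect_gt(max(abs(A[, 1])), 0)
})
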