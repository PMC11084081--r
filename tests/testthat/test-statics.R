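test_that("ground reaction follows the body-weight share", {
  expect_equal(ground_reaction(514, 0.2, 9.81), c(0, 0, 1008.468))
  expect_equal(ground_reaction(514, 0), c(0, 0, 0))
  expect_equal(ground_reaction(100, 1, 9.81), c(0, 0, 981))
  expect_error(ground_reaction(-5), "positive")
  expect_error(ground_reaction(100, 1.2), "fraction")
})

test_that("segment loads are gravity forces at the centers of mass", {
  one <- segment_loads(100, data.frame(name = "thigh", mass_fraction = 0.1,
                                       x = 0, y = 0, z = 0.3))
  expect_equal(as.numeric(one[1, c("fx", "fy", "fz")]), c(0, 0, -98.1))
  empty <- segment_loads(100, data.frame(name = character(0),
                                         mass_fraction = numeric(0),
                                         x = numeric(0), y = numeric(0),
                                         z = numeric(0)))
  expect_equal(nrow(empty), 0)

  fr <- nauwelaerts_defaults()
  segs <- data.frame(name = names(fr), mass_fraction = as.numeric(fr),
                     x = 0, y = 0, z = seq(0.3, 0.02, length.out = 5))
  five <- segment_loads(514, segs)
  # hand-summed total weight of the five subunits
  expect_equal(sum(five$fz), -sum(as.numeric(fr)) * 514 * 9.81)
  expect_equal(five$fz / five$fz[1],
               as.numeric(fr) / fr[[1]], tolerance = 1e-12)

  expect_warning(
    segment_loads(100, data.frame(name = c("a", "b"),
                                  mass_fraction = c(0.6, 0.6),
                                  x = 0, y = 0, z = 0)),
    "sum to more than 1")
})

test_that("net joint moments follow the lever cross products", {
  geom <- single_actuator_geometry()
  # GRF applied directly below the hip: collinear with gravity, no moment
  loads0 <- external_loads(c(0, 0, 100), c(0, 0, -1),
                           segment_loads(514, geom$segments[0, ]))
  m0 <- net_joint_moments(geom, loads0,
                          distal = list(coxofemoral = list(grf = TRUE,
                                                           segments = character(0)),
                                        femorotibial = list(grf = TRUE,
                                                            segments = character(0)),
                                        femoropatellar = list(grf = FALSE,
                                                              segments = character(0))))
  expect_equal(m0$M[, "coxofemoral"], c(x = 0, y = 0, z = 0))

  # horizontal offset of 0.1 m gives (0, -10, 0) N m
  loads1 <- external_loads(c(0, 0, 100), c(0.1, 0, -1),
                           segment_loads(514, geom$segments[0, ]))
  m1 <- net_joint_moments(geom, loads1,
                          distal = list(coxofemoral = list(grf = TRUE,
                                                           segments = character(0)),
                                        femorotibial = list(grf = FALSE,
                                                            segments = character(0)),
                                        femoropatellar = list(grf = FALSE,
                                                              segments = character(0))))
  expect_equal(m1$M[, "coxofemoral"] -
                 cross_oracle(c(0.1, 0, -1) - c(0, 0, 0), c(0, 0, 100)),
               c(x = 0, y = 0, z = 0))
  expect_equal(as.numeric(m1$M[, "coxofemoral"]), c(0, -10, 0))
})

test_that("a force applied at the joint center produces no moment there", {
  geom <- generate_limb(5, 8)$geometry
  cj <- as.numeric(geom$joints[1, c("x", "y", "z")])
  loads <- external_loads(c(30, -20, 110), cj,
                          segment_loads(514, geom$segments[0, ]))
  m <- net_joint_moments(geom, loads,
                         distal = list(coxofemoral = list(grf = TRUE,
                                                          segments = character(0)),
                                       femorotibial = list(grf = FALSE,
                                                           segments = character(0)),
                                       femoropatellar = list(grf = FALSE,
                                                             segments = character(0))))
  expect_equal(max(abs(m$M[, "coxofemoral"])), 0)
})

test_that("the femoropatellar net moment is zero by definition", {
  inst <- generate_limb(13, 10, mode = "gravity")
  expect_equal(max(abs(inst$moments$M[, "femoropatellar"])), 0)
})

test_that("net moments are invariant under translation, equivariant under rotation", {
  inst <- generate_limb(23, 10, mode = "gravity")
  geom <- inst$geometry
  loads <- inst$loads
  m <- net_joint_moments(geom, loads)

  t <- c(0.7, -1.3, 2.1)
  mt <- net_joint_moments(transform_geometry(geom, diag(3), t),
                          transform_loads(loads, diag(3), t))
  expect_equal(mt$M, m$M, tolerance = 1e-10)

  R <- random_rotation(77)
  mr <- net_joint_moments(transform_geometry(geom, R),
                          transform_loads(loads, R))
  expect_equal(mr$M, R %*% m$M, tolerance = 1e-10,
               ignore_attr = TRUE)
})
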