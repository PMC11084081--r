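#' Generate a synthetic limb instance
#'
#' Builds a seeded, fully reproducible test instance with the structure of
#' the standing hindlimb analysis: a three-joint serial chain
#' (coxofemoral -> femorotibial -> femoropatellar) with five mass-bearing
#' segments and `n_actuators` line actuators whose lever arms, PCSA and
#' force scales are drawn from configurable, physiologically plausible
#' ranges (forces on the order of 10^2-10^3 N). No anatomical realism is
#' claimed; the generator exists so every pipeline stage can be tested.
#'
#' Two modes control where the net joint moments come from:
#' \describe{
#'   \item{`"reference"`}{reference forces `F_ref` are drawn strictly
#'     inside the bounds and the moments are set to `A %*% F_ref`, so the
#'     instance is feasible by construction and the optimum's cost can
#'     never exceed that of `F_ref`.}
#'   \item{`"gravity"`}{moments follow from the generated ground reaction
#'     and segmental gravity loads via [net_joint_moments()]; such moments
#'     may be unreachable under the tonus floors and are meant for statics
#'     tests, not solver tests.}
#' }
#'
#' @param seed integer seed; the same seed always returns the identical
#'   instance (Mersenne-Twister, inversion normals).
#' @param n_actuators number of actuators (default 20).
#' @param config list overriding defaults: `lever_range` (m, default
#'   `c(0.02, 0.15)`), `pcsa_range` (m^2, default `c(5e-4, 5e-3)`),
#'   `sigma_iso` nominal maximum isometric stress (Pa, default 3e5, so
#'   maximum forces span roughly 150-1500 N), `tonus` (default 0.01),
#'   `body_mass` (kg, default 514), `ligament_share` (default 0.15),
#'   `two_joint_share` (default 0.3).
#' @param mode `"reference"` (default) or `"gravity"`.
#' @return list of class `synthetic_limb`: `geometry`, `loads`, `moments`,
#'   `reference_forces` (NULL in gravity mode), `bounds`.
#' @export
generate_limb <- function(seed, n_actuators = 20L, config = list(),
                          mode = c("reference", "gravity")) {
  mode <- match.arg(mode)
  cfg <- modifyList(list(lever_range = c(0.02, 0.15),
                         pcsa_range = c(5e-4, 5e-3),
                         sigma_iso = 3e5,
                         tonus = 0.01,
                         body_mass = 514,
                         ligament_share = 0.15,
                         two_joint_share = 0.3), config)
  if (cfg$lever_range[1L] >= cfg$lever_range[2L] ||
      cfg$pcsa_range[1L] >= cfg$pcsa_range[2L]) {
    stop("config ranges must be nonempty intervals", call. = FALSE)
  }
  if (n_actuators < 1L) stop("n_actuators must be >= 1", call. = FALSE)

  with_seed(seed, {
    # compact chain so that a point can sit within lever range of two
    # neighboring joints
    joints <- data.frame(
      name = c("coxofemoral", "femorotibial", "femoropatellar"),
      x = c(0.00, 0.04, 0.08),
      y = c(0.00, 0.00, 0.01),
      z = c(0.30, 0.20, 0.22))
    centers <- as.matrix(joints[, c("x", "y", "z")])
    fractions <- nauwelaerts_defaults()
    segments <- data.frame(
      name = names(fractions),
      mass_fraction = as.numeric(fractions),
      x = c(0.02, 0.05, 0.06, 0.06, 0.06),
      y = c(0.00, 0.00, 0.00, 0.00, 0.00),
      z = c(0.25, 0.12, 0.06, 0.03, 0.01))
    hoof <- c(0.06, 0, 0)

    rand_unit <- function() {
      repeat {
        v <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
        n <- vec_norm(v)
        if (n > 1e-3 && n <= 1) return(v / n)
      }
    }
    # span assignment: first 3*ceiling cycles guarantee each joint gets
    # several actuators, remainder sampled (some spanning two adjacent
    # joints)
    pairs <- list(c(1L, 2L), c(2L, 3L))
    span_sets <- vector("list", n_actuators)
    for (i in seq_len(n_actuators)) {
      if (i <= 3L) {
        span_sets[[i]] <- i
      } else if (runif(1) < cfg$two_joint_share) {
        span_sets[[i]] <- pairs[[sample.int(2L, 1L)]]
      } else {
        span_sets[[i]] <- sample.int(3L, 1L)
      }
    }

    rows <- vector("list", n_actuators)
    for (i in seq_len(n_actuators)) {
      S <- span_sets[[i]]
      anchor <- colMeans(centers[S, , drop = FALSE])
      p <- NULL
      for (try in 1:200) {
        cand <- anchor + runif(1, cfg$lever_range[1L], 0.08) * rand_unit()
        d <- sqrt(rowSums((centers[S, , drop = FALSE] -
                             matrix(cand, length(S), 3,
                                    byrow = TRUE))^2))
        if (all(d >= cfg$lever_range[1L] & d <= cfg$lever_range[2L])) {
          p <- cand
          break
        }
      }
      if (is.null(p)) {  # fall back to a single-joint span
        S <- S[1L]
        p <- centers[S, ] + runif(1, cfg$lever_range[1L],
                                  cfg$lever_range[2L]) * rand_unit()
      }
      o <- p + runif(1, 0.10, 0.30) * rand_unit()
      kind <- if (runif(1) < cfg$ligament_share) "ligament" else "muscle"
      pcsa <- runif(1, cfg$pcsa_range[1L], cfg$pcsa_range[2L])
      fmax <- pcsa * cfg$sigma_iso
      rows[[i]] <- data.frame(
        name = sprintf("act_%02d", i),
        kind = kind,
        ox = o[1L], oy = o[2L], oz = o[3L],
        ix = p[1L], iy = p[2L], iz = p[3L],
        pcsa_m2 = pcsa, fmax_N = fmax,
        fmin_N = if (kind == "ligament") 0 else cfg$tonus * fmax,
        spans = paste(joints$name[S], collapse = ";"),
        attaches_femur = runif(1) < 0.5,
        area_label = sprintf("area_%02d", i),
        stringsAsFactors = FALSE)
    }
    acts <- do.call(rbind, rows)
    geom <- limb_geometry(joints = joints, actuators = acts,
                          segments = segments,
                          body_mass = cfg$body_mass, hoof_contact = hoof)
    loads <- standing_loads(geom)
    bounds <- default_bounds(geom$actuators,
                             grf_magnitude = vec_norm(loads$grf),
                             tonus = cfg$tonus)

    if (mode == "reference") {
      u <- runif(nrow(acts), 0.1, 0.9)
      f_ref <- bounds$lower + u * (bounds$upper - bounds$lower)
      names(f_ref) <- acts$name
      A <- assemble_system(geom)$A
      M <- matrix(drop(A %*% f_ref), nrow = 3,
                  dimnames = list(c("x", "y", "z"), joints$name))
      moments <- net_moments(M, source = "reference")
      ref <- f_ref
    } else {
      moments <- net_joint_moments(geom, loads)
      ref <- NULL
    }
    structure(list(geometry = geom, loads = loads, moments = moments,
                   reference_forces = ref, bounds = bounds, seed = seed,
                   mode = mode),
              class = "synthetic_limb")
  })
}

#' Write a synthetic instance to files
#'
#' Convenience wrapper that serializes the generated geometry (YAML, see
#' [write_geometry()]) and a loads configuration block (YAML with
#' `body_mass_kg`, `hindlimb_fraction`, `g` and the segment fraction
#' table).
#'
#' @param instance a `synthetic_limb` from [generate_limb()].
#' @param geometry_path,loads_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_synthetic <- function(instance, geometry_path, loads_path) {
  stopifnot(inherits(instance, "synthetic_limb"))
  write_geometry(instance$geometry, geometry_path)
  segs <- instance$geometry$segments
  yaml::write_yaml(list(
    body_mass_kg = instance$geometry$body_mass,
    hindlimb_fraction = 0.2,
    g = 9.81,
    segment_fractions = as.list(setNames(segs$mass_fraction, segs$name))),
    loads_path, precision = 15)
  invisible(c(geometry_path, loads_path))
}

#' @export
print.synthetic_limb <- function(x, ...) {
  cat("Synthetic limb (seed", x$seed, ", mode", x$mode, "):",
      nrow(x$geometry$actuators), "actuators\n")
  invisible(x)
}
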