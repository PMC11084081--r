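# Static optimization of the redundant muscle-force distribution:
#   minimize U(F) = sum_i (F_i / PCSA_i)^3
#   subject to A F = M (moment balance) and lower <= F <= upper.
# U is strictly convex on the nonnegative orthant (bounds keep F >= 0), so
# any KKT point is the global optimum. Internally the problem is posed in
# dimensionless activations a_i = F_i / (PCSA_i * sigma0) with a nominal
# muscle stress sigma0, which conditions the cubic; U = sigma0^3 * sum a^3,
# so the minimizer is unchanged.

#' Default physiological force bounds
#'
#' Builds the box constraints of the static optimization. Muscles get a
#' lower bound of `tonus` (default 1%) of their maximum isometric force,
#' representing resting muscle tonus, and an upper bound of the maximum
#' isometric force. The superficial digital flexor additionally gets a floor
#' of `sdf_fraction` (default 90%) of the ground reaction force magnitude,
#' standing in for the stabilizing moment of the hock. Ligaments transmit
#' force passively: lower bound 0, upper bound their configured cap
#' (`fmax_N`). An explicit `fmin_N` on an actuator overrides the rule
#' (provenance `"custom"`).
#'
#' @param actuators actuator data.frame (from a [limb_geometry()]).
#' @param grf_magnitude magnitude of the ground reaction force, N.
#' @param tonus resting-tonus fraction of the maximum isometric force.
#' @param sdf_fraction GRF fraction for the superficial digital flexor
#'   floor.
#' @param sdf_pattern regular expression identifying the superficial
#'   digital flexor by name (case-insensitive).
#' @return object of class `bound_spec`: data.frame with `name`, `lower`,
#'   `upper`, `provenance` (`tonus`, `payne_max`, `sdf_grf`, `ligament`, or
#'   `custom`).
#' @export
default_bounds <- function(actuators, grf_magnitude = 0,
                           tonus = 0.01, sdf_fraction = 0.9,
                           sdf_pattern = "superficial.*digital.*flexor|digital.*flexor.*superficial") {
  acts <- as.data.frame(actuators)
  n <- nrow(acts)
  lower <- numeric(n)
  upper <- acts$fmax_N
  prov <- character(n)
  fmin <- if (is.null(acts$fmin_N)) rep(NA_real_, n) else acts$fmin_N
  for (i in seq_len(n)) {
    if (acts$kind[i] == "ligament") {
      lower[i] <- 0
      prov[i] <- "ligament"
    } else {
      lower[i] <- tonus * acts$fmax_N[i]
      prov[i] <- "tonus"
      if (grepl(sdf_pattern, acts$name[i], ignore.case = TRUE)) {
        floor_sdf <- sdf_fraction * grf_magnitude
        if (floor_sdf > lower[i]) {
          lower[i] <- floor_sdf
          prov[i] <- "sdf_grf"
        }
      }
    }
    if (!is.na(fmin[i])) {
      lower[i] <- fmin[i]
      prov[i] <- "custom"
    }
    if (lower[i] > upper[i] + 1e-12) {
      stop("infeasible bounds for actuator '", acts$name[i],
           "': lower ", signif(lower[i], 6), " N exceeds upper ",
           signif(upper[i], 6), " N", call. = FALSE)
    }
  }
  structure(data.frame(name = acts$name, lower = lower, upper = upper,
                       provenance = prov, stringsAsFactors = FALSE),
            class = c("bound_spec", "data.frame"))
}

#' Solve the muscle-force distribution
#'
#' Minimizes the cubic PCSA-normalized cost subject to moment balance
#' (equality constraints from [assemble_system()] and the net joint
#' moments) and the physiological box bounds. The solver runs an augmented
#' Lagrangian over the scaled equality constraints with box-constrained
#' L-BFGS-B inner iterations, then polishes the result with Newton steps on
#' the reduced KKT system of the free (non-bound-active) actuators. The
#' start point is the midpoint of the bounds, making the solve
#' deterministic.
#'
#' @param system a `system_matrix` from [assemble_system()].
#' @param moments a `net_joint_moments` object (or numeric vector of length
#'   `nrow(system$A)`).
#' @param pcsa physiological cross-sectional areas, m^2, one per actuator
#'   (named vectors are matched by name).
#' @param bounds a `bound_spec` from [default_bounds()].
#' @param control list of solver knobs: `sigma0` nominal muscle stress
#'   (Pa, default 3e5), `tol_feas` relative feasibility tolerance (1e-8),
#'   `tol_opt` optimality tolerance (1e-8), `max_outer` augmented-Lagrangian
#'   iterations (60), `rho0` initial penalty (10).
#' @return object of class `force_solution`: `forces` (named, N),
#'   `objective` (value of the cubic cost), `moment_residual` (per joint
#'   row, N m), `active_bounds` (factor: lower/upper/free), `converged`,
#'   `status`, `iterations`, and `kkt` (relative KKT residual).
#' @export
solve_forces <- function(system, moments, pcsa, bounds, control = list()) {
  ctl <- modifyList(list(sigma0 = 3e5, tol_feas = 1e-8, tol_opt = 1e-8,
                         max_outer = 60L, rho0 = 10), control)
  stopifnot(inherits(system, "system_matrix"))
  A <- system$A
  n <- ncol(A)
  M <- if (inherits(moments, "net_joint_moments")) {
    moments_vector(moments, system$joints)
  } else {
    as.numeric(moments)
  }
  if (length(M) != nrow(A)) {
    stop("moments length ", length(M), " does not match system rows ",
         nrow(A), call. = FALSE)
  }
  pcsa <- match_by_name(pcsa, system$actuators, "pcsa")
  if (any(!is.finite(pcsa) | pcsa <= 0)) {
    stop("pcsa must be positive and finite for all actuators",
         call. = FALSE)
  }
  bl <- match_by_name(bounds$lower, system$actuators, "bounds",
                      names = bounds$name)
  bu <- match_by_name(bounds$upper, system$actuators, "bounds",
                      names = bounds$name)
  if (any(bl > bu + 1e-12) || any(bl < 0)) {
    stop("invalid bounds: need 0 <= lower <= upper", call. = FALSE)
  }

  # Activation scaling (columns) and row scaling.
  s <- pcsa * ctl$sigma0
  la <- bl / s
  ua <- bu / s
  B <- A * rep(s, each = nrow(A))
  rownorm <- sqrt(rowSums(B^2))
  keep <- rownorm > 1e-12 * max(1, max(rownorm))
  if (any(!keep & abs(M) > ctl$tol_feas * max(1, vec_norm(M)))) {
    bad <- which(!keep & abs(M) > ctl$tol_feas * max(1, vec_norm(M)))[1L]
    return(force_solution_obj(
      forces = setNames(bl, system$actuators), pcsa = pcsa,
      A = A, M = M, bl = bl, bu = bu, converged = FALSE,
      status = paste0("infeasible: no actuator produces moment on row '",
                      rownames(A)[bad], "'"),
      iterations = 0L, system = system))
  }
  Bs <- B[keep, , drop = FALSE] / rownorm[keep]
  Ms <- M[keep] / rownorm[keep]

  # Augmented Lagrangian with L-BFGS-B inner solves.
  a <- (la + ua) / 2
  lambda <- rep(0, length(Ms))
  rho <- ctl$rho0
  cnorm_prev <- Inf
  iters <- 0L
  for (outer in seq_len(ctl$max_outer)) {
    fn <- function(x) {
      cc <- drop(Bs %*% x) - Ms
      sum(x^3) + sum(lambda * cc) + 0.5 * rho * sum(cc^2)
    }
    gr <- function(x) {
      cc <- drop(Bs %*% x) - Ms
      3 * x^2 + drop(crossprod(Bs, lambda + rho * cc))
    }
    fit <- optim(a, fn, gr, method = "L-BFGS-B", lower = la, upper = ua,
                 control = list(maxit = 1000L, factr = 10, pgtol = 1e-12))
    a <- fit$par
    iters <- iters + fit$counts[["function"]]
    cc <- drop(Bs %*% a) - Ms
    cnorm <- vec_norm(cc)
    lambda <- lambda + rho * cc
    if (cnorm <= 1e-10 * max(1, vec_norm(Ms))) break
    if (cnorm > 0.25 * cnorm_prev) rho <- min(rho * 5, 1e12)
    cnorm_prev <- cnorm
  }

  # Newton polish on the reduced KKT system of free activations.
  a <- kkt_polish(a, Bs, Ms, la, ua)

  F <- a * s
  res <- drop(A %*% F) - M
  feas_ok <- vec_norm(res) <= max(ctl$tol_feas, 1e-8) * max(1, vec_norm(M))
  sol <- force_solution_obj(
    forces = setNames(F, system$actuators), pcsa = pcsa, A = A, M = M,
    bl = bl, bu = bu,
    converged = feas_ok,
    status = if (feas_ok) "converged" else
      "infeasible: equality system unreachable within bounds (minimal-residual iterate returned)",
    iterations = iters, system = system)
  kkt <- kkt_residual(sol, system, pcsa, bounds, sigma0 = ctl$sigma0)
  sol$kkt <- kkt
  if (feas_ok && kkt > max(ctl$tol_opt, 1e-6)) {
    sol$status <- "feasible but optimality tolerance not met"
  }
  sol
}

match_by_name <- function(x, actuator_names, what, names = base::names(x)) {
  if (!is.null(names) && all(actuator_names %in% names)) {
    return(as.numeric(x[match(actuator_names, names)]))
  }
  if (length(x) != length(actuator_names)) {
    stop(what, " must have one entry per actuator", call. = FALSE)
  }
  as.numeric(x)
}

force_solution_obj <- function(forces, pcsa, A, M, bl, bu, converged,
                               status, iterations, system) {
  tol <- 1e-6 * pmax(1, bu - bl)
  active <- ifelse(forces <= bl + tol, "lower",
                   ifelse(forces >= bu - tol, "upper", "free"))
  res <- drop(A %*% forces) - M
  names(res) <- rownames(A)
  structure(list(
    forces = forces,
    objective = sum((forces / pcsa)^3),
    moment_residual = res,
    moment_residual_rel = vec_norm(res) / max(1, vec_norm(M)),
    active_bounds = setNames(active, names(forces)),
    lower = setNames(bl, names(forces)),
    upper = setNames(bu, names(forces)),
    converged = converged, status = status,
    iterations = as.integer(iterations), kkt = NA_real_),
    class = "force_solution")
}

# Newton iterations on the stationarity + feasibility system restricted to
# activations strictly inside their bounds; bound-active activations are
# frozen. Falls back to the input iterate if a step fails.
kkt_polish <- function(a, Bs, Ms, la, ua, max_iter = 40L) {
  best <- a
  tol_act <- 1e-9 * pmax(1, ua - la)
  for (rebuild in 1:4) {
    free <- which(a > la + tol_act & a < ua - tol_act)
    if (!length(free)) return(best)
    Bf <- Bs[, free, drop = FALSE]
    rhs <- Ms - drop(Bs[, -free, drop = FALSE] %*% a[-free])
    if (!ncol(Bf)) return(best)
    g <- 3 * a[free]^2
    nu <- tryCatch(qr.coef(qr(t(Bf)), g), error = function(e) NULL)
    if (is.null(nu)) return(best)
    nu[is.na(nu)] <- 0
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      af <- a[free]
      r1 <- 3 * af^2 - drop(crossprod(Bf, nu))
      r2 <- drop(Bf %*% af) - rhs
      rn <- vec_norm(c(r1, r2))
      if (rn < 1e-13 * max(1, vec_norm(Ms))) break
      H <- diag(6 * af, nrow = length(af))
      Kmat <- rbind(cbind(H, -t(Bf)),
                    cbind(Bf, matrix(0, nrow(Bf), nrow(Bf))))
      step <- tryCatch(solve(Kmat, -c(r1, r2)), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) { ok <- FALSE; break }
      # damped update, keep activations inside the box
      t_max <- 1
      da <- step[seq_along(af)]
      hit_lo <- da < 0
      hit_hi <- da > 0
      if (any(hit_lo)) {
        t_max <- min(t_max, min((la[free][hit_lo] - af[hit_lo]) / da[hit_lo]))
      }
      if (any(hit_hi)) {
        t_max <- min(t_max, min((ua[free][hit_hi] - af[hit_hi]) / da[hit_hi]))
      }
      t_step <- min(1, 0.9995 * t_max)
      if (t_step <= 0) { ok <- FALSE; break }
      a[free] <- af + t_step * da
      nu <- nu + t_step * step[-seq_along(af)]
    }
    if (!ok) return(best)
    # accept if feasibility did not degrade
    if (vec_norm(drop(Bs %*% a) - Ms) <=
        vec_norm(drop(Bs %*% best) - Ms) + 1e-12) {
      best <- a
    }
    # variables pushed to a bound: refreeze and redo with the new active set
    at_bound <- a[free] <= la[free] + tol_act[free] |
      a[free] >= ua[free] - tol_act[free]
    if (!any(at_bound)) break
    a[free][a[free] < la[free]] <- la[free][a[free] < la[free]]
    a[free][a[free] > ua[free]] <- ua[free][a[free] > ua[free]]
  }
  best
}

#' KKT residual of a force solution
#'
#' Certifies optimality of a converged solution: because the cubic cost is
#' convex over nonnegative forces, a (near-)zero projected-gradient
#' residual implies a global optimum. The residual is evaluated in the
#' solver's dimensionless activation space: equality multipliers are fitted
#' by least squares on the free (non-bound-active) coordinates and the
#' remaining gradient components are projected onto the feasible directions
#' at the bounds. The returned value is the norm of the projected gradient
#' relative to the gradient scale.
#'
#' @inheritParams solve_forces
#' @param solution a `force_solution`.
#' @param sigma0 nominal muscle stress used for activation scaling (Pa).
#' @return scalar relative residual (dimensionless).
#' @export
kkt_residual <- function(solution, system, pcsa, bounds, sigma0 = 3e5) {
  A <- system$A
  pcsa <- match_by_name(pcsa, system$actuators, "pcsa")
  bl <- match_by_name(bounds$lower, system$actuators, "bounds",
                      names = bounds$name)
  bu <- match_by_name(bounds$upper, system$actuators, "bounds",
                      names = bounds$name)
  s <- pcsa * sigma0
  a <- as.numeric(solution$forces) / s
  la <- bl / s
  ua <- bu / s
  B <- A * rep(s, each = nrow(A))
  rownorm <- sqrt(rowSums(B^2))
  keep <- rownorm > 1e-12 * max(1, max(rownorm))
  Bs <- B[keep, , drop = FALSE] / rownorm[keep]
  g <- 3 * a^2
  tol_act <- 1e-7 * pmax(1, ua - la)
  free <- a > la + tol_act & a < ua - tol_act

  project <- function(nu) {
    z <- g - drop(crossprod(Bs, nu))
    viol <- abs(z)
    viol[!free & a <= la + tol_act] <- pmax(0, -z[!free & a <= la + tol_act])
    viol[!free & a >= ua - tol_act] <- pmax(0, z[!free & a >= ua - tol_act])
    vec_norm(viol)
  }
  nu0 <- tryCatch({
    cols <- if (any(free)) which(free) else seq_along(a)
    fit <- qr.coef(qr(t(Bs[, cols, drop = FALSE])), g[cols])
    fit[is.na(fit)] <- 0
    fit
  }, error = function(e) rep(0, nrow(Bs)))
  r <- project(nu0)
  if (r > 0 && nrow(Bs) <= 12) {
    # corner cases (no free coordinates): search multipliers directly
    opt <- tryCatch(
      optim(nu0, project, method = "Nelder-Mead",
            control = list(maxit = 2000L, reltol = 1e-14,
                           warn.1d.NelderMead = FALSE)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value < r) r <- opt$value
  }
  r / max(1, vec_norm(g))
}

#' @export
print.force_solution <- function(x, ...) {
  cat("Force solution:", x$status, "\n")
  cat(sprintf("  objective U = %.6g; relative moment residual = %.3g; kkt = %.3g\n",
              x$objective, x$moment_residual_rel, x$kkt))
  df <- data.frame(force_N = round(x$forces, 1), at = x$active_bounds)
  print(df[order(-df$force_N), , drop = FALSE], ...)
  invisible(x)
}
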