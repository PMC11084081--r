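#' Brute-force reference optimizer (test oracle)
#'
#' Independent solution path for tiny instances (at most 4 actuators): a
#' dense grid over the force box is projected onto the moment-balance
#' affine subspace, feasible candidates are kept, and the best few are
#' refined by penalized Nelder-Mead over the nullspace parameterization.
#' This shares no code with [solve_forces()] and exists to cross-check it;
#' it is exported for use in tests and validation scripts only.
#'
#' @inheritParams solve_forces
#' @param grid_n grid points per dimension (default 9).
#' @return list with `forces`, `objective`, `status`
#'   (`"ok"` or `"infeasible"`).
#' @export
brute_force_oracle <- function(system, moments, pcsa, bounds, grid_n = 9L) {
  A <- system$A
  n <- ncol(A)
  if (n > 4L) stop("brute_force_oracle supports at most 4 actuators",
                   call. = FALSE)
  M <- if (inherits(moments, "net_joint_moments")) {
    moments_vector(moments, system$joints)
  } else as.numeric(moments)
  pcsa <- match_by_name(pcsa, system$actuators, "pcsa")
  bl <- match_by_name(bounds$lower, system$actuators, "bounds",
                      names = bounds$name)
  bu <- match_by_name(bounds$upper, system$actuators, "bounds",
                      names = bounds$name)
  Uof <- function(F) sum((F / pcsa)^3)
  feas_tol <- 1e-6 * max(1, vec_norm(M))

  sv <- svd(A, nv = n)
  pos <- which(sv$d > 1e-12 * max(sv$d, 1))
  # least-squares projector onto the affine subspace {A F = M}
  proj <- function(F) {
    r <- drop(A %*% F) - M
    F - drop(sv$v[, pos, drop = FALSE] %*%
               (crossprod(sv$u[, pos, drop = FALSE], r) / sv$d[pos]))
  }
  clip <- function(F) pmin(pmax(F, bl), bu)
  in_box <- function(F, tol = 1e-7) {
    all(F >= bl - tol * pmax(1, bu - bl)) &&
      all(F <= bu + tol * pmax(1, bu - bl))
  }
  resid <- function(F) vec_norm(drop(A %*% F) - M)

  # Feasibility probe: alternating projections between box and subspace.
  F <- (bl + bu) / 2
  for (k in 1:20000) {
    Fn <- clip(proj(F))
    if (resid(Fn) <= 0.5 * feas_tol) { F <- Fn; break }
    if (vec_norm(Fn - F) < 1e-16 * max(1, vec_norm(F))) { F <- Fn; break }
    F <- Fn
  }
  probe <- F
  if (resid(probe) > feas_tol) {
    return(list(forces = setNames(probe, system$actuators),
                objective = NA_real_, status = "infeasible"))
  }

  grids <- lapply(seq_len(n), function(i) seq(bl[i], bu[i],
                                              length.out = grid_n))
  cand <- as.matrix(expand.grid(grids))
  keep <- list(list(F = probe, U = Uof(probe)))
  for (i in seq_len(nrow(cand))) {
    Fp <- proj(cand[i, ])
    if (in_box(Fp) && resid(clip(Fp)) <= feas_tol) {
      Fp <- clip(Fp)
      keep[[length(keep) + 1L]] <- list(F = Fp, U = Uof(Fp))
    }
  }
  ord <- order(vapply(keep, `[[`, numeric(1), "U"))
  keep <- keep[ord[seq_len(min(8L, length(ord)))]]

  # Refinement over the nullspace of A. Moving along a nullspace direction
  # z keeps the equality constraints satisfied; the admissible step range
  # follows from the box. Exact convex 1-D minimization per direction
  # (cyclic passes for higher-dimensional nullspaces, preceded by a
  # penalized simplex search to escape corners).
  Z <- sv$v[, setdiff(seq_len(n), pos), drop = FALSE]
  line_range <- function(F, z) {
    tlo <- -Inf; thi <- Inf
    for (i in seq_along(z)) {
      if (abs(z[i]) < 1e-14) next
      r <- sort(c((bl[i] - F[i]) / z[i], (bu[i] - F[i]) / z[i]))
      tlo <- max(tlo, r[1]); thi <- min(thi, r[2])
    }
    c(tlo, thi)
  }
  refine <- function(F0) {
    if (!ncol(Z)) return(F0)
    F <- F0
    if (ncol(Z) > 1L) {
      y <- rep(0, ncol(Z))
      for (mu in c(1e4, 1e7, 1e10)) {
        pen <- function(y) {
          Fy <- F0 + drop(Z %*% y)
          Uof(clip(Fy)) + mu * sum(pmax(0, bl - Fy)^2 + pmax(0, Fy - bu)^2)
        }
        y <- optim(y, pen, method = "Nelder-Mead",
                   control = list(maxit = 4000L, reltol = 1e-15))$par
      }
      F <- clip(F0 + drop(Z %*% y))
    }
    for (pass in 1:60) {
      moved <- FALSE
      for (k in seq_len(ncol(Z))) {
        z <- Z[, k]
        rng <- line_range(F, z)
        if (!all(is.finite(rng)) || rng[2] - rng[1] < 1e-15) next
        opt <- optimize(function(t) Uof(F + t * z), rng, tol = 1e-13)
        tb <- opt$minimum
        if (Uof(F + rng[1] * z) < opt$objective) tb <- rng[1]
        if (Uof(F + rng[2] * z) < Uof(F + tb * z)) tb <- rng[2]
        if (abs(tb) > 1e-14 && Uof(F + tb * z) < Uof(F) - 1e-300) {
          F <- clip(F + tb * z)
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    F
  }
  out <- lapply(keep, function(b) {
    F <- refine(b$F)
    if (resid(F) <= feas_tol) list(F = F, U = Uof(F)) else b
  })
  U <- vapply(out, `[[`, numeric(1), "U")
  k <- which.min(U)
  list(forces = setNames(out[[k]]$F, system$actuators),
       objective = U[k], status = "ok")
}
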