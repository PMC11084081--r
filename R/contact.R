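#' Joint contact force
#'
#' Estimates the articular contact force at a joint as the sum of the
#' intersegmental force transmitted there (ground reaction plus gravity of
#' the segments distal to the joint) and the forces of all actuators
#' spanning the joint, each taken as magnitude times its effective line of
#' action. The result is reported as the force acting on the proximal bone
#' from the distal side; the magnitude is its Euclidean norm. Because
#' antagonistic co-contraction is cancelled by static optimization, these
#' estimates tend to be conservative lower bounds on in vivo loads.
#'
#' @param joint joint name.
#' @param geometry a [limb_geometry()].
#' @param solution a converged `force_solution` from [solve_forces()].
#' @param loads an [external_loads()] object, or NULL to omit the
#'   intersegmental contribution.
#' @param distal optional distal-force bookkeeping (see
#'   [net_joint_moments()]).
#' @return numeric 3-vector (N) with attribute `"magnitude"`.
#' @export
contact_force <- function(joint, geometry, solution, loads = NULL,
                          distal = NULL) {
  stopifnot(inherits(geometry, "limb_geometry"))
  if (!joint %in% geometry$joints$name) {
    stop("unknown joint '", joint, "'", call. = FALSE)
  }
  f <- c(0, 0, 0)
  if (!is.null(loads)) {
    if (is.null(distal)) distal <- default_distal_map(geometry)
    d <- distal[[joint]]
    if (is.null(d)) stop("no distal-force map for joint '", joint, "'",
                         call. = FALSE)
    if (isTRUE(d$grf)) f <- f + loads$grf
    segs <- loads$segment_forces
    for (s in d$segments) {
      k <- match(s, segs$name)
      if (is.na(k)) stop("segment '", s, "' not present in loads",
                         call. = FALSE)
      f <- f + as.numeric(segs[k, c("fx", "fy", "fz")])
    }
  }
  acts <- geometry$actuators
  for (i in seq_len(nrow(acts))) {
    if (joint %in% parse_spans(acts$spans[i])) {
      Fi <- solution$forces[[acts$name[i]]]
      if (is.null(Fi) || is.na(Fi)) {
        stop("solution has no force for actuator '", acts$name[i], "'",
             call. = FALSE)
      }
      f <- f + Fi * effective_direction(acts[i, ])
    }
  }
  attr(f, "magnitude") <- vec_norm(f)
  f
}

#' Contact forces at every joint
#'
#' @inheritParams contact_force
#' @return data.frame with columns `joint`, `fx`, `fy`, `fz`,
#'   `magnitude_N`.
#' @export
contact_forces <- function(geometry, solution, loads = NULL,
                           distal = NULL) {
  joints <- geometry$joints$name
  rows <- lapply(joints, function(j) {
    f <- contact_force(j, geometry, solution, loads, distal)
    data.frame(joint = j, fx = f[1L], fy = f[2L], fz = f[3L],
               magnitude_N = attr(f, "magnitude"))
  })
  do.call(rbind, rows)
}
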