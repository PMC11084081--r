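#' Default segment mass fractions for the equine hindlimb
#'
#' Editable configuration of segment masses as fractions of body mass for
#' the five-subunit standing model (thigh, crus, metatarsus, hind pastern,
#' hind hoof), in the spirit of published equine segment-inertia tables.
#' These are order-of-magnitude defaults; substitute study-specific values
#' when available.
#'
#' @return named numeric vector of mass fractions.
#' @export
nauwelaerts_defaults <- function() {
  c("thigh" = 0.0350,
    "crus" = 0.0150,
    "metatarsus" = 0.0035,
    "hind pastern" = 0.0015,
    "hind hoof" = 0.0020)
}

#' Ground reaction force for square standing
#'
#' In square standing each hindlimb carries a fixed share of body weight
#' (about 20%), applied vertically at the center of the hoof.
#'
#' @param body_mass body mass, kg (> 0).
#' @param fraction share of body weight on the limb, in `[0, 1]`
#'   (default 0.2).
#' @param g gravitational acceleration, m/s^2 (default 9.81).
#' @return numeric 3-vector `(0, 0, +fraction * body_mass * g)` in N.
#' @examples
#' ground_reaction(514, 0.2)  # about 1008.5 N upward
#' @export
ground_reaction <- function(body_mass, fraction = 0.2, g = 9.81) {
  if (!is.finite(body_mass) || body_mass <= 0) {
    stop("body_mass must be positive", call. = FALSE)
  }
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  c(0, 0, fraction * body_mass * g)
}

#' Segmental gravity loads
#'
#' One downward force per limb segment, `(0, 0, -mass_fraction * body_mass
#' * g)`, applied at the segment's center of mass.
#'
#' @param body_mass body mass, kg.
#' @param segments data.frame with `name`, `mass_fraction`, `x`, `y`, `z`
#'   (as in [limb_geometry()]).
#' @param g gravitational acceleration, m/s^2.
#' @return data.frame with columns `name`, `x`, `y`, `z`, `fx`, `fy`, `fz`.
#' @export
segment_loads <- function(body_mass, segments, g = 9.81) {
  segs <- as.data.frame(segments)
  if (!nrow(segs)) {
    return(data.frame(name = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), fx = numeric(0), fy = numeric(0),
                      fz = numeric(0)))
  }
  if (sum(segs$mass_fraction) > 1) {
    warning("segment mass fractions sum to more than 1")
  }
  data.frame(name = segs$name, x = segs$x, y = segs$y, z = segs$z,
             fx = 0, fy = 0, fz = -segs$mass_fraction * body_mass * g)
}

#' Bundle external loads acting on the limb
#'
#' @param grf ground reaction force 3-vector, N.
#' @param grf_point application point of the GRF (hoof contact), m.
#' @param segment_forces data.frame from [segment_loads()].
#' @return object of class `external_loads`.
#' @export
external_loads <- function(grf, grf_point, segment_forces) {
  structure(list(grf = as_point3(grf, "grf"),
                 grf_point = as_point3(grf_point, "grf_point"),
                 segment_forces = as.data.frame(segment_forces)),
            class = "external_loads")
}

#' External loads of the standing configuration
#'
#' Convenience constructor: vertical GRF at the hoof plus the five segmental
#' gravity loads of a geometry.
#'
#' @param geometry a [limb_geometry()].
#' @param fraction hindlimb share of body weight (default 0.2).
#' @param g gravitational acceleration, m/s^2.
#' @return an [external_loads()] object.
#' @export
standing_loads <- function(geometry, fraction = 0.2, g = 9.81) {
  external_loads(
    grf = ground_reaction(geometry$body_mass, fraction, g),
    grf_point = geometry$hoof_contact,
    segment_forces = segment_loads(geometry$body_mass, geometry$segments, g))
}

# Which external forces act distal to each joint in the serial chain.
# For the canonical hip -> stifle -> patella model: the GRF (at the hoof,
# most distal point) counts for the coxofemoral and femorotibial joints; the
# thigh's own weight loads only the coxofemoral joint; the femoropatellar
# joint sees no gravitational load (patellar branch).
default_distal_map <- function(geometry) {
  segs <- geometry$segments$name
  map <- list()
  for (j in geometry$joints$name) {
    map[[j]] <- switch(j,
      "coxofemoral" = list(grf = TRUE, segments = segs),
      "femorotibial" = list(grf = TRUE, segments = setdiff(segs, "thigh")),
      "femoropatellar" = list(grf = FALSE, segments = character(0)),
      NULL)
  }
  if (any(vapply(map, is.null, logical(1)))) {
    stop("no default distal-force bookkeeping for joint '",
         geometry$joints$name[vapply(map, is.null, logical(1))][1L],
         "'; supply `distal` explicitly", call. = FALSE)
  }
  map
}

#' Net joint moments from external loads
#'
#' Inverse statics for the standing limb: the moment each joint's muscles
#' must cancel is the sum, over all external forces applied distal to the
#' joint, of `(application_point - joint_center) x F`. In standing these
#' external forces are the ground reaction at the hoof and the segmental
#' gravity loads. The femoropatellar net moment is set to exactly zero: the
#' patella has negligible gravitational load.
#'
#' @param geometry a [limb_geometry()].
#' @param loads an [external_loads()] object in the same frame.
#' @param distal optional named list (per joint) with fields `grf` (logical)
#'   and `segments` (character vector of segment names distal to the joint).
#'   Defaults cover the canonical coxofemoral / femorotibial /
#'   femoropatellar chain.
#' @param patellar_zero force the `femoropatellar` entry to zero
#'   (default TRUE).
#' @return object of class `net_joint_moments`: a 3 x J matrix `M` (N m,
#'   columns in joint order) plus joint names.
#' @export
net_joint_moments <- function(geometry, loads, distal = NULL,
                              patellar_zero = TRUE) {
  stopifnot(inherits(geometry, "limb_geometry"),
            inherits(loads, "external_loads"))
  if (is.null(distal)) distal <- default_distal_map(geometry)
  joints <- geometry$joints$name
  M <- matrix(0, nrow = 3, ncol = length(joints),
              dimnames = list(c("x", "y", "z"), joints))
  segs <- loads$segment_forces
  for (j in joints) {
    if (is.null(distal[[j]])) {
      stop("no distal-force map for joint '", j, "'", call. = FALSE)
    }
    cj <- joint_center(geometry, j)
    m <- c(0, 0, 0)
    if (isTRUE(distal[[j]]$grf)) {
      m <- m + cross3(loads$grf_point - cj, loads$grf)
    }
    for (s in distal[[j]]$segments) {
      k <- match(s, segs$name)
      if (is.na(k)) stop("segment '", s, "' not present in loads",
                         call. = FALSE)
      p <- as.numeric(segs[k, c("x", "y", "z")])
      f <- as.numeric(segs[k, c("fx", "fy", "fz")])
      m <- m + cross3(p - cj, f)
    }
    M[, j] <- m
  }
  if (patellar_zero && "femoropatellar" %in% joints) {
    M[, "femoropatellar"] <- 0
  }
  net_moments(M, source = "gravity")
}

#' Construct net joint moments directly
#'
#' Low-level constructor used when moment targets do not come from inverse
#' statics — e.g. the synthetic generator's reference-derived targets, or
#' externally supplied moment tables.
#'
#' @param M numeric 3 x J matrix (N m), columns named by joint.
#' @param source provenance tag: `"gravity"` for inverse-statics moments,
#'   `"reference"` for targets built from reference forces, `"direct"`
#'   otherwise.
#' @return object of class `net_joint_moments`.
#' @export
net_moments <- function(M, source = "direct") {
  stopifnot(is.matrix(M), nrow(M) == 3L)
  structure(list(M = M, joints = colnames(M), source = source),
            class = "net_joint_moments")
}

#' Stack net joint moments into one vector
#'
#' @param moments a `net_joint_moments` object.
#' @param joints joint order (default: the object's own order).
#' @return numeric vector of length `3 * J` (x, y, z per joint).
#' @export
moments_vector <- function(moments, joints = moments$joints) {
  miss <- setdiff(joints, moments$joints)
  if (length(miss)) stop("moments missing joint '", miss[1L], "'",
                         call. = FALSE)
  as.numeric(moments$M[, joints])
}

#' @export
print.net_joint_moments <- function(x, ...) {
  cat("Net joint moments (N m,", x$source, "):\n")
  mag <- sqrt(colSums(x$M^2))
  for (j in x$joints) {
    cat(sprintf("  %-16s |M| = %8.2f  (%s)\n", j, mag[j],
                paste(sprintf("%.2f", x$M[, j]), collapse = ", ")))
  }
  invisible(x)
}
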