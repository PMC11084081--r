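#' Lever arm of an attachment point about a joint center
#'
#' @param attachment attachment point, 3-vector (m).
#' @param joint_center joint center of rotation, 3-vector (m).
#' @return numeric 3-vector `attachment - joint_center`.
#' @export
lever_arm <- function(attachment, joint_center) {
  as_point3(attachment, "attachment") - as_point3(joint_center,
                                                  "joint_center")
}

#' Moment coefficient of an actuator about a joint
#'
#' The moment (N m) produced about a joint per newton of actuator force:
#' the weighted sum over the actuator's attachment points of
#' `lever_arm x direction`, with the unit line of action from
#' [effective_direction()]. Actuators that do not span the joint contribute
#' the zero vector.
#'
#' By default the insertion-side attachment points carry the lever arm; for
#' joints listed in the actuator's `origin_side_joints` field the origin
#' point is used instead (the attachment on the segment distal to that
#' joint).
#'
#' @param actuator one-row actuator data.frame.
#' @param joint joint name.
#' @param joint_center the joint's center of rotation, 3-vector (m).
#' @return numeric 3-vector, N m per N.
#' @export
moment_coefficient <- function(actuator, joint, joint_center) {
  act <- as.list(actuator)
  if (!(joint %in% parse_spans(act$spans))) return(c(0, 0, 0))
  rhat <- effective_direction(act)
  cj <- as_point3(joint_center, "joint_center")
  if (joint %in% parse_spans(act$origin_side_joints)) {
    return(cross3(c(act$ox, act$oy, act$oz) - cj, rhat))
  }
  ap <- attachment_points(act)
  out <- c(0, 0, 0)
  for (k in seq_len(nrow(ap$points))) {
    out <- out + ap$weights[k] * cross3(ap$points[k, ] - cj, rhat)
  }
  out
}

#' Assemble the moment-balance system matrix
#'
#' Stacks, for each joint, a 3-row block whose column `i` is the moment
#' coefficient of actuator `i` about that joint; multiplying by the vector
#' of actuator force magnitudes gives the total muscular moment per joint.
#' Setting that product equal to the net joint moments yields the (typically
#' underdetermined) linear system that static optimization resolves.
#'
#' @param geometry a [limb_geometry()].
#' @param joints joint order for the row blocks (default: the geometry's
#'   joint order).
#' @return object of class `system_matrix`: list with `A` (`3J x N` matrix,
#'   N m per N), `joints`, and `actuators` (column names).
#' @export
assemble_system <- function(geometry, joints = geometry$joints$name) {
  stopifnot(inherits(geometry, "limb_geometry"))
  miss <- setdiff(joints, geometry$joints$name)
  if (length(miss)) stop("unknown joint '", miss[1L], "'", call. = FALSE)
  acts <- geometry$actuators
  n <- nrow(acts)
  A <- matrix(0, nrow = 3L * length(joints), ncol = n,
              dimnames = list(
                paste(rep(joints, each = 3L), c("x", "y", "z"), sep = "."),
                acts$name))
  for (jdx in seq_along(joints)) {
    cj <- joint_center(geometry, joints[jdx])
    rows <- (3L * (jdx - 1L) + 1L):(3L * jdx)
    for (i in seq_len(n)) {
      A[rows, i] <- moment_coefficient(acts[i, ], joints[jdx], cj)
    }
  }
  structure(list(A = A, joints = joints, actuators = acts$name),
            class = "system_matrix")
}

#' @export
print.system_matrix <- function(x, ...) {
  cat("Moment-balance system:", nrow(x$A), "rows (",
      length(x$joints), "joints ) x", ncol(x$A), "actuators\n")
  invisible(x)
}

#' Write a system matrix to delimited text
#'
#' Debug dump of the assembled coefficients (rows = joint axes, columns =
#' actuators), tab-separated.
#'
#' @param system a `system_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_system_matrix <- function(system, path) {
  stopifnot(inherits(system, "system_matrix"))
  df <- data.frame(row = rownames(system$A), system$A,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
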