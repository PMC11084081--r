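#' Construct a limb geometry
#'
#' Container for the static hindlimb model: joint centers of rotation,
#' limb segments with mass fractions and centers of mass, and the line
#' actuators (muscles and ligaments) that span the joints. All coordinates
#' share one right-handed frame in meters with +z vertically up; gravity acts
#' along -z.
#'
#' @param joints data.frame with columns `name`, `x`, `y`, `z` (meters).
#'   Typical joint names are `"coxofemoral"`, `"femorotibial"`,
#'   `"femoropatellar"`, but free labels are allowed.
#' @param actuators data.frame of line actuators, one row per muscle or
#'   ligament. Required columns: `name`, `kind` (`"muscle"` or `"ligament"`),
#'   origin `ox, oy, oz`, insertion `ix, iy, iz` (meters), `pcsa_m2`
#'   (physiological cross-sectional area, m^2), `fmax_N` (maximum isometric
#'   force, N), `spans` (semicolon-separated joint names), `attaches_femur`
#'   (logical), `area_label` (attachment-area handle for FEA export).
#'   Optional columns: `dx, dy, dz` (direction override near the insertion,
#'   used instead of the origin-to-insertion line for curved muscles such as
#'   the biceps femoris group), `fmin_N` (explicit lower force bound),
#'   secondary insertion points `p2x..p2z`, `p3x..p3z` with weights
#'   `w1, w2, w3` summing to 1 (used for broad insertions such as the tensor
#'   fasciae latae), and `origin_side_joints` (semicolon list of spanned
#'   joints for which the origin-side point carries the lever arm; default is
#'   the insertion side).
#' @param segments data.frame with columns `name`, `mass_fraction`
#'   (share of body mass), `x`, `y`, `z` (center of mass, meters). The
#'   canonical five-subunit standing model uses `thigh`, `crus`,
#'   `metatarsus`, `hind pastern`, `hind hoof`.
#' @param body_mass body mass in kg.
#' @param hoof_contact 3-vector, point of ground reaction force application
#'   (center of the hoof), meters.
#'
#' @return An object of class `limb_geometry`.
#' @seealso [read_geometry()], [assemble_system()], [net_joint_moments()]
#' @export
limb_geometry <- function(joints, actuators, segments, body_mass,
                          hoof_contact) {
  geom <- structure(
    list(joints = as.data.frame(joints),
         actuators = normalize_actuators(as.data.frame(actuators)),
         segments = as.data.frame(segments),
         body_mass = as.numeric(body_mass),
         hoof_contact = as_point3(hoof_contact, "hoof_contact")),
    class = "limb_geometry")
  validate_geometry(geom)
  geom
}

# Fill optional actuator columns with defaults so downstream code can rely on
# a fixed schema.
normalize_actuators <- function(acts) {
  n <- nrow(acts)
  defaults <- list(dx = NA_real_, dy = NA_real_, dz = NA_real_,
                   fmin_N = NA_real_,
                   p2x = NA_real_, p2y = NA_real_, p2z = NA_real_,
                   p3x = NA_real_, p3y = NA_real_, p3z = NA_real_,
                   w1 = 1, w2 = 0, w3 = 0,
                   origin_side_joints = "")
  for (col in names(defaults)) {
    if (is.null(acts[[col]])) acts[[col]] <- rep(defaults[[col]], n)
  }
  acts$attaches_femur <- as.logical(acts$attaches_femur)
  for (col in c("name", "kind", "spans", "area_label",
                "origin_side_joints")) {
    acts[[col]] <- as.character(acts[[col]])
  }
  num_cols <- c("ox", "oy", "oz", "ix", "iy", "iz", "dx", "dy", "dz",
                "pcsa_m2", "fmax_N", "fmin_N", "p2x", "p2y", "p2z",
                "p3x", "p3y", "p3z", "w1", "w2", "w3")
  for (col in num_cols) acts[[col]] <- as.numeric(acts[[col]])
  # canonical column order so geometries compare equal after I/O
  acts <- acts[, c("name", "kind", "ox", "oy", "oz", "ix", "iy", "iz",
                   "dx", "dy", "dz", "pcsa_m2", "fmax_N", "fmin_N",
                   "spans", "attaches_femur", "area_label",
                   "p2x", "p2y", "p2z", "p3x", "p3y", "p3z",
                   "w1", "w2", "w3", "origin_side_joints")]
  rownames(acts) <- NULL
  acts
}

validate_geometry <- function(geom) {
  jn <- geom$joints$name
  if (anyDuplicated(jn)) {
    stop("joints: duplicated joint name '", jn[duplicated(jn)][1L], "'",
         call. = FALSE)
  }
  for (col in c("x", "y", "z")) {
    if (any(!is.finite(geom$joints[[col]]))) {
      stop("joints: non-finite coordinate in column '", col, "'",
           call. = FALSE)
    }
  }
  if (!is.finite(geom$body_mass) || geom$body_mass <= 0) {
    stop("body_mass must be a positive number", call. = FALSE)
  }
  segs <- geom$segments
  if (nrow(segs)) {
    bad <- which(!is.finite(segs$mass_fraction) | segs$mass_fraction < 0 |
                   segs$mass_fraction >= 1)
    if (length(bad)) {
      stop("segments: mass_fraction out of [0, 1) in row ", bad[1L],
           " ('", segs$name[bad[1L]], "')", call. = FALSE)
    }
  }
  acts <- geom$actuators
  for (i in seq_len(nrow(acts))) {
    a <- acts[i, ]
    row_id <- sprintf("actuator row %d ('%s')", i, a$name)
    if (!a$kind %in% c("muscle", "ligament")) {
      stop(row_id, ": kind must be 'muscle' or 'ligament'", call. = FALSE)
    }
    if (a$kind == "muscle" && (!is.finite(a$pcsa_m2) || a$pcsa_m2 <= 0)) {
      stop(row_id, ": pcsa_m2 must be > 0 for muscles", call. = FALSE)
    }
    if (!is.finite(a$fmax_N) || a$fmax_N < 0) {
      stop(row_id, ": fmax_N must be a nonnegative number", call. = FALSE)
    }
    if (!is.na(a$fmin_N)) {
      if (a$fmin_N < 0) stop(row_id, ": fmin_N must be >= 0", call. = FALSE)
      if (a$fmin_N > a$fmax_N) {
        stop(row_id, ": fmin_N exceeds fmax_N", call. = FALSE)
      }
    }
    w <- attachment_weights(a)
    if (abs(sum(w) - 1) > 1e-9) {
      stop(row_id, ": attachment weights w1..w3 must sum to 1", call. = FALSE)
    }
    spanned <- parse_spans(a$spans)
    unknown <- setdiff(spanned, jn)
    if (length(unknown)) {
      stop(row_id, ": spans unknown joint '", unknown[1L], "'",
           call. = FALSE)
    }
  }
  invisible(geom)
}

parse_spans <- function(s) {
  if (is.null(s) || !length(s) || is.na(s) || !nzchar(s)) {
    return(character(0))
  }
  trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
}

has_field <- function(act, field) {
  !is.null(act[[field]]) && length(act[[field]]) && !is.na(act[[field]])
}

attachment_weights <- function(act) {
  w <- c(if (has_field(act, "w1")) act$w1 else 1,
         if (has_field(act, "w2")) act$w2 else 0,
         if (has_field(act, "w3")) act$w3 else 0)
  keep <- c(TRUE, has_field(act, "p2x"), has_field(act, "p3x"))
  w[keep]
}

# Insertion-side attachment points (1-3 rows) with their weight fractions.
attachment_points <- function(act) {
  pts <- rbind(c(act$ix, act$iy, act$iz))
  if (has_field(act, "p2x")) pts <- rbind(pts, c(act$p2x, act$p2y, act$p2z))
  if (has_field(act, "p3x")) pts <- rbind(pts, c(act$p3x, act$p3y, act$p3z))
  list(points = pts, weights = attachment_weights(act))
}

joint_center <- function(geom, joint) {
  i <- match(joint, geom$joints$name)
  if (is.na(i)) stop("unknown joint '", joint, "'", call. = FALSE)
  as.numeric(geom$joints[i, c("x", "y", "z")])
}

#' Effective line of action of an actuator
#'
#' The unit direction along which the actuator pulls. By default this is the
#' normalized origin-to-insertion vector. When a direction override is
#' present (columns `dx, dy, dz`) it is normalized and used instead; this
#' models curved muscles whose force direction near the insertion differs
#' from the straight origin-insertion line (biceps femoris, semitendinosus,
#' semimembranosus).
#'
#' @param actuator one-row data.frame (a row of `geometry$actuators`) or a
#'   list with fields `ox..oz`, `ix..iz` and optional `dx..dz`.
#' @return unit numeric 3-vector.
#' @export
effective_direction <- function(actuator) {
  a <- as.list(actuator)
  if (!is.null(a$dx) && !is.na(a$dx)) {
    return(unit_vector(c(a$dx, a$dy, a$dz), "direction override"))
  }
  v <- c(a$ix - a$ox, a$iy - a$oy, a$iz - a$oz)
  if (vec_norm(v) < 1e-300) {
    stop("actuator '", if (is.null(a$name)) "?" else a$name,
         "': origin equals insertion and no direction override given",
         call. = FALSE)
  }
  unit_vector(v, "line of action")
}

#' Least-squares sphere fit
#'
#' Fits a sphere to surface points, as used to locate the femoral head
#' center (hip center of rotation). The algebraic (linear) fit solves
#' `|p|^2 = 2 c . p + d` in least squares; an optional Gauss-Newton polish
#' refines center and radius geometrically.
#'
#' @param points numeric n x 3 matrix (or data.frame with x,y,z), n >= 4,
#'   not coplanar.
#' @param polish logical, run the geometric refinement (default TRUE).
#' @return list with `center` (3-vector), `radius`, and `residual` (RMS of
#'   distance-to-sphere errors).
#' @export
fit_sphere <- function(points, polish = TRUE) {
  pts <- as.matrix(points)
  if (!is.null(colnames(pts)) && all(c("x", "y", "z") %in% colnames(pts))) {
    pts <- pts[, c("x", "y", "z"), drop = FALSE]
  }
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L || any(!is.finite(pts))) {
    stop("points must be a finite n x 3 matrix", call. = FALSE)
  }
  n <- nrow(pts)
  if (n < 4L) {
    stop("sphere fit needs at least 4 points (got ", n, ")", call. = FALSE)
  }
  X <- cbind(2 * pts, 1)
  qrX <- qr(X)
  if (qrX$rank < 4L) {
    stop("sphere fit is degenerate: points are coplanar or coincident",
         call. = FALSE)
  }
  b <- rowSums(pts^2)
  beta <- qr.coef(qrX, b)
  center <- beta[1:3]
  r2 <- beta[4L] + sum(center^2)
  if (r2 <= 0) stop("sphere fit is degenerate: nonpositive radius",
                    call. = FALSE)
  radius <- sqrt(r2)

  if (polish) {
    # Gauss-Newton on geometric residuals d_i(c) - r.
    for (iter in 1:50) {
      diffs <- sweep(pts, 2, center)
      d <- sqrt(rowSums(diffs^2))
      r <- mean(d)
      res <- d - r
      J <- cbind(-diffs / pmax(d, 1e-300), -1)
      step <- tryCatch(qr.coef(qr(J), -res), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      center <- center + step[1:3]
      radius <- r + step[4L]
      if (vec_norm(step) < 1e-14 * max(1, radius)) break
    }
  }
  d <- sqrt(rowSums(sweep(pts, 2, center)^2))
  list(center = unname(center), radius = unname(radius),
       residual = sqrt(mean((d - radius)^2)))
}

#' Derive joint centers from bony landmarks
#'
#' Standard constructions for the three joints of the proximal hindlimb:
#' the coxofemoral (hip) center is the center of a sphere fitted to femoral
#' head surface points; the femorotibial (stifle) center is the midpoint of
#' the lateral and medial femoral epicondyles; the femoropatellar center is
#' the supplied patella-femur contact point (for standing the complex
#' patellofemoral articulation reduces to a contact point).
#'
#' @param landmarks data.frame with columns `label`, `x`, `y`, `z`. Expected
#'   labels: `"epicondyle_lateral"`, `"epicondyle_medial"`, one
#'   `"patellar_contact"`, and >= 4 rows whose label starts with
#'   `"femoral_head"` (head surface points).
#' @return data.frame of joints (`name`, `x`, `y`, `z`) for
#'   `coxofemoral`, `femorotibial`, `femoropatellar`.
#' @export
derive_joint_centers <- function(landmarks) {
  lm <- as.data.frame(landmarks)
  need <- function(label) {
    i <- which(lm$label == label)
    if (!length(i)) {
      stop("missing landmark '", label, "'", call. = FALSE)
    }
    as.numeric(lm[i[1L], c("x", "y", "z")])
  }
  lat <- need("epicondyle_lateral")
  med <- need("epicondyle_medial")
  if (vec_norm(lat - med) < 1e-12) {
    warning("lateral and medial epicondyles coincide; ",
            "femorotibial center is degenerate")
  }
  stifle <- (lat + med) / 2

  head_rows <- grepl("^femoral_head", lm$label)
  if (sum(head_rows) < 4L) {
    stop("missing landmark 'femoral_head*': need >= 4 head surface points",
         call. = FALSE)
  }
  hip <- fit_sphere(lm[head_rows, c("x", "y", "z")])$center
  pat <- need("patellar_contact")

  data.frame(name = c("coxofemoral", "femorotibial", "femoropatellar"),
             x = c(hip[1L], stifle[1L], pat[1L]),
             y = c(hip[2L], stifle[2L], pat[2L]),
             z = c(hip[3L], stifle[3L], pat[3L]))
}

#' @export
print.limb_geometry <- function(x, ...) {
  cat("Limb geometry:", nrow(x$joints), "joints,",
      nrow(x$actuators), "actuators,",
      nrow(x$segments), "segments\n")
  cat("  body mass:", x$body_mass, "kg; hoof contact at (",
      paste(signif(x$hoof_contact, 4), collapse = ", "), ") m\n")
  invisible(x)
}
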