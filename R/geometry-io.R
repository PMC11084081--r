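#' Read and write limb geometries
#'
#' Geometries are stored as a single YAML document with blocks `body_mass_kg`,
#' `hoof_contact`, `joints`, `segments` and `actuators`. Units are meters and
#' newtons throughout (documented in the file header). `write_geometry()`
#' followed by `read_geometry()` reproduces the geometry exactly up to
#' numeric formatting (15 significant digits); all type invariants are
#' re-validated on read, and violations raise errors naming the offending
#' field and row.
#'
#' @param path file path of the YAML geometry document.
#' @param geometry a [limb_geometry()] object.
#' @return `read_geometry()` returns a `limb_geometry`;
#'   `write_geometry()` returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  doc <- yaml::read_yaml(path)
  for (block in c("body_mass_kg", "hoof_contact", "joints", "actuators")) {
    if (is.null(doc[[block]])) {
      stop("geometry file is missing block '", block, "'", call. = FALSE)
    }
  }
  joints <- rows_to_df(doc$joints, c("name", "x", "y", "z"), "joints")
  segments <- if (length(doc$segments)) {
    rows_to_df(doc$segments, c("name", "mass_fraction", "x", "y", "z"),
               "segments")
  } else {
    data.frame(name = character(0), mass_fraction = numeric(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
  }
  required <- c("name", "kind", "ox", "oy", "oz", "ix", "iy", "iz",
                "pcsa_m2", "fmax_N", "spans", "attaches_femur", "area_label")
  acts <- rows_to_df(doc$actuators, required, "actuators",
                     optional = c("dx", "dy", "dz", "fmin_N",
                                  "p2x", "p2y", "p2z", "p3x", "p3y", "p3z",
                                  "w1", "w2", "w3", "origin_side_joints"))
  acts$attaches_femur <- as.logical(acts$attaches_femur)
  limb_geometry(joints = joints, actuators = acts, segments = segments,
                body_mass = doc$body_mass_kg,
                hoof_contact = unlist(doc$hoof_contact))
}

rows_to_df <- function(rows, required, block, optional = character(0)) {
  if (!length(rows)) stop("block '", block, "' is empty", call. = FALSE)
  out <- lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    missing <- setdiff(required, names(r))
    if (length(missing)) {
      stop(sprintf("%s row %d: missing field '%s'", block, i, missing[1L]),
           call. = FALSE)
    }
    r[setdiff(names(r), c(required, optional))] <- NULL
    for (f in setdiff(optional, names(r))) r[[f]] <- NA
    as.data.frame(r[c(required, optional)])
  })
  do.call(rbind, out)
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "limb_geometry"))
  df_to_rows <- function(df, drop_na = character(0)) {
    lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, , drop = FALSE])
      r <- lapply(r, function(v) if (is.factor(v)) as.character(v) else v)
      for (f in drop_na) if (f %in% names(r) && is.na(r[[f]])) r[[f]] <- NULL
      r
    })
  }
  opt <- c("dx", "dy", "dz", "fmin_N", "p2x", "p2y", "p2z",
           "p3x", "p3y", "p3z")
  doc <- list(
    units = "meters, newtons, kilograms; right-handed frame, +z up",
    body_mass_kg = geometry$body_mass,
    hoof_contact = as.list(setNames(geometry$hoof_contact,
                                    c("x", "y", "z"))),
    joints = df_to_rows(geometry$joints),
    segments = df_to_rows(geometry$segments),
    actuators = df_to_rows(geometry$actuators, drop_na = opt))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
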