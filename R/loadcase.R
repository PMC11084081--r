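#' Select femoral loads for finite-element analysis
#'
#' Applies the published handoff rule: keep every actuator that attaches to
#' the femur and whose solved force strictly exceeds the threshold
#' (default 100 N, roughly 10 kg-force — smaller loads do not materially
#' change the stress distribution). Forces are tagged with their
#' attachment-area label and marked for uniform distribution over that
#' area.
#'
#' @param forces a `force_solution` (requires `geometry`) or a data.frame
#'   with columns `name`, `force_N`, `attaches_femur` and optionally
#'   `area_label` (e.g. [standing_forces_reference()]).
#' @param geometry optional [limb_geometry()]; supplies attachment flags,
#'   area labels and line-of-action vectors for a `force_solution`.
#' @param threshold inclusion cutoff in N; strictly-greater comparison, so
#'   a force of exactly the threshold is excluded.
#' @return data.frame of load-case entries: `name`, `force_N`, `fx`, `fy`,
#'   `fz` (force vector, NA when no geometry is available), `area_label`,
#'   `distribution` (always `"uniform"`).
#' @export
select_femoral_loads <- function(forces, geometry = NULL, threshold = 100) {
  if (inherits(forces, "force_solution")) {
    if (is.null(geometry)) {
      stop("selecting from a force_solution requires the geometry",
           call. = FALSE)
    }
    acts <- geometry$actuators
    dirs <- t(vapply(seq_len(nrow(acts)),
                     function(i) effective_direction(acts[i, ]),
                     numeric(3)))
    tab <- data.frame(name = acts$name,
                      force_N = as.numeric(forces$forces[acts$name]),
                      attaches_femur = acts$attaches_femur,
                      area_label = acts$area_label,
                      dx = dirs[, 1L], dy = dirs[, 2L], dz = dirs[, 3L],
                      stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(forces)
    need <- c("name", "force_N", "attaches_femur")
    miss <- setdiff(need, names(tab))
    if (length(miss)) {
      stop("force table missing column '", miss[1L], "'", call. = FALSE)
    }
    if (is.null(tab$area_label)) tab$area_label <- NA_character_
    tab$dx <- tab$dy <- tab$dz <- NA_real_
  }
  sel <- tab$attaches_femur & tab$force_N > threshold
  out <- tab[sel, , drop = FALSE]
  data.frame(name = out$name,
             force_N = out$force_N,
             fx = out$force_N * out$dx,
             fy = out$force_N * out$dy,
             fz = out$force_N * out$dz,
             area_label = out$area_label,
             distribution = rep("uniform", nrow(out)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble an FEA load case
#'
#' Bundles selected femoral loads with the boundary-condition metadata of
#' the standing analysis: the medial condyle contact area acts as a fixed
#' support and the lateral condyle is constrained in the proximal-distal
#' and anterior-posterior directions (leaving medial-lateral strain free,
#' so the system is not statically overdetermined). The femorotibial
#' contact force is therefore represented by these supports rather than as
#' an applied load, while the coxofemoral and femoropatellar contact forces
#' may be applied to the femur as loads.
#'
#' @param entries data.frame from [select_femoral_loads()].
#' @param boundary_conditions list; defaults describe the condylar
#'   supports.
#' @param contact_loads named logical flags stating which joint contact
#'   forces are exported as applied loads.
#' @param threshold_N the selection cutoff used, stored for provenance.
#' @return object of class `load_case`.
#' @export
load_case <- function(entries,
                      boundary_conditions = list(
                        medial_condyle = "fixed",
                        lateral_condyle = c("proximal-distal",
                                            "anterior-posterior")),
                      contact_loads = c(coxofemoral = TRUE,
                                        femoropatellar = TRUE,
                                        femorotibial = FALSE),
                      threshold_N = 100) {
  structure(list(schema_version = "1.0",
                 entries = as.data.frame(entries),
                 boundary_conditions = boundary_conditions,
                 contact_loads = as.list(contact_loads),
                 threshold_N = threshold_N),
            class = "load_case")
}

#' Export / import an FEA load case
#'
#' `export_loadcase()` writes the load case as a schema-versioned JSON
#' document and a flat CSV (`name, force_N, fx, fy, fz, area_label`) next
#' to it (same stem, `.csv` extension). Output is deterministic:
#' byte-identical across runs for identical input. `read_loadcase()`
#' restores the structure from the JSON file.
#'
#' @param loadcase a [load_case()].
#' @param path output path for the JSON document (used as stem for the
#'   CSV).
#' @return `export_loadcase()` returns `path` invisibly;
#'   `read_loadcase()` returns a `load_case`.
#' @export
export_loadcase <- function(loadcase, path) {
  stopifnot(inherits(loadcase, "load_case"))
  json <- jsonlite::toJSON(unclass(loadcase), dataframe = "rows",
                           auto_unbox = TRUE, digits = I(10), pretty = TRUE,
                           na = "null")
  con <- file(path, open = "wb")
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  close(con)

  csv_path <- sub("\\.[^.]*$", "", path)
  csv_path <- paste0(csv_path, ".csv")
  e <- loadcase$entries
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))
  lines <- c("name,force_N,fx,fy,fz,area_label",
             if (nrow(e)) sprintf("%s,%s,%s,%s,%s,%s",
                                  e$name, fmt(e$force_N), fmt(e$fx),
                                  fmt(e$fy), fmt(e$fz), e$area_label))
  con <- file(csv_path, open = "wb")
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(path)
}

#' @rdname export_loadcase
#' @export
read_loadcase <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  entries <- as.data.frame(doc$entries)
  if (!nrow(entries)) {
    entries <- data.frame(name = character(0), force_N = numeric(0),
                          fx = numeric(0), fy = numeric(0),
                          fz = numeric(0), area_label = character(0),
                          distribution = character(0),
                          stringsAsFactors = FALSE)
  }
  load_case(entries,
            boundary_conditions = doc$boundary_conditions,
            contact_loads = doc$contact_loads,
            threshold_N = doc$threshold_N)
}

#' @export
print.load_case <- function(x, ...) {
  cat("FEA load case (schema", x$schema_version, "):",
      nrow(x$entries), "femoral loads, threshold >",
      x$threshold_N, "N\n")
  if (nrow(x$entries)) {
    print(x$entries[, c("name", "force_N", "area_label")], row.names = FALSE)
  }
  invisible(x)
}
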