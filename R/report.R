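#' Material card for safety-factor reporting
#'
#' Yield and ultimate strengths of an implant or bone material. Compressive
#' values may be given with either sign; magnitudes are stored.
#'
#' @param name material name.
#' @param yield_compressive,yield_tensile yield strengths, MPa.
#' @param ultimate_compressive,ultimate_tensile optional ultimate
#'   strengths, MPa.
#' @return object of class `material_card`.
#' @export
material_card <- function(name, yield_compressive, yield_tensile,
                          ultimate_compressive = NA_real_,
                          ultimate_tensile = NA_real_) {
  vals <- c(yield_compressive = abs(yield_compressive),
            yield_tensile = abs(yield_tensile),
            ultimate_compressive = abs(ultimate_compressive),
            ultimate_tensile = abs(ultimate_tensile))
  if (any(!is.na(vals) & vals <= 0)) {
    stop("material strengths must be nonzero", call. = FALSE)
  }
  structure(c(list(name = name), as.list(vals)), class = "material_card")
}

#' Read a material card from YAML
#'
#' Expects top-level fields `name`, `yield_compressive_MPa`,
#' `yield_tensile_MPa` and optional `ultimate_*_MPa`.
#'
#' @param path YAML file path.
#' @return a [material_card()].
#' @export
read_material_card <- function(path) {
  doc <- yaml::read_yaml(path)
  for (f in c("name", "yield_compressive_MPa", "yield_tensile_MPa")) {
    if (is.null(doc[[f]])) stop("material card missing field '", f, "'",
                                call. = FALSE)
  }
  material_card(doc$name, doc$yield_compressive_MPa, doc$yield_tensile_MPa,
                doc$ultimate_compressive_MPa %||% NA_real_,
                doc$ultimate_tensile_MPa %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sum of forces over a named muscle group
#'
#' @param forces a `force_solution`, a named numeric vector, or a
#'   data.frame with columns `name` and `force_N`.
#' @param members character vector of member names (e.g. the four
#'   quadriceps heads).
#' @return total force in N.
#' @export
group_sum <- function(forces, members) {
  v <- extract_forces(forces)
  miss <- setdiff(members, names(v))
  if (length(miss)) {
    stop("unknown actuator '", miss[1L], "' in group", call. = FALSE)
  }
  sum(v[members])
}

extract_forces <- function(forces) {
  if (inherits(forces, "force_solution")) return(forces$forces)
  if (is.data.frame(forces)) {
    if (!all(c("name", "force_N") %in% names(forces))) {
      stop("force table needs columns 'name' and 'force_N'", call. = FALSE)
    }
    return(setNames(forces$force_N, forces$name))
  }
  if (is.numeric(forces) && !is.null(names(forces))) return(forces)
  stop("cannot interpret 'forces'", call. = FALSE)
}

#' Implant safety factor
#'
#' Ratio of material yield strength to peak computed stress, rounded half
#' away from zero to one decimal (the precision such factors are reported
#' at). Signs are ignored, so compressive pairs may be given as negative
#' values. A factor above 1 indicates no plastic deformation is expected.
#'
#' @param yield_MPa material yield strength, MPa (nonzero).
#' @param peak_stress_MPa peak computed stress, MPa (nonzero).
#' @return scalar ratio, one decimal.
#' @examples
#' safety_factor(-1074, -348)  # 3.1
#' safety_factor(982, 197)     # 5.0
#' @export
safety_factor <- function(yield_MPa, peak_stress_MPa) {
  if (!is.finite(peak_stress_MPa) || peak_stress_MPa == 0) {
    stop("peak stress must be nonzero", call. = FALSE)
  }
  if (!is.finite(yield_MPa) || yield_MPa == 0) {
    stop("yield strength must be nonzero", call. = FALSE)
  }
  round_half_up(abs(yield_MPa) / abs(peak_stress_MPa), 1)
}

#' Muscle-group and safety-factor report
#'
#' Combines group force sums and implant safety factors into one list,
#' suitable for JSON serialization.
#'
#' @param forces force table (see [group_sum()]).
#' @param groups named list of character vectors (group -> members).
#' @param material optional [material_card()].
#' @param peak_compressive_MPa,peak_tensile_MPa optional peak stresses from
#'   an external finite-element analysis, MPa.
#' @return list with `group_forces_N` and, when material and peaks are
#'   given, `safety_factor_compressive` / `safety_factor_tensile`.
#' @export
force_report <- function(forces, groups = list(), material = NULL,
                         peak_compressive_MPa = NULL,
                         peak_tensile_MPa = NULL) {
  out <- list(group_forces_N = lapply(groups, group_sum, forces = forces))
  if (!is.null(material)) {
    if (!is.null(peak_compressive_MPa)) {
      out$safety_factor_compressive <-
        safety_factor(material$yield_compressive, peak_compressive_MPa)
    }
    if (!is.null(peak_tensile_MPa)) {
      out$safety_factor_tensile <-
        safety_factor(material$yield_tensile, peak_tensile_MPa)
    }
  }
  out
}

#' The four quadriceps femoris heads
#'
#' Member names for the quadriceps group in [standing_forces_reference()].
#'
#' @return character vector of four muscle names.
#' @export
quadriceps_heads <- function() {
  c("M. rectus femoris", "M. vastus lateralis", "M. vastus medialis",
    "M. vastus intermedius")
}
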