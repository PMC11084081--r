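#' Run the full standing analysis
#'
#' One-call pipeline: external loads, net joint moments, moment-balance
#' system, physiological bounds, static optimization, and joint contact
#' forces.
#'
#' @param geometry a [limb_geometry()].
#' @param loads an [external_loads()] object; default [standing_loads()]
#'   of the geometry.
#' @param moments a `net_joint_moments` object; default computed from
#'   `loads` by [net_joint_moments()]. Pass precomputed moments (e.g. a
#'   synthetic instance's reference-derived targets) to skip the inverse
#'   statics.
#' @param bounds a `bound_spec`; default [default_bounds()] with the GRF
#'   magnitude of `loads`.
#' @param control solver control list, see [solve_forces()].
#' @return list with `loads`, `moments`, `system`, `bounds`, `solution`,
#'   `contacts` (data.frame from [contact_forces()]).
#' @export
standing_analysis <- function(geometry, loads = standing_loads(geometry),
                              moments = net_joint_moments(geometry, loads),
                              bounds = default_bounds(
                                geometry$actuators,
                                grf_magnitude = vec_norm(loads$grf)),
                              control = list()) {
  system <- assemble_system(geometry)
  pcsa <- setNames(geometry$actuators$pcsa_m2, geometry$actuators$name)
  solution <- solve_forces(system, moments, pcsa, bounds, control)
  contacts <- contact_forces(geometry, solution, loads)
  list(loads = loads, moments = moments, system = system,
       bounds = bounds, solution = solution, contacts = contacts)
}
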