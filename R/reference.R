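#' Reference muscle and ligament forces for the standing hindlimb
#'
#' Published solution of the static optimization for a 514 kg horse in
#' square standing: per-actuator force magnitudes together with whether
#' each actuator attaches to the femur (the flag that, combined with the
#' 100 N cutoff, decides inclusion in the femoral finite-element load
#' case). Ships with the package so that group sums, load-case selection
#' and report generation can be exercised and validated without the full
#' geometry inputs.
#'
#' The femur-attachment flags are anatomical: the gluteals insert on the
#' trochanters, adductor and pectineus on the femoral body, the vasti and
#' the gastrocnemius / superficial digital flexor / peroneus tertius /
#' extensor digitalis longus origins sit on the femur, and the tensor
#' fasciae latae reaches the femur through its split insertion. The
#' hamstrings (biceps femoris, semitendinosus, semimembranosus), gracilis,
#' sartorius, rectus femoris and the patellar ligaments bypass the femur.
#'
#' @return data.frame with columns `name`, `kind`, `force_N`,
#'   `attaches_femur`, `area_label`.
#' @export
standing_forces_reference <- function() {
  df <- data.frame(
    name = c("M. tensor fasciae latae", "M. gastrocnemius", "M. pectineus",
             "M. superficial digital flexor", "M. vastus medialis",
             "M. biceps femoris", "M. gluteus superficialis",
             "M. peroneus tertius", "M. gluteus medius",
             "M. vastus lateralis", "M. adductor", "M. gracilis",
             "M. gluteus profundus", "M. semimembranosus",
             "M. rectus femoris", "M. semitendinosus", "M. sartorius",
             "M. extensor digitalis longus", "M. vastus intermedius",
             "Lig. patellae intermediale", "Lig. patellae medialis",
             "Lig. patellae laterale"),
    kind = c(rep("muscle", 19L), rep("ligament", 3L)),
    force_N = c(2158, 1550, 1010, 905, 840, 834, 445, 285, 119, 66, 63,
                40, 32, 32, 32, 28, 24, 16, 13, 2092, 170, 0),
    attaches_femur = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                       FALSE, TRUE, TRUE, TRUE,
                       TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                       FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  df$area_label <- paste0("area_", gsub("[^a-z]+", "_",
                                        tolower(df$name)))
  df
}
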