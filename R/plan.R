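# Beams and plans. A plan is a list of main beams plus zero or more
# sub-beams; dose is normalized to 100% of prescription at the isocenter.

#' Treatment beam
#'
#' @param id Beam identifier string.
#' @param gantry,collimator Angles in degrees (IEC 61217).
#' @param isocenter Isocenter in DCS mm.
#' @param aperture An [mlc_aperture()].
#' @param weight Relative beam weight (>= 0).
#' @param role `"main"`, `"sub1"` or `"sub2"`.
#' @param sad Source-to-axis distance in mm.
#' @param energy_mv Nominal photon energy label in MV (informational).
#' @return An object of class `fif_beam`.
#' @export
fif_beam <- function(id, gantry, collimator = 0, isocenter = c(0, 0, 0),
                     aperture, weight = 1, role = "main", sad = 1000,
                     energy_mv = 10) {
  stopifnot(is.character(id), weight >= 0, role %in% c("main", "sub1", "sub2"),
            inherits(aperture, "mlc_aperture"))
  structure(list(id = id, role = role, gantry = gantry %% 360,
                 collimator = collimator %% 360, isocenter = as.numeric(isocenter),
                 sad = sad, energy_mv = energy_mv, aperture = aperture,
                 weight = weight),
            class = "fif_beam")
}

beam_geom <- function(beam) {
  beam_geometry(beam$gantry, beam$collimator, beam$isocenter, beam$sad)
}

#' Treatment plan
#'
#' @param beams List of [fif_beam()] objects; at least one `"main"` beam.
#' @param prescription_gy Total prescription dose in Gy.
#' @param fractions Number of fractions.
#' @return An object of class `fif_plan`.
#' @export
fif_plan <- function(beams, prescription_gy = 30, fractions = 15) {
  stopifnot(length(beams) >= 1,
            all(vapply(beams, inherits, logical(1), "fif_beam")))
  if (!any(vapply(beams, function(b) b$role == "main", logical(1))))
    stop("a plan needs at least one main beam")
  structure(list(beams = beams, prescription_gy = prescription_gy,
                 fractions = fractions, normalization = "100% at isocenter"),
            class = "fif_plan")
}

#' @export
print.fif_plan <- function(x, ...) {
  cat(sprintf("<fif_plan> %g Gy in %d fractions, %s\n",
              x$prescription_gy, x$fractions, x$normalization))
  for (b in x$beams)
    cat(sprintf("  %-12s %-5s gantry %5.1f col %5.1f weight %.4f\n",
                b$id, b$role, b$gantry, b$collimator, b$weight))
  invisible(x)
}

main_beams <- function(plan) Filter(function(b) b$role == "main", plan$beams)

plan_weights <- function(plan) {
  data.frame(id = vapply(plan$beams, `[[`, character(1), "id"),
             role = vapply(plan$beams, `[[`, character(1), "role"),
             gantry = vapply(plan$beams, `[[`, numeric(1), "gantry"),
             weight = vapply(plan$beams, `[[`, numeric(1), "weight"))
}
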