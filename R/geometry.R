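# Frame chain DCS -> ICS -> BCS -> BEV.
#
# DCS: DICOM patient axes (LPS), head-first supine. ICS: DCS translated so
# the isocenter is the origin. BCS: right-handed frame fixed to the
# collimator; at gantry = collimator = 0 the X' axis is cross-plane
# (patient right), Y' is vertical pointing at the source, Z' is in-plane
# (patient superior). Gantry rotates the frame about the fixed patient
# longitudinal axis, collimator about the beam axis Y', both in the
# IEC 61217 sense (gantry 90 deg puts the source at the patient's left).
# The source sits at (0, SAD, 0) in the BCS for every angle pair; the BEV
# plane is Y' = 0.

#' Beam geometry
#'
#' Isocentric beam description: isocenter position, gantry and collimator
#' angles, and source-to-axis distance (SAD).
#'
#' @param gantry Gantry angle in degrees (IEC 61217 scale).
#' @param collimator Collimator angle in degrees.
#' @param isocenter Isocenter in DCS millimetres (length 3).
#' @param sad Source-to-axis distance in millimetres (default 1000).
#' @return An object of class `beam_geometry`.
#' @export
beam_geometry <- function(gantry, collimator = 0, isocenter = c(0, 0, 0), sad = 1000) {
  stopifnot(is.finite(gantry), is.finite(collimator),
            length(isocenter) == 3L, all(is.finite(isocenter)), sad > 0)
  structure(list(gantry = gantry %% 360, collimator = collimator %% 360,
                 isocenter = as.numeric(isocenter), sad = as.numeric(sad)),
            class = "beam_geometry")
}

# BCS basis vectors expressed in DCS, as columns (X', Y', Z').
# At zero angles: X' = -x (patient right), Y' = -y (anterior, toward the
# source), Z' = +z (superior); this triad is right-handed. Gantry is an
# extrinsic rotation about the DCS z axis, collimator an intrinsic rotation
# about the frame's own Y' axis.
bcs_axes <- function(geom) {
  e0 <- cbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1))
  g <- geom$gantry * pi / 180
  c_ <- geom$collimator * pi / 180
  rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  ry <- matrix(c(cos(c_), 0, -sin(c_), 0, 1, 0, sin(c_), 0, cos(c_)), 3, 3)
  rz %*% e0 %*% ry
}

# source position in DCS
source_position <- function(geom) {
  geom$isocenter + geom$sad * bcs_axes(geom)[, 2]
}

as_point_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = FALSE, nrow = 1)
  stopifnot(ncol(p) == 3, all(is.finite(p)))
  p
}

#' Translate DCS points to the isocenter coordinate system
#'
#' @param p Point(s) in DCS millimetres: a length-3 vector or an n x 3 matrix.
#' @param geom A [beam_geometry()].
#' @return Points in the ICS (same shape as input, always a matrix).
#' @export
dcs_to_ics <- function(p, geom) {
  p <- as_point_matrix(p)
  sweep(p, 2, geom$isocenter, "-")
}

#' Rotate ICS points into the beam coordinate system
#'
#' Applies the gantry rotation (about the patient longitudinal axis) and the
#' collimator rotation (about the beam axis), IEC 61217 senses.
#'
#' @param p Point(s) in the ICS: length-3 vector or n x 3 matrix.
#' @param geom A [beam_geometry()].
#' @return n x 3 matrix of (X', Y', Z') BCS coordinates.
#' @export
ics_to_bcs <- function(p, geom) {
  p <- as_point_matrix(p)
  p %*% bcs_axes(geom)   # row vectors: p_bcs = t(M) %*% p
}

#' Project BCS points onto the beam's-eye-view plane
#'
#' Central projection from the source at (0, SAD, 0) onto the isocenter
#' plane Y' = 0:
#' `X_BEV = X' * SAD / (SAD - Y')`, `Z_BEV = Z' * SAD / (SAD - Y')`.
#'
#' @param p Point(s) in the BCS: length-3 vector or n x 3 matrix.
#' @param geom A [beam_geometry()].
#' @return n x 2 matrix with columns `X_BEV`, `Z_BEV` (mm at the isocenter
#'   plane).
#' @export
project_to_bev <- function(p, geom) {
  p <- as_point_matrix(p)
  denom <- geom$sad - p[, 2]
  if (any(denom <= 1e-9))
    stop("degenerate projection: point at or beyond the source plane (Y' >= SAD)")
  mag <- geom$sad / denom
  cbind(X_BEV = p[, 1] * mag, Z_BEV = p[, 3] * mag)
}

#' Full DCS-to-BEV projection
#'
#' Convenience composition of [dcs_to_ics()], [ics_to_bcs()] and
#' [project_to_bev()].
#'
#' @inheritParams dcs_to_ics
#' @return n x 2 matrix of BEV coordinates.
#' @export
dcs_to_bev <- function(p, geom) {
  project_to_bev(ics_to_bcs(dcs_to_ics(p, geom), geom), geom)
}
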