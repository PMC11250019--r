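# Synthetic fixtures: a head-like ellipsoid phantom and the two-opposed-
# lateral-field original plan. The lateral (beam-path) thickness of an
# ellipsoid shrinks toward the anterior/posterior poles, which is what puts
# the hotspots of an opposed-lateral plan in the frontal and occipital
# regions.

#' Generate a head-like density phantom with BODY and PTV masks
#'
#' BODY is an axis-aligned ellipsoid of water-equivalent density in air,
#' centred at the DCS origin; the PTV is BODY eroded by a metric margin so
#' that surface voxels are excluded from the target. An optional seeded
#' surface perturbation (a smooth random field of low-order sinusoids on
#' the unit sphere, amplitude `noise` mm) diversifies test cases.
#'
#' @param a,b,c Ellipsoid semi-axes in mm: lateral (x), anterior-posterior
#'   (y), superior-inferior (z). Defaults 70, 95, 80.
#' @param spacing Isotropic voxel spacing in mm (default 2.5, a typical
#'   planning dose-grid resolution).
#' @param erosion PTV erosion margin in mm (default 5).
#' @param noise Surface perturbation amplitude in mm (default 0, i.e. a
#'   smooth ellipsoid).
#' @param seed Integer seed for the surface perturbation.
#' @param pad Air margin around the ellipsoid in mm (default 5).
#' @return A list with elements `density` ([density_grid()]), `body` and
#'   `ptv` ([structure_mask()]s).
#' @export
make_head_phantom <- function(a = 70, b = 95, c = 80, spacing = 2.5,
                              erosion = 5, noise = 0, seed = 1, pad = 5) {
  stopifnot(spacing > 0, min(a, b, c) > 2 * spacing, noise >= 0)
  half <- c(a, b, c) + pad + noise
  n <- 2 * ceiling(half / spacing) + 1          # odd counts: centre voxel at 0
  origin <- -(n - 1) / 2 * spacing
  ax <- list(x = origin[1] + (seq_len(n[1]) - 1) * spacing,
             y = origin[2] + (seq_len(n[2]) - 1) * spacing,
             z = origin[3] + (seq_len(n[3]) - 1) * spacing)
  X <- array(ax$x, n)
  Y <- array(rep(ax$y, each = n[1]), n)
  Z <- array(rep(ax$z, each = n[1] * n[2]), n)

  if (noise > 0) {
    rng <- local({ set.seed(as.integer(seed)); list(
      dir = matrix(stats::rnorm(18), 6, 3),
      freq = stats::runif(6, 1, 3),
      phase = stats::runif(6, 0, 2 * pi),
      amp = stats::runif(6, 0.5, 1)) })
    rng$dir <- rng$dir / sqrt(rowSums(rng$dir^2))
    r <- sqrt(X^2 + Y^2 + Z^2)
    r[r == 0] <- 1
    s <- 0
    for (j in 1:6)
      s <- s + rng$amp[j] * sin(rng$freq[j] *
             (X * rng$dir[j, 1] + Y * rng$dir[j, 2] + Z * rng$dir[j, 3]) / r +
             rng$phase[j])
    s <- s / max(abs(s))
    # radial perturbation: compare |p| with the ellipsoid radius along p/|p|
    re <- 1 / sqrt((X / r / a)^2 + (Y / r / b)^2 + (Z / r / c)^2)
    body_arr <- sqrt(X^2 + Y^2 + Z^2) <= re + noise * s
    body_arr[X == 0 & Y == 0 & Z == 0] <- TRUE
  } else {
    body_arr <- (X / a)^2 + (Y / b)^2 + (Z / c)^2 <= 1
  }

  body <- structure_mask(body_arr, origin, spacing, "BODY")
  ptv <- mask_erode(body, erosion)
  ptv$label <- "PTV"
  list(density = density_grid(body_arr * 1.0, origin, spacing),
       body = body, ptv = ptv)
}

#' Build the two-opposed-lateral-field original plan
#'
#' Two beams at gantry 90 and 270 degrees (collimator 0), isocenter at the
#' PTV centroid (snapped to the nearest voxel centre), equal unit weights,
#' and rectangular MLC/jaw apertures enclosing the BEV projection of the
#' PTV with a fixed margin.
#'
#' @param body,ptv [structure_mask()]s from [make_head_phantom()].
#' @param margin Aperture margin around the projected PTV in mm (default 7,
#'   a typical clinical block margin).
#' @param bank An [mlc_bank()] (default [default_mlc_bank()]).
#' @param sad Source-to-axis distance in mm.
#' @param prescription_gy,fractions Prescription (default 30 Gy / 15).
#' @return An [fif_plan()] with two main beams.
#' @export
make_original_plan <- function(body, ptv, margin = 7, bank = default_mlc_bank(),
                               sad = 1000, prescription_gy = 30, fractions = 15) {
  stopifnot(inherits(ptv, "structure_mask"))
  centres <- voxel_centres(ptv)
  if (nrow(centres) == 0) stop("empty PTV")
  iso <- (nearest_voxel(ptv, colMeans(centres)) - 1) * ptv$spacing + ptv$origin

  half_vox <- ptv$spacing / 2
  beams <- lapply(seq_along(c(90, 270)), function(i) {
    g <- c(90, 270)[i]
    geom <- beam_geometry(g, 0, iso, sad)
    bev <- dcs_to_bev(centres, geom)
    jaw <- c(min(bev[, 1]) - margin - half_vox, max(bev[, 1]) + margin + half_vox,
             min(bev[, 2]) - margin - half_vox, max(bev[, 2]) + margin + half_vox)
    jaw <- c(floor(jaw[1]), ceiling(jaw[2]), floor(jaw[3]), ceiling(jaw[4]))
    fif_beam(id = sprintf("main-%d", i), gantry = g, collimator = 0,
             isocenter = iso, aperture = open_aperture(bank, jaw),
             weight = 1, role = "main", sad = sad)
  })
  fif_plan(beams, prescription_gy, fractions)
}
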