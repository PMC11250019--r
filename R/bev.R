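# Hotspot identification and projection into a binary beam's-eye-view
# raster at the isocenter plane.

#' Binary BEV raster
#'
#' A 2D boolean raster in the isocenter plane, axes aligned with
#' (X_BEV, Z_BEV). Pixel (i, j) is centred at
#' `(xmin + (i - 0.5) * pixel, zmin + (j - 0.5) * pixel)`.
#'
#' @param xlim,zlim Extent in mm, `c(lo, hi)`.
#' @param pixel Pixel size in mm (default 1.0, finer than both leaf widths).
#' @return An object of class `bev_raster` with all pixels FALSE.
#' @export
bev_raster <- function(xlim, zlim, pixel = 1.0) {
  stopifnot(pixel > 0, xlim[1] < xlim[2], zlim[1] < zlim[2])
  nx <- ceiling((xlim[2] - xlim[1]) / pixel)
  nz <- ceiling((zlim[2] - zlim[1]) / pixel)
  structure(list(values = matrix(FALSE, nx, nz),
                 xmin = xlim[1], zmin = zlim[1], pixel = pixel),
            class = "bev_raster")
}

raster_x_centres <- function(r) r$xmin + (seq_len(nrow(r$values)) - 0.5) * r$pixel
raster_z_centres <- function(r) r$zmin + (seq_len(ncol(r$values)) - 0.5) * r$pixel

#' @export
print.bev_raster <- function(x, ...) {
  cat(sprintf("<bev_raster> %d x %d px of %.3g mm, %d set, X [%.4g, %.4g], Z [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pixel, sum(x$values),
              x$xmin, x$xmin + nrow(x$values) * x$pixel,
              x$zmin, x$zmin + ncol(x$values) * x$pixel))
  invisible(x)
}

# raster covering an aperture's jaw field plus a pad (default 10 mm)
raster_for_aperture <- function(aperture, pixel = 1.0, pad = 10) {
  j <- aperture$jaw
  bev_raster(c(j[1] - pad, j[2] + pad), c(j[3] - pad, j[4] + pad), pixel)
}

#' Identify hotspot voxels
#'
#' Voxels of a normalized dose grid receiving strictly more than the
#' threshold dose. The threshold is exclusive, so a plan driven exactly to
#' the threshold has no hotspot voxels.
#'
#' @param dose A [dose_grid()] normalized to 100 at the isocenter.
#' @param threshold Hotspot dose threshold in % of prescription
#'   (default 105).
#' @return A [structure_mask()] labelled `"HOTSPOT"`.
#' @export
find_hotspots <- function(dose, threshold = 105) {
  stopifnot(inherits(dose, "dose_grid"))
  structure_mask(dose$values > threshold, dose$origin, dose$spacing, "HOTSPOT")
}

#' Project a 3D structure mask into a BEV raster
#'
#' Every TRUE voxel's 8 corners are projected through the beam geometry onto
#' the isocenter plane and the filled convex hull of the projected corners
#' is rasterized; the result is the union over voxels. Projecting corners
#' rather than centres is conservative: the later MLC block fully shadows
#' the 3D region.
#'
#' @param mask A [structure_mask()] in the DCS frame.
#' @param geom A [beam_geometry()].
#' @param raster A [bev_raster()] defining extent and pixel size.
#' @return The raster with projected pixels set.
#' @export
project_mask_to_bev <- function(mask, geom, raster) {
  stopifnot(inherits(mask, "structure_mask"), inherits(raster, "bev_raster"))
  idx <- which(mask$values, arr.ind = TRUE)
  out <- raster
  if (nrow(idx) == 0) return(out)
  m <- cpp_project_mask_bev(idx - 1L, mask$origin, mask$spacing,
                            bcs_axes(geom), geom$isocenter, geom$sad,
                            raster$xmin, raster$zmin, raster$pixel,
                            nrow(raster$values), ncol(raster$values))
  out$values <- raster$values | m
  out
}
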