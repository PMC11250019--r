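# Regular, axis-aligned voxel lattices in the DICOM patient coordinate
# system (DCS): LPS axes, millimetres, isotropic spacing.  `origin` is the
# centre of the voxel with array index (1,1,1); voxel extents are half-open.

new_volume_grid <- function(values, origin, spacing, class) {
  stopifnot(length(dim(values)) == 3L, length(origin) == 3L,
            is.numeric(spacing), length(spacing) == 1L, spacing > 0)
  structure(
    list(values = values, origin = as.numeric(origin), spacing = as.numeric(spacing)),
    class = c(class, "volume_grid")
  )
}

#' Relative electron-density grid
#'
#' A 3D array of relative electron density (water = 1.0, air = 0.0) on a
#' regular lattice in the DICOM patient frame. Stands in for the planning CT.
#'
#' @param values 3D numeric array, densities >= 0.
#' @param origin Centre of voxel (1,1,1) in DCS millimetres (length 3).
#' @param spacing Isotropic voxel spacing in millimetres.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(values, origin, spacing) {
  if (any(values < 0)) stop("densities must be non-negative")
  new_volume_grid(values, origin, spacing, "density_grid")
}

#' Dose grid
#'
#' A 3D scalar dose field in percent of the prescription dose, on the same
#' lattice convention as [density_grid()].
#'
#' @inheritParams density_grid
#' @param values 3D numeric array of dose in % of prescription.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, spacing) {
  new_volume_grid(values, origin, spacing, "dose_grid")
}

#' Structure mask
#'
#' A 3D logical array marking the voxels of a contoured structure (e.g. the
#' PTV or the external BODY contour) on the lattice of a companion grid.
#'
#' @inheritParams density_grid
#' @param values 3D logical array.
#' @param label Structure name, e.g. `"PTV"`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(values, origin, spacing, label = "STRUCT") {
  stopifnot(is.logical(values))
  g <- new_volume_grid(values, origin, spacing, "structure_mask")
  g$label <- label
  g
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.3g mm, origin (%.4g, %.4g, %.4g) mm\n",
              class(x)[1], d[1], d[2], d[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  if (inherits(x, "structure_mask"))
    cat(sprintf("  label %s, %d voxels set\n", x$label, sum(x$values)))
  invisible(x)
}

# voxel-centre coordinate vectors along each axis
grid_axes <- function(g) {
  d <- dim(g$values)
  list(x = g$origin[1] + (seq_len(d[1]) - 1) * g$spacing,
       y = g$origin[2] + (seq_len(d[2]) - 1) * g$spacing,
       z = g$origin[3] + (seq_len(d[3]) - 1) * g$spacing)
}

same_lattice <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    abs(a$spacing - b$spacing) < tol
}

# index (1-based) of the voxel whose centre is nearest `point` (DCS mm)
nearest_voxel <- function(g, point) {
  d <- dim(g$values)
  i <- round((point - g$origin) / g$spacing) + 1
  i <- pmin(pmax(i, 1), d)
  as.integer(i)
}

# n x 3 matrix of DCS centres of all TRUE voxels
voxel_centres <- function(mask) {
  idx <- which(mask$values, arr.ind = TRUE)
  sweep((idx - 1) * mask$spacing, 2, mask$origin, "+")
}

shift_array <- function(a, off) {
  # integer-voxel shift with FALSE fill
  d <- dim(a)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) { dst[[ax]] <- seq_len(d[ax] - o) + o; src[[ax]] <- seq_len(d[ax] - o) }
    else        { dst[[ax]] <- seq_len(d[ax] + o);     src[[ax]] <- seq_len(d[ax] + o) - o }
    if (length(dst[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Erode a structure mask by a metric radius
#'
#' Morphological erosion with a spherical structuring element of the given
#' radius in millimetres; voxels outside the array count as background.
#'
#' @param mask A [structure_mask()].
#' @param radius Erosion radius in millimetres.
#' @return The eroded `structure_mask`.
#' @export
mask_erode <- function(mask, radius) {
  stopifnot(inherits(mask, "structure_mask"), radius >= 0)
  if (radius == 0) return(mask)
  r <- floor(radius / mask$spacing + 1e-9)
  offs <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  offs <- offs[sqrt(rowSums(offs^2)) * mask$spacing <= radius + 1e-9, , drop = FALSE]
  acc <- mask$values
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    if (all(o == 0)) next
    acc <- acc & shift_array(mask$values, -o)
    # eroded(p) requires mask at p + o for every offset o in the ball
  }
  structure_mask(acc, mask$origin, mask$spacing, mask$label)
}
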