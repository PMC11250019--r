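# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: rotations are built from the Rodrigues formula,
# DVH quantities from literal scans over the dose samples.

# rotation matrix about an arbitrary unit axis (Rodrigues)
rot_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# BCS axes (columns, in DCS) built independently of bcs_axes():
# start from the zero-angle triad, rotate the frame about the fixed DCS z
# axis by the gantry angle, then about the frame's own (rotated) Y' axis by
# the collimator angle, both as world rotations.
oracle_bcs_axes <- function(gantry, collimator) {
  e0 <- cbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1))
  m <- rot_about_axis(c(0, 0, 1), gantry) %*% e0
  rot_about_axis(m[, 2], collimator) %*% m
}

# largest dose covering at least fraction v, by scanning candidate doses
oracle_dose_at_volume <- function(doses, v) {
  best <- -Inf
  for (d in sort(unique(doses)))
    if (mean(doses >= d) >= v) best <- max(best, d)
  best
}

oracle_volume_at_dose <- function(doses, d) 100 * sum(doses >= d) / length(doses)

# random hotspot raster: a few filled rectangles inside the jaw rectangle
random_hot_raster <- function(raster, jaw, n_blobs = 3) {
  xc <- raster$xmin + (seq_len(nrow(raster$values)) - 0.5) * raster$pixel
  zc <- raster$zmin + (seq_len(ncol(raster$values)) - 0.5) * raster$pixel
  ok_x <- which(xc > jaw[1] & xc < jaw[2])
  ok_z <- which(zc > jaw[3] & zc < jaw[4])
  for (b in seq_len(n_blobs)) {
    i0 <- sample(ok_x, 1); j0 <- sample(ok_z, 1)
    w <- sample(1:8, 1); h <- sample(1:8, 1)
    ii <- intersect(i0:(i0 + w), ok_x)
    jj <- intersect(j0:(j0 + h), ok_z)
    raster$values[ii, jj] <- TRUE
  }
  raster
}

# small water-slab fixture: nx voxels along x, single voxel in y/z
slab_density <- function(nx = 11, spacing = 2.5) {
  density_grid(array(1, c(nx, 1, 1)),
               origin = c(-(nx - 1) / 2 * spacing, 0, 0), spacing = spacing)
}

simple_aperture <- function(jaw = c(-20, 20, -20, 20)) {
  fifwbi:::open_aperture(mlc_bank(c(-20, 0, 20)), jaw)
}

# coarse (5 mm) phantom shared by the unit tests; built once per run
coarse <- local({
  ph <- make_head_phantom(spacing = 5)
  ph$plan <- make_original_plan(ph$body, ph$ptv)
  ph
})
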