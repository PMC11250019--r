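# Multileaf collimator bank, apertures, and the per-row blocking rule.
#
# Leaf pairs are stacked along Z_BEV; each pair has a left (X1) and right
# (X2) leaf tip position at the isocenter plane. The open strip of pair k is
# x1[k] < X_BEV < x2[k] within the jaw rectangle; everything else in the
# field is under a leaf (or jaw).

#' MLC bank layout
#'
#' Leaf-pair boundaries along Z_BEV. The default is a Millennium-style HD
#' bank: a central block of 14 leaf pairs of 2.5 mm width flanked on each
#' side by 16 pairs of 5 mm width (46 pairs, 195 mm total), centred on
#' Z_BEV = 0.
#'
#' @param boundaries Strictly increasing vector of pair boundaries (mm);
#'   `length(boundaries) - 1` pairs.
#' @return An object of class `mlc_bank`.
#' @export
mlc_bank <- function(boundaries) {
  stopifnot(is.numeric(boundaries), length(boundaries) >= 2,
            all(diff(boundaries) > 0))
  structure(list(boundaries = as.numeric(boundaries),
                 n_pairs = length(boundaries) - 1L),
            class = "mlc_bank")
}

#' @rdname mlc_bank
#' @export
default_mlc_bank <- function() {
  b <- c(seq(-97.5, -22.5, by = 5),    # 16 x 5 mm pairs
         seq(-17.5, 17.5, by = 2.5),   # 14 x 2.5 mm pairs
         seq(22.5, 97.5, by = 5))      # 16 x 5 mm pairs
  mlc_bank(b)
}

#' MLC aperture
#'
#' Per-pair left/right leaf tips plus the rectangular jaw field, all in mm
#' at the isocenter plane of the beam's BEV frame.
#'
#' @param bank An [mlc_bank()].
#' @param x1,x2 Left/right leaf tip positions, one per pair; `x1 <= x2`.
#' @param jaw Jaw rectangle `c(X1, X2, Z1, Z2)` with `X1 < X2`, `Z1 < Z2`.
#' @return An object of class `mlc_aperture`.
#' @export
mlc_aperture <- function(bank, x1, x2, jaw) {
  stopifnot(inherits(bank, "mlc_bank"),
            length(x1) == bank$n_pairs, length(x2) == bank$n_pairs,
            all(x1 <= x2 + 1e-9), length(jaw) == 4,
            jaw[1] < jaw[2], jaw[3] < jaw[4])
  structure(list(bank = bank, x1 = as.numeric(x1), x2 = as.numeric(x2),
                 jaw = as.numeric(jaw)),
            class = "mlc_aperture")
}

# rectangular field: all pairs open to the jaw X range
open_aperture <- function(bank, jaw) {
  mlc_aperture(bank, rep(jaw[1], bank$n_pairs), rep(jaw[2], bank$n_pairs), jaw)
}

same_bank <- function(a, b, tol = 1e-9) {
  a$bank$n_pairs == b$bank$n_pairs &&
    all(abs(a$bank$boundaries - b$bank$boundaries) < tol)
}

# leaf pair index containing each z (NA outside the bank)
pair_of_z <- function(bank, z) {
  k <- findInterval(z, bank$boundaries, rightmost.closed = FALSE)
  k[k < 1 | k > bank$n_pairs] <- NA_integer_
  k
}

#' Is a BEV point in the open part of an aperture?
#'
#' A point is open when it lies strictly inside the jaw rectangle and
#' strictly between the leaf tips of the pair whose Z band contains it;
#' points outside the leaf bank are covered.
#'
#' @param aperture An [mlc_aperture()].
#' @param x,z BEV coordinates (mm), vectorized.
#' @return Logical vector.
#' @export
aperture_is_open <- function(aperture, x, z) {
  k <- pair_of_z(aperture$bank, z)
  open <- !is.na(k) &
    x > aperture$jaw[1] & x < aperture$jaw[2] &
    z > aperture$jaw[3] & z < aperture$jaw[4]
  ki <- k[open]
  open[open] <- x[open] > aperture$x1[ki] & x[open] < aperture$x2[ki]
  open
}

quant_up   <- function(v, q = 0.1) ceiling(v / q - 1e-9) * q
quant_down <- function(v, q = 0.1) floor(v / q + 1e-9) * q

#' Fit a sub-beam aperture that blocks a projected hotspot mask
#'
#' Shapes the MLC of a sub-beam so that every hotspot pixel of the BEV
#' raster is covered by a leaf, using the per-row centre-line rule:
#' for each leaf pair, looking at the hotspot pixels in that pair's Z band,
#' (i) no hotspot: the tips stay where the duplicated main beam had them;
#' (ii) hotspot entirely on one side of the vertical centre line
#' (X_BEV = 0): the leaf on that side advances to the hotspot edge nearest
#' the centre line; (iii) a hotspot run crosses the centre line: the
#' distances d1 (left) and d2 (right) from the centre line to the outer
#' hotspot edges are compared and the leaf on the side with the larger
#' distance travels across the centre line to cover the row's full hotspot
#' extent. Two disjoint runs on opposite sides are each covered by their own
#' leaf. Tips are quantized to 0.1 mm, always in the covering direction;
#' jaws are never moved and leaves never retract behind the main-beam field.
#'
#' @param hotspots A [bev_raster()] with the projected hotspot pixels.
#' @param open_field The duplicated main-beam [mlc_aperture()].
#' @param tie Side chosen when d1 == d2 in rule (iii): `"left"` (default)
#'   or `"right"`.
#' @return The fitted blocking `mlc_aperture`.
#' @export
fit_blocking_aperture <- function(hotspots, open_field, tie = c("left", "right")) {
  tie <- match.arg(tie)
  stopifnot(inherits(hotspots, "bev_raster"), inherits(open_field, "mlc_aperture"))
  bank <- open_field$bank
  px <- hotspots$pixel
  xc <- raster_x_centres(hotspots)
  zc <- raster_z_centres(hotspots)
  x1 <- open_field$x1
  x2 <- open_field$x2
  jaw <- open_field$jaw

  # pixels already outside the jaws are blocked by the jaws themselves
  in_jaw_x <- xc > jaw[1] & xc < jaw[2]
  in_jaw_z <- zc > jaw[3] & zc < jaw[4]
  zpair <- pair_of_z(bank, zc)

  for (k in seq_len(bank$n_pairs)) {
    rows <- which(!is.na(zpair) & zpair == k & in_jaw_z)
    if (length(rows) == 0) next
    hot_ix <- which(hotspots$values[, rows, drop = FALSE], arr.ind = TRUE)[, 1]
    hot_ix <- sort(unique(hot_ix[in_jaw_x[hot_ix]]))
    if (length(hot_ix) == 0) next

    # connected runs of hot pixels along X, with their outer pixel extents
    brk <- c(0, which(diff(hot_ix) > 1), length(hot_ix))
    runs <- lapply(seq_len(length(brk) - 1), function(j) {
      ix <- hot_ix[(brk[j] + 1):brk[j + 1]]
      c(lo = xc[ix[1]] - px / 2, hi = xc[ix[length(ix)]] + px / 2)
    })
    lo_all <- min(vapply(runs, `[[`, numeric(1), "lo"))
    hi_all <- max(vapply(runs, `[[`, numeric(1), "hi"))
    crossing <- any(vapply(runs, function(r) r["lo"] < 0 && r["hi"] > 0, logical(1)))

    if (crossing) {
      d1 <- abs(lo_all)   # centre line to outer left edge
      d2 <- hi_all        # centre line to outer right edge
      use_right <- d2 > d1 || (d2 == d1 && tie == "right")
      if (use_right) x2[k] <- min(x2[k], quant_down(lo_all))
      else           x1[k] <- max(x1[k], quant_up(hi_all))
    } else {
      left_hi  <- vapply(runs, function(r) if (r["hi"] <= 0) r[["hi"]] else NA_real_, numeric(1))
      right_lo <- vapply(runs, function(r) if (r["lo"] >= 0) r[["lo"]] else NA_real_, numeric(1))
      if (any(!is.na(left_hi)))  x1[k] <- max(x1[k], quant_up(max(left_hi, na.rm = TRUE)))
      if (any(!is.na(right_lo))) x2[k] <- min(x2[k], quant_down(min(right_lo, na.rm = TRUE)))
    }
    if (x1[k] > x2[k]) { m <- (x1[k] + x2[k]) / 2; x1[k] <- x2[k] <- quant_down(m) }
  }
  mlc_aperture(bank, x1, x2, jaw)
}

#' Region blocked by a sub-beam relative to its main beam
#'
#' Rasterizes the pixels that are open in the main-beam aperture but covered
#' by a leaf in the sub-beam aperture.
#'
#' @param aperture_sub,aperture_main [mlc_aperture()]s sharing bank and jaws.
#' @param raster A [bev_raster()] defining the pixel lattice.
#' @return A `bev_raster` marking the blocked pixels.
#' @export
blocked_region <- function(aperture_sub, aperture_main, raster) {
  if (!same_bank(aperture_sub, aperture_main)) stop("MLC bank mismatch")
  xc <- raster_x_centres(raster)
  zc <- raster_z_centres(raster)
  g <- expand.grid(x = xc, z = zc)
  open_main <- aperture_is_open(aperture_main, g$x, g$z)
  open_sub <- aperture_is_open(aperture_sub, g$x, g$z)
  out <- raster
  out$values <- matrix(open_main & !open_sub, nrow = length(xc))
  out
}
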