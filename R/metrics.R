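# Cumulative DVH and dose indices. The DVH is voxel-exact (sorted samples,
# no binning); D_V uses the lower-quantile convention: the largest dose d
# such that at least the fraction V of the structure receives >= d.

#' Compute the cumulative DVH of a structure
#'
#' @param dose A [dose_grid()].
#' @param structure A non-empty [structure_mask()] on the same lattice.
#' @return An object of class `dvh`: the sorted (decreasing) dose samples of
#'   all structure voxels.
#' @export
compute_dvh <- function(dose, structure) {
  stopifnot(inherits(dose, "dose_grid"), inherits(structure, "structure_mask"))
  if (!same_lattice(dose, structure)) stop("dose and structure lattices differ")
  d <- dose$values[structure$values]
  if (length(d) == 0) stop("empty structure")
  structure(list(doses = sort(d, decreasing = TRUE), n = length(d),
                 label = structure$label),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s, %d voxels, dose range [%.2f, %.2f] %%Rx\n",
              x$label, x$n, min(x$doses), max(x$doses)))
  invisible(x)
}

#' Dose covering a fractional volume (D_V)
#'
#' Largest dose d such that at least the fraction `v` of the structure
#' volume receives >= d.
#'
#' @param dvh A [compute_dvh()] result.
#' @param v Volume fraction in (0, 1), e.g. 0.95 for D95.
#' @return Dose in % of prescription.
#' @export
dose_at_volume <- function(dvh, v) {
  stopifnot(inherits(dvh, "dvh"), v > 0, v < 1)
  dvh$doses[ceiling(v * dvh$n)]
}

#' Volume receiving at least a dose (V_D)
#'
#' @param dvh A [compute_dvh()] result.
#' @param d Dose in % of prescription, e.g. 105 for V105.
#' @return Volume in % of the structure volume.
#' @export
volume_at_dose <- function(dvh, d) {
  stopifnot(inherits(dvh, "dvh"), d >= 0)
  100 * mean(dvh$doses >= d)
}

#' Homogeneity index
#'
#' `HI = (D2% - D98%) / D50%`, reported in percent; 0 for a perfectly
#' uniform dose.
#'
#' @param dvh A [compute_dvh()] result.
#' @return HI in %.
#' @export
homogeneity_index <- function(dvh) {
  d50 <- dose_at_volume(dvh, 0.50)
  if (d50 == 0) stop("D50 is zero; HI undefined")
  100 * (dose_at_volume(dvh, 0.02) - dose_at_volume(dvh, 0.98)) / d50
}

#' Standard dose indices of a structure
#'
#' D95, D2, D98, D50, Dmax (% of prescription), V95 and V105 (% of the
#' structure volume), and the homogeneity index.
#'
#' @inheritParams compute_dvh
#' @return A one-row data frame.
#' @export
dose_indices <- function(dose, structure) {
  dvh <- compute_dvh(dose, structure)
  data.frame(D95 = dose_at_volume(dvh, 0.95),
             D2 = dose_at_volume(dvh, 0.02),
             D98 = dose_at_volume(dvh, 0.98),
             D50 = dose_at_volume(dvh, 0.50),
             Dmax = max(dvh$doses),
             V95 = volume_at_dose(dvh, 95),
             V105 = volume_at_dose(dvh, 105),
             HI = homogeneity_index(dvh))
}

#' Write a DVH as a two-column CSV
#'
#' Columns `dose_pct` (sorted increasing) and `volume_fraction` (fraction of
#' the structure receiving at least that dose).
#'
#' @param dvh A [compute_dvh()] result.
#' @param path Output file path.
#' @export
write_dvh_csv <- function(dvh, path) {
  d <- sort(unique(dvh$doses))
  vol <- vapply(d, function(t) mean(dvh$doses >= t), numeric(1))
  utils::write.csv(data.frame(dose_pct = d, volume_fraction = vol),
                   path, row.names = FALSE)
  invisible(path)
}
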