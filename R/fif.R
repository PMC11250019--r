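# The semiautomatic field-in-field planner.
#
# Step 1: hotspots of the original plan (dose > D_th) are projected into
# each main beam's BEV and blocked by a duplicated sub-beam whose MLC is
# fitted to the projection; weights are reassigned in closed form from the
# original-plan maximum so that unblocked doses are unchanged and blocked
# doses drop by the fraction f = (D_max - D_th) / D_max.
#
# Step 2 (when Step 1 costs more than the D95 criterion): the same
# construction is applied twice with half-sized reductions - first at the
# intermediate threshold D_ith = (D_max + D_th) / 2 against the original
# dose, then at D_th against the resulting two-sub-beam dose - yielding a
# four-sub-beam plan that trades less target coverage for the same hotspot
# control.

#' Planner configuration
#'
#' @param d_th Hotspot dose threshold in % of prescription (default 105,
#'   chosen so the plan maximum stays below the ICRU 107% ceiling).
#' @param criterion D95-reduction criterion in percentage points (default
#'   1.0); a Step-1 plan losing more than this is escalated to four
#'   sub-beams.
#' @param engine An [engine_config()].
#' @param bev_pixel BEV raster pixel size in mm (default 1.0).
#' @param bev_pad BEV raster pad beyond the jaws in mm (default 10).
#' @param tie Tie-break side for the MLC centre-line rule.
#' @return An object of class `fif_config`.
#' @export
fif_config <- function(d_th = 105, criterion = 1.0, engine = engine_config(),
                       bev_pixel = 1.0, bev_pad = 10, tie = "left") {
  stopifnot(d_th > 0, criterion >= 0, inherits(engine, "engine_config"))
  structure(list(d_th = d_th, criterion = criterion, engine = engine,
                 bev_pixel = bev_pixel, bev_pad = bev_pad, tie = tie),
            class = "fif_config")
}

#' Step-1 closed-form weight assignment
#'
#' For a main beam of weight `w_main`, the fractional reduction needed to
#' pull the plan maximum down to the threshold is
#' `f = (d_max - d_th) / d_max`; the main-beam weight is reduced to
#' `w_main * (1 - f) = w_main * d_th / d_max` and the sub-beam receives the
#' complement, so that open-in-both regions keep their dose exactly while
#' regions blocked in the sub-beam drop by `f`.
#'
#' @param d_max Maximum dose of the original plan, % of prescription.
#' @param d_th Hotspot threshold, % of prescription.
#' @param w_main Original main-beam weight.
#' @return A list with `f`, `w_main_fif`, `w_sub_fif`, and `fif_needed`
#'   (FALSE when `d_max <= d_th`, in which case the weights are unchanged).
#' @export
step1_weights <- function(d_max, d_th, w_main = 1) {
  stopifnot(d_th > 0, d_max > 0, w_main >= 0)
  if (d_max <= d_th)
    return(list(f = 0, w_main_fif = w_main, w_sub_fif = 0, fif_needed = FALSE))
  f <- (d_max - d_th) / d_max
  w_main_fif <- w_main * d_th / d_max
  list(f = f, w_main_fif = w_main_fif, w_sub_fif = w_main - w_main_fif,
       fif_needed = TRUE)
}

# duplicate each main beam, fit its MLC to block `hot3d`, weight the pair
add_blocking_subs <- function(plan, hot3d, d_max, d_ref, cfg, role, suffix) {
  beams <- list()
  for (b in plan$beams) {
    if (b$role != "main") { beams <- c(beams, list(b)); next }
    w <- step1_weights(d_max, d_ref, b$weight)
    geom <- beam_geom(b)
    raster <- raster_for_aperture(b$aperture, cfg$bev_pixel, cfg$bev_pad)
    bev <- project_mask_to_bev(hot3d, geom, raster)
    sub_ap <- fit_blocking_aperture(bev, b$aperture, tie = cfg$tie)
    main2 <- b
    main2$weight <- w$w_main_fif
    sub <- fif_beam(id = paste0(b$id, "-", suffix), gantry = b$gantry,
                    collimator = b$collimator, isocenter = b$isocenter,
                    aperture = sub_ap, weight = w$w_sub_fif, role = role,
                    sad = b$sad, energy_mv = b$energy_mv)
    beams <- c(beams, list(main2, sub))
  }
  fif_plan(beams, plan$prescription_gy, plan$fractions)
}

#' Build the Step-1 two-sub-beam FIF plan
#'
#' Duplicates each main beam as a sub-beam whose MLC blocks the BEV
#' projection of the original plan's hotspots, applies the Step-1 weights,
#' and recomputes the normalized dose.
#'
#' @param original A two-main-beam [fif_plan()].
#' @param dose_orig The normalized original-plan [dose_grid()].
#' @param density The [density_grid()].
#' @param cfg A [fif_config()].
#' @return A list with `plan`, `dose`, `f`, `d_max`, and `fif_needed`
#'   (FALSE when there is no hotspot, in which case the original plan and
#'   dose are returned unchanged).
#' @export
build_step1_plan <- function(original, dose_orig, density, cfg = fif_config()) {
  d_max <- max(dose_orig$values)
  if (d_max <= cfg$d_th)
    return(list(plan = original, dose = dose_orig, f = 0, d_max = d_max,
                fif_needed = FALSE))
  hot3d <- find_hotspots(dose_orig, cfg$d_th)
  plan <- add_blocking_subs(original, hot3d, d_max, cfg$d_th, cfg, "sub1", "sub1")
  dose <- compute_plan_dose(density, plan, cfg$engine)
  list(plan = plan, dose = dose, f = (d_max - cfg$d_th) / d_max, d_max = d_max,
       fif_needed = TRUE)
}

#' D95 reduction caused by a FIF plan
#'
#' @param dose_orig,dose_fif Normalized [dose_grid()]s on the same lattice.
#' @param ptv The PTV [structure_mask()].
#' @return `D95(original) - D95(FIF)` in percentage points of prescription.
#' @export
evaluate_step1 <- function(dose_orig, dose_fif, ptv) {
  dose_at_volume(compute_dvh(dose_orig, ptv), 0.95) -
    dose_at_volume(compute_dvh(dose_fif, ptv), 0.95)
}

#' Build the Step-2 four-sub-beam FIF plan
#'
#' First sub-beam pair: blocks the high-hotspot region of the original dose
#' above the intermediate threshold `D_ith = (D_max + D_th) / 2`, weighted
#' as in Step 1 with `D_th` replaced by `D_ith`. The intermediate dose is
#' recomputed and its maximum `w_ithmax` taken. Second pair: blocks the
#' low-hotspot region above `D_th` in the intermediate dose; main weights
#' shrink by the factor `D_th / w_ithmax` and the second sub-beams receive
#' the complement.
#'
#' @inheritParams build_step1_plan
#' @return A list with `plan`, `dose`, `d_max`, `d_ith`, `w_ithmax`, and
#'   `second_pair` (FALSE when the intermediate plan already has no dose
#'   above `D_th`, in which case the second pair is skipped).
#' @export
build_step2_plan <- function(original, dose_orig, density, cfg = fif_config()) {
  d_max <- max(dose_orig$values)
  if (d_max <= cfg$d_th)
    return(list(plan = original, dose = dose_orig, d_max = d_max,
                d_ith = NA_real_, w_ithmax = NA_real_, second_pair = FALSE))
  d_ith <- (d_max + cfg$d_th) / 2

  hot_high <- find_hotspots(dose_orig, d_ith)
  plan2sf <- add_blocking_subs(original, hot_high, d_max, d_ith, cfg, "sub1", "sub1")
  dose2sf <- compute_plan_dose(density, plan2sf, cfg$engine)
  w_ithmax <- max(dose2sf$values)

  if (w_ithmax <= cfg$d_th)
    return(list(plan = plan2sf, dose = dose2sf, d_max = d_max, d_ith = d_ith,
                w_ithmax = w_ithmax, second_pair = FALSE))

  hot_low <- find_hotspots(dose2sf, cfg$d_th)
  plan4sf <- add_blocking_subs(plan2sf, hot_low, w_ithmax, cfg$d_th, cfg,
                               "sub2", "sub2")
  dose4sf <- compute_plan_dose(density, plan4sf, cfg$engine)
  list(plan = plan4sf, dose = dose4sf, d_max = d_max, d_ith = d_ith,
       w_ithmax = w_ithmax, second_pair = TRUE)
}

#' Run the full semiautomatic FIF workflow
#'
#' Computes the original-plan dose, builds the Step-1 two-sub-beam plan,
#' and, when the D95 reduction exceeds the criterion, discards it and
#' builds the Step-2 four-sub-beam plan. Returns the selected plan, its
#' dose, and a report with the dose indices and the weight table.
#'
#' @param original A [fif_plan()] without sub-beams.
#' @param density The [density_grid()].
#' @param ptv The PTV [structure_mask()].
#' @param cfg A [fif_config()].
#' @return A list with `plan`, `dose`, and `report` (class `fif_report`).
#' @export
autofif <- function(original, density, ptv, cfg = fif_config()) {
  dose_orig <- compute_plan_dose(density, original, cfg$engine)
  idx_orig <- dose_indices(dose_orig, ptv)
  d_max <- max(dose_orig$values)

  if (d_max <= cfg$d_th) {
    report <- structure(list(scheme = "none", d_max = d_max, d_th = cfg$d_th,
                             criterion = cfg$criterion, f = 0,
                             delta_d95_step1 = 0, delta_d95_final = 0,
                             indices = list(original = idx_orig),
                             weights = plan_weights(original)),
                        class = "fif_report")
    return(list(plan = original, dose = dose_orig, report = report))
  }

  s1 <- build_step1_plan(original, dose_orig, density, cfg)
  dd95_1 <- evaluate_step1(dose_orig, s1$dose, ptv)
  indices <- list(original = idx_orig, fif = dose_indices(s1$dose, ptv))

  if (dd95_1 > cfg$criterion) {
    s2 <- build_step2_plan(original, dose_orig, density, cfg)
    dd95_2 <- evaluate_step1(dose_orig, s2$dose, ptv)
    indices$fif4sf <- dose_indices(s2$dose, ptv)
    report <- structure(list(scheme = "FIF-4SF", d_max = d_max, d_th = cfg$d_th,
                             d_ith = s2$d_ith, w_ithmax = s2$w_ithmax,
                             criterion = cfg$criterion, f = s1$f,
                             delta_d95_step1 = dd95_1, delta_d95_final = dd95_2,
                             indices = indices, weights = plan_weights(s2$plan)),
                        class = "fif_report")
    return(list(plan = s2$plan, dose = s2$dose, report = report))
  }

  report <- structure(list(scheme = "FIF", d_max = d_max, d_th = cfg$d_th,
                           criterion = cfg$criterion, f = s1$f,
                           delta_d95_step1 = dd95_1, delta_d95_final = dd95_1,
                           indices = indices, weights = plan_weights(s1$plan)),
                      class = "fif_report")
  list(plan = s1$plan, dose = s1$dose, report = report)
}

#' @export
print.fif_report <- function(x, ...) {
  cat(sprintf("<fif_report> scheme: %s\n", x$scheme))
  cat(sprintf("  D_max (original) %.2f %%Rx, D_th %.1f %%Rx, f %.4f\n",
              x$d_max, x$d_th, x$f))
  if (!is.null(x$d_ith) && !is.na(x$d_ith))
    cat(sprintf("  D_ith %.2f %%Rx, w_ithmax %.2f %%Rx\n", x$d_ith, x$w_ithmax))
  cat(sprintf("  Delta D95: step 1 %.3f pp, selected plan %.3f pp (criterion %.1f)\n",
              x$delta_d95_step1, x$delta_d95_final, x$criterion))
  cat("  PTV indices:\n")
  tab <- do.call(rbind, x$indices)
  print(round(tab, 3))
  cat("  beam weights:\n")
  print(x$weights, row.names = FALSE)
  invisible(x)
}
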