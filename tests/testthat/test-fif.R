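test_that("step1_weights: closed form, conservation, degenerate cases", {
  # printed-average scenario: D_max 107.3, D_th 105
  w <- step1_weights(107.3, 105, 1)
  expect_equal(round(w$w_main_fif, 3), 0.979)
  expect_equal(round(w$w_sub_fif, 3), 0.021)
  expect_equal(w$f, (107.3 - 105) / 107.3)
  expect_equal(w$w_main_fif + w$w_sub_fif, 1)   # exact conservation
  # D_max == D_th: nothing to do
  w0 <- step1_weights(105, 105, 1)
  expect_false(w0$fif_needed)
  expect_equal(w0$w_sub_fif, 0)
  expect_equal(w0$w_main_fif, 1)
  # D_max below threshold: no-op signal
  expect_false(step1_weights(103, 105, 1)$fif_needed)
  # f = 1/22 example and per-beam scaling
  w2 <- step1_weights(110, 105, 0.8)
  expect_equal(w2$f, 1 / 22)
  expect_equal(w2$w_main_fif, 0.8 * 105 / 110)
  expect_equal(w2$w_main_fif + w2$w_sub_fif, 0.8)
})

test_that("blocked-point dose drops by exactly f under the linear engine", {
  # two-voxel toy: with T_mlc = 0 the blocked voxel's pre-normalization dose
  # scales by (1 - f) while the open voxel's is untouched
  mu <- 0.002
  cfg <- engine_config(mu_eff = mu, t_mlc = 0, inv_square = FALSE)
  slab <- density_grid(array(1, c(3, 1, 2)), c(-2.5, 0, -2.5), 2.5)
  bank <- mlc_bank(c(-20, 0, 20))
  jaw <- c(-20, 20, -20, 20)
  open_ap <- fifwbi:::open_aperture(bank, jaw)
  blocked_ap <- mlc_aperture(bank, c(-20, -20), c(-20, 20), jaw)  # lower band shut
  main <- fif_beam("m", 90, isocenter = c(0, 0, 0), aperture = open_ap, weight = 1)
  w <- step1_weights(110, 105, 1)
  main_fif <- main; main_fif$weight <- w$w_main_fif
  sub <- fif_beam("s", 90, isocenter = c(0, 0, 0), aperture = blocked_ap,
                  weight = w$w_sub_fif, role = "sub1")
  d_orig <- compute_beam_dose(slab, main, cfg)$values
  d_fif <- compute_beam_dose(slab, main_fif, cfg)$values +
           compute_beam_dose(slab, sub, cfg)$values
  expect_equal(d_fif[, , 1], (1 - w$f) * d_orig[, , 1], tolerance = 1e-12)
  expect_equal(d_fif[, , 2], d_orig[, , 2], tolerance = 1e-12)
})

test_that("midpoint intermediate threshold", {
  # D_max 107.8, D_th 105 -> D_ith 106.4 (matches the reported high-hotspot level)
  expect_equal((107.8 + 105) / 2, 106.4)
  eps <- 1e-6
  expect_equal((105 + 2 * eps + 105) / 2, 105 + eps)
})

test_that("step-2 weight reconstruction is consistent with the reported 4SF split", {
  # D_max ~ 107.8 -> D_ith = 106.4; first pair from step1_weights at D_ith;
  # clinically reported split 0.973 / 0.013 / 0.014 implies w_ithmax ~ 106.5
  w1 <- step1_weights(107.8, 106.4, 1)
  expect_lt(abs(w1$w_sub_fif - 0.013), 1.5e-3)
  w_ithmax <- 106.5
  w_main_2nd <- w1$w_main_fif * 105 / w_ithmax
  expect_lt(abs(w_main_2nd - 0.973), 1.5e-3)
  expect_lt(abs((w1$w_main_fif - w_main_2nd) - 0.014), 1.5e-3)
})

test_that("evaluate_step1 measures the D95 reduction in percentage points", {
  ph <- coarse
  dose <- compute_plan_dose(ph$density, ph$plan)
  expect_equal(evaluate_step1(dose, dose, ph$ptv), 0)
  shifted <- dose
  shifted$values <- shifted$values - 2
  expect_equal(evaluate_step1(dose, shifted, ph$ptv), 2)
  # sort-based oracle on a random pair
  set.seed(41)
  a <- dose; a$values <- array(stats::runif(length(a$values), 90, 110), dim(a$values))
  b <- dose; b$values <- array(stats::runif(length(b$values), 90, 110), dim(b$values))
  expect_equal(evaluate_step1(a, b, ph$ptv),
               oracle_dose_at_volume(a$values[ph$ptv$values], 0.95) -
               oracle_dose_at_volume(b$values[ph$ptv$values], 0.95))
})

test_that("build_step1_plan duplicates mains as fitted sub-beams", {
  ph <- coarse
  cfg <- fif_config()
  dose <- compute_plan_dose(ph$density, ph$plan, cfg$engine)
  s1 <- build_step1_plan(ph$plan, dose, ph$density, cfg)
  expect_true(s1$fif_needed)
  expect_length(s1$plan$beams, 4)
  roles <- vapply(s1$plan$beams, `[[`, character(1), "role")
  expect_equal(sum(roles == "main"), 2)
  expect_equal(sum(roles == "sub1"), 2)
  # weight conservation per opposing side
  wt <- fifwbi:::plan_weights(s1$plan)
  for (g in c(90, 270))
    expect_equal(sum(wt$weight[wt$gantry == g]), 1)
  # sub apertures block something
  for (b in s1$plan$beams)
    if (b$role == "sub1")
      expect_gt(sum(b$aperture$x1 > b$aperture$jaw[1] + 1e-9) +
                sum(b$aperture$x2 < b$aperture$jaw[2] - 1e-9), 0)
  # hotspots essentially removed in the step-1 dose
  expect_lte(volume_at_dose(compute_dvh(s1$dose, ph$ptv), 105), 0.2)
})

test_that("a hotspot-free plan is passed through untouched", {
  ph <- coarse
  cfg <- fif_config(d_th = 200)
  dose <- compute_plan_dose(ph$density, ph$plan, cfg$engine)
  s1 <- build_step1_plan(ph$plan, dose, ph$density, cfg)
  expect_false(s1$fif_needed)
  expect_identical(s1$plan, ph$plan)
  res <- autofif(ph$plan, ph$density, ph$ptv, cfg)
  expect_equal(res$report$scheme, "none")
  expect_length(res$plan$beams, 2)
})

test_that("autofif selects FIF on the default phantom and escalates when forced", {
  ph <- coarse
  res <- autofif(ph$plan, ph$density, ph$ptv, fif_config())
  expect_equal(res$report$scheme, "FIF")
  expect_length(res$plan$beams, 4)
  expect_true(all(fifwbi:::plan_weights(res$plan)$weight >= 0))
  # criterion 0 forces the four-sub-beam scheme whenever D95 moves at all
  res0 <- autofif(ph$plan, ph$density, ph$ptv, fif_config(criterion = 0))
  if (res0$report$delta_d95_step1 > 0) {
    expect_equal(res0$report$scheme, "FIF-4SF")
    expect_length(res0$plan$beams, 6)
    expect_equal(res0$report$d_ith, (res0$report$d_max + 105) / 2)
  }
})

test_that("scheme selection is a pure function of the D95 change and criterion", {
  ph <- coarse
  res <- autofif(ph$plan, ph$density, ph$ptv, fif_config())
  dd <- res$report$delta_d95_step1
  expect_identical(res$report$scheme, if (dd > 1) "FIF-4SF" else "FIF")
  # repeat run is bit-identical
  res2 <- autofif(ph$plan, ph$density, ph$ptv, fif_config())
  expect_identical(res$dose$values, res2$dose$values)
})
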