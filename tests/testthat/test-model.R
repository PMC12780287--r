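test_that("automatic remote detection finds the viable sector", {
  case <- noisy_phantom(seed = 6, n_slices = 2)
  est <- estimate_remote_auto(case$stack, case$mask, case$contours)
  expect_lt(abs(est$mean - 20) / 20, 0.1)
  # the pooled voxels avoid the infarct wedge
  expect_true(all(case$truth_weights[est$idx] == 0))

  # a uniform stack yields the global mean from whichever sector
  fx <- annulus_fixture(value = 42)
  u <- estimate_remote_auto(fx$stack, fx$mask, fx$contours)
  expect_equal(u$mean, 42)

  # circumferential enhancement contaminates the estimate and warns
  ring <- generate_phantom(phantom_spec(extent_deg = 350, remote_sd = 2,
                                        infarct_sd = 2, n_slices = 2), seed = 1)
  expect_warning(estimate_remote_auto(ring$stack, ring$mask, ring$contours),
                 "contaminated")
})

test_that("coil correction is the identity on bias-free stacks", {
  case <- solid_phantom(n_slices = 2)
  co <- coil_correction(case$stack, case$mask)
  rel <- abs(co$voxels[case$mask$mask] / case$stack$voxels[case$mask$mask] - 1)
  expect_lt(max(rel), 0.005)
  expect_error(coil_correction(case$stack, lgequant:::new_lge_mask(
    array(FALSE, dim(case$stack$voxels)), case$stack)), "empty")
})

test_that("coil correction removes a 30% linear ramp from the remote wall", {
  flat <- solid_phantom(n_slices = 2)
  ramp <- generate_phantom(phantom_spec(coil_amplitude = 0.3, n_slices = 2),
                           seed = 1)
  co <- coil_correction(ramp$stack, ramp$mask)
  # pure remote voxels: remote ROI restricted to the midmural band
  band <- midmural_band(ramp$mask, ramp$contours, ramp$stack)
  rem <- lgequant:::resolve_rois(ramp$rois, "remote", ramp$stack, ramp$mask) & band
  cv <- function(v) stats::sd(v) / mean(v)
  expect_gt(cv(ramp$stack$voxels[rem]) / cv(co$voxels[rem]), 5)
})

test_that("two-Gaussian EM recovers parameters and is monotone in likelihood", {
  # perfectly separated two-point data
  v <- c(rep(10, 30), rep(50, 10))
  fit <- em_two_gaussians(v)
  expect_equal(fit$mean_normal, 10, tolerance = 1e-6)
  expect_equal(fit$mean_infarct, 50, tolerance = 1e-6)
  expect_equal(fit$lambda, 0.25, tolerance = 1e-6)

  # parameter recovery on simulated mixtures (the acceptance run uses the
  # full 20-seed, n = 10000 setting)
  for (seed in 1:5) {
    set.seed(seed)
    v <- c(rnorm(8000, 50, 10), rnorm(2000, 200, 20))
    fit <- em_two_gaussians(v)
    expect_lt(abs(fit$mean_normal - 50) / 50, 0.02)
    expect_lt(abs(fit$mean_infarct - 200) / 200, 0.02)
    expect_lt(abs(fit$sd_normal - 10) / 10, 0.10)
    expect_lt(abs(fit$sd_infarct - 20) / 20, 0.10)
    expect_true(all(diff(fit$loglik) > -1e-8 * abs(fit$loglik[-1])))
    expect_gt(fit$mean_infarct, fit$mean_normal)
  }

  # log-likelihood is non-decreasing on arbitrary inputs too
  set.seed(99)
  for (i in 1:10) {
    v <- rgamma(500, shape = runif(1, 0.5, 5), rate = 0.1)
    fit <- em_two_gaussians(v)
    expect_true(all(diff(fit$loglik) > -1e-8 * abs(fit$loglik[-1])))
  }

  expect_error(em_two_gaussians(rep(3, 100)), "degenerate")
  expect_error(em_two_gaussians(1:5), "at least 10")
})

test_that("EM agrees with an independent mixture fitter", {
  set.seed(12)
  v <- c(rnorm(3000, 50, 10), rnorm(1000, 200, 20))
  fit <- em_two_gaussians(v)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  ref <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$mean_normal, min(ref$parameters$mean), tolerance = 0.02)
  expect_equal(fit$mean_infarct, max(ref$parameters$mean), tolerance = 0.02)
})

test_that("MVO inclusion fills only regions enclosed by infarct or endocardium", {
  fx <- annulus_fixture(value = 10)
  g <- lgequant:::grid_xy(fx$stack)
  ang <- (atan2(g$y - fx$center[2], g$x - fx$center[1]) * 180 / pi) %% 360
  r <- sqrt((g$x - fx$center[1])^2 + (g$y - fx$center[2])^2)
  wedge <- fx$mask$mask[, , 1] & ang < 90
  core <- wedge & ang > 30 & ang < 60 & r < (fx$r_endo + fx$r_epi) / 2
  supp <- array(wedge & !core, dim = dim(fx$stack$voxels))
  filled <- include_mvo(supp, fx$mask, fx$contours, fx$stack)
  expect_true(all(filled[core]))  # ringed by infarct/endo: filled

  # a dark region reaching the epicardial border is not filled
  core_epi <- wedge & ang > 30 & ang < 60 & r > (fx$r_endo + fx$r_epi) / 2
  supp2 <- array(wedge & !core_epi, dim = dim(fx$stack$voxels))
  filled2 <- include_mvo(supp2, fx$mask, fx$contours, fx$stack)
  expect_false(any(filled2[core_epi & !supp2[, , 1]]))
})

test_that("small-component removal is strict below the cutoff", {
  stack <- lge_stack(array(1, c(20, 20, 1)), spacing = 1, thickness = 8)
  supp <- array(FALSE, c(20, 20, 1))
  supp[2, 2:11, 1] <- TRUE   # 10 voxels = 0.084 g at 1.05
  supp[10, 2:13, 1] <- TRUE  # 12 voxels = 0.1008 g
  out <- remove_small_components(supp, stack, min_mass_g = 0.1)
  expect_equal(sum(out), 12)
  # a blob exactly at the cutoff is retained
  out2 <- remove_small_components(supp, stack, min_mass_g = 10 * 0.008 * 1.05)
  expect_equal(sum(out2), 22)
  expect_equal(sum(remove_small_components(array(FALSE, c(20, 20, 1)), stack,
                                           min_mass_g = 0.1)), 0)
})

test_that("FACT feature filters drop small, distant and dim candidates", {
  fx <- annulus_fixture(grid = 64, spacing = 1, r_endo = 12, r_epi = 24,
                        value = 10)
  c0 <- fx$center[1]
  # good: 16 voxels (0.134 g), bright, at the endocardium
  b1 <- paint_blob(fx$stack, fx$mask, c0, c0 + fx$r_endo + 1.2, 4, 100)
  # too small: ~10 voxels (0.084 g), bright, at the endocardium
  b2 <- paint_blob(b1$stack, fx$mask, c0 + fx$r_endo + 1.2, c0, 3, 100)
  # too far: bright and big but ~3 mm interior of the endocardium
  b3 <- paint_blob(b2$stack, fx$mask, c0, c0 - fx$r_endo - 5.0, 4, 100)
  # too dim: big and close but below 50% of the pooled candidate mean
  b4 <- paint_blob(b3$stack, fx$mask, c0 - fx$r_endo - 1.2, c0, 4, 30)
  stack <- b4$stack
  supp <- array(FALSE, dim(stack$voxels))
  supp[c(b1$idx, b2$idx, b3$idx, b4$idx)] <- TRUE
  ed <- endocardial_distance(fx$mask, fx$contours, stack)
  expect_gt(min(ed[b3$idx]), 2)       # construction sanity
  expect_lte(min(ed[b1$idx]), 2)
  kept <- fact_feature_filter(supp, stack, fx$mask, ed)
  expect_setequal(which(kept), b1$idx)
})

test_that("composite methods recover the noise-free wedge", {
  case <- solid_phantom()
  truth <- case$truth_fraction_pct
  fact <- segment_fact(case$stack, case$contours, mask = case$mask)
  expect_lt(abs(fact$fraction_pct - truth), 1.5)
  hei <- segment_heiberg08(case$stack, case$contours, mask = case$mask)
  expect_lt(abs(hei$fraction_pct - truth), 2)
  ewa <- segment_ewa(case$stack, case$contours, mask = case$mask)
  expect_lt(abs(ewa$fraction_pct - truth), 2)

  # weighted fractions cannot exceed their own binary support fraction
  for (seg in list(hei, ewa)) {
    bin <- sum(seg$support) * case$mask$voxel_volume_ml * case$mask$density
    expect_lte(seg$mass_g, bin + 1e-9)
  }
})

test_that("Heiberg-08 refuses PSIR input", {
  ps <- generate_phantom(phantom_spec(convention = "PSIR", n_slices = 2), seed = 1)
  expect_error(segment_heiberg08(ps$stack, ps$contours, mask = ps$mask), "PSIR")
})

test_that("EWA includes the hypointense MVO core", {
  mv <- generate_phantom(phantom_spec(mvo_fraction = 0.5, remote_sd = 3,
                                      infarct_sd = 5), seed = 11)
  core <- mv$truth_weights > 0.99 & mv$stack$voxels < mv$spec$remote_mean
  ewa <- segment_ewa(mv$stack, mv$contours, mask = mv$mask)
  expect_gt(mean(ewa$weights[core]), 0.9)
  fact <- segment_fact(mv$stack, mv$contours, mask = mv$mask)
  expect_gt(mean(fact$weights[core]), 0.9)
  # a method without MVO inclusion misses the core mass
  fw <- segment_fwhm(mv$stack, mv$mask, mv$rois)
  expect_lt(fw$fraction_pct, fact$fraction_pct)
})

test_that("EWA reports no infarct on pure-remote myocardium", {
  nul <- generate_phantom(phantom_spec(extent_deg = 0, remote_sd = 5,
                                       infarct_sd = 8, n_slices = 2), seed = 3)
  expect_warning(z <- segment_ewa(nul$stack, nul$contours, mask = nul$mask),
                 "no infarct evidence")
  expect_equal(z$fraction_pct, 0)
})

test_that("zero- vs remote-anchored FWHM order by their thresholds on PSIR", {
  # with a negative remote mean the zero anchor sits *above* the remote
  # anchor (max/2 > (max + remote)/2), so zero anchoring selects a subset
  ps <- generate_phantom(phantom_spec(convention = "PSIR", remote_sd = 5,
                                      infarct_sd = 8, n_slices = 2), seed = 5)
  fr <- segment_fwhm(ps$stack, ps$mask, ps$rois, anchor = "remote")
  suppressWarnings(
    fz <- segment_fwhm(ps$stack, ps$mask, ps$rois, anchor = "zero",
                       force_psir = TRUE))
  expect_gt(fz$thresholds$threshold, fr$thresholds$threshold)
  expect_true(all(fr$support[fz$support]))
  expect_lte(fz$fraction_pct, fr$fraction_pct)
})
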