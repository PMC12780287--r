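test_that("annulus rasterization matches the analytic area and a PIP oracle", {
  fx <- annulus_fixture(grid = 70, spacing = 1, r_endo = 20, r_epi = 30)
  n <- sum(fx$mask$mask)
  expect_lt(abs(n - pi * (30^2 - 20^2)) / (pi * 500), 0.01)

  # voxel-exact agreement with an independent winding-number oracle
  g <- lgequant:::grid_xy(fx$stack)
  sl <- fx$contours$slices[[1]]
  oracle <- winding_inside(as.vector(g$x), as.vector(g$y), sl$epi) &
    !winding_inside(as.vector(g$x), as.vector(g$y), sl$endo)
  expect_identical(as.vector(fx$mask$mask[, , 1]), oracle)
})

test_that("rasterization agrees with the winding oracle on random star-convex contours", {
  set.seed(42)
  stack <- lge_stack(array(0, c(32, 32, 1)), spacing = 1, thickness = 8)
  g <- lgequant:::grid_xy(stack)
  for (i in 1:100) {
    poly <- random_star_polygon(15.5, 15.5, 14)
    contours <- lge_contours(list(list(epi = poly)), validate = FALSE)
    mask <- rasterize_contours(contours, stack)
    oracle <- winding_inside(as.vector(g$x), as.vector(g$y), poly)
    expect_identical(as.vector(mask$mask[, , 1]), oracle)
  }
})

test_that("degenerate contours and size bookkeeping behave", {
  # zero-width wall: endo == epi
  stack <- lge_stack(array(0, c(32, 32, 1)), spacing = 1, thickness = 8)
  p <- circle_polygon(15.5, 15.5, 10)
  m <- rasterize_contours(lge_contours(list(list(endo = p, epi = p)),
                                       validate = FALSE), stack)
  expect_equal(sum(m$mask), 0)

  # endo outside epi is a contract violation
  expect_error(
    rasterize_contours(lge_contours(list(list(
      endo = circle_polygon(15.5, 15.5, 12),
      epi = circle_polygon(15.5, 15.5, 8)
    )), validate = FALSE), stack),
    "not inside"
  )

  # 10 voxels at 1x1x8 mm: 0.08 mL, 0.084 g at 1.05 g/mL
  w <- array(0, c(32, 32, 1))
  fx <- annulus_fixture(grid = 32, r_endo = 5, r_epi = 14)
  idx <- which(fx$mask$mask)[1:10]
  w[idx] <- 1
  sz <- infarct_size(w, fx$mask, fx$stack)
  expect_equal(sz$volume_ml, 0.08)
  expect_equal(sz$mass_g, 0.084)
})

test_that("sector partition is an equal-width angular partition", {
  fx <- annulus_fixture(grid = 70, spacing = 1, r_endo = 20, r_epi = 30)
  lab <- sector_partition(fx$mask, fx$stack, n_sectors = 5)
  counts <- tabulate(lab[fx$mask$mask], 5)
  expect_true(all(abs(counts - mean(counts)) / mean(counts) < 0.01))
  # every masked voxel carries exactly one label
  expect_false(anyNA(lab[fx$mask$mask]))
  expect_true(all(is.na(lab[!fx$mask$mask])))

  lab1 <- sector_partition(fx$mask, fx$stack, n_sectors = 1)
  expect_true(all(lab1[fx$mask$mask] == 1L))

  # annulus with two opposite quadrants removed (keeps the centroid at the
  # ring center) and bins aligned to quadrants: those sectors stay empty
  fx2 <- annulus_fixture(grid = 70, spacing = 1, r_endo = 20, r_epi = 30)
  g <- lgequant:::grid_xy(fx2$stack)
  ang <- (atan2(g$y - fx2$center[2], g$x - fx2$center[1]) * 180 / pi) %% 360
  fx2$mask$mask[, , 1][ang < 90 | (ang >= 180 & ang < 270)] <- FALSE
  lab4 <- sector_partition(fx2$mask, fx2$stack, n_sectors = 4)
  counts4 <- tabulate(lab4[fx2$mask$mask], 4)
  expect_equal(counts4 == 0, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("midmural band sits at half depth and degrades gracefully", {
  fx <- annulus_fixture(grid = 60, spacing = 1, r_endo = 10, r_epi = 22)
  band <- midmural_band(fx$mask, fx$contours, fx$stack)
  expect_true(all(band[!fx$mask$mask] == FALSE))
  frac <- sum(band) / sum(fx$mask$mask)
  # 12 px wall: band should be ~6 px (+- 1 px discretization)
  expect_gt(frac * 12, 5)
  expect_lt(frac * 12, 7)

  # narrowing the window shrinks the band monotonically
  narrow <- midmural_band(fx$mask, fx$contours, fx$stack, window = c(0.35, 0.65))
  expect_true(all(band[narrow]))
  expect_lt(sum(narrow), sum(band))

  # full disk without an endocardial contour has no transmural axis
  stack <- lge_stack(array(0, c(32, 32, 1)), spacing = 1, thickness = 8)
  disk <- rasterize_contours(lge_contours(list(list(
    epi = circle_polygon(15.5, 15.5, 10))), validate = FALSE), stack)
  expect_error(midmural_band(disk, lge_contours(list(list(
    epi = circle_polygon(15.5, 15.5, 10))), validate = FALSE), stack),
    "transmural")

  # 2-px wall still yields a non-empty band
  fx2 <- annulus_fixture(grid = 40, spacing = 1, r_endo = 10, r_epi = 12)
  band2 <- midmural_band(fx2$mask, fx2$contours, fx2$stack)
  expect_gt(sum(band2), 0)
})

test_that("endocardial distance is Euclidean in mm", {
  # circle endo of radius 5 at (10, 10): point at (16, 10) is 1 mm away
  endo <- circle_polygon(10, 10, 5)
  expect_lt(abs(dist_to_polygon(16, 10, endo) - 1), 0.05)
  # a vertex lies exactly on the boundary
  expect_equal(dist_to_polygon(endo[1, 1], endo[1, 2], endo), 0)

  # spacing 1.5 mm: voxel two pixels away from the boundary is 3 mm away
  fx <- annulus_fixture(grid = 40, spacing = 1.5, r_endo = 9, r_epi = 21)
  ed <- endocardial_distance(fx$mask, fx$contours, fx$stack)
  g <- lgequant:::grid_xy(fx$stack)
  r <- sqrt((g$x - fx$center[1])^2 + (g$y - fx$center[2])^2)
  two_px <- fx$mask$mask[, , 1] & abs(r - (fx$r_endo + 3)) < 0.4
  expect_true(any(two_px))
  expect_true(all(abs(ed[, , 1][two_px] - 3) < 0.75 + 0.4))

  # slices without an endo contour are flagged
  cs <- lge_contours(list(list(epi = circle_polygon(29.25, 29.25, 21))),
                     validate = FALSE)
  disk <- rasterize_contours(cs, fx$stack)
  ed2 <- endocardial_distance(disk, cs, fx$stack)
  expect_equal(attr(ed2, "missing_endo"), 1L)
  expect_true(all(is.nan(ed2[disk$mask])))
})

test_that("connected components use 6-connectivity with volume bookkeeping", {
  stack <- lge_stack(array(1, c(10, 10, 2)), spacing = 1.5, thickness = 8)
  supp <- array(FALSE, c(10, 10, 2))
  supp[2:2, 2:6, 1] <- TRUE          # 5-voxel blob
  supp[8:8, 2:6, 2] <- TRUE          # 5-voxel blob, other slice/corner
  comps <- connected_components(supp, stack)
  expect_length(comps, 2)
  expect_setequal(vapply(comps, `[[`, 0L, "n"), c(5L, 5L))

  single <- array(FALSE, c(10, 10, 1))
  single[5, 5, 1] <- TRUE
  c1 <- connected_components(single, lge_stack(array(0, c(10, 10, 1)),
                                               spacing = 1.5, thickness = 8))
  expect_equal(c1[[1]]$volume_ml, 1.5 * 1.5 * 8 / 1000)

  # diagonal-only adjacency in-plane separates (4-connectivity in-plane)
  diag2 <- array(FALSE, c(10, 10, 1))
  diag2[3, 3, 1] <- TRUE; diag2[4, 4, 1] <- TRUE
  expect_length(connected_components(diag2, stack), 2)

  # face adjacency across slices joins
  across <- array(FALSE, c(10, 10, 2))
  across[3, 3, 1] <- TRUE; across[3, 3, 2] <- TRUE
  expect_length(connected_components(across, stack), 1)

  expect_length(connected_components(array(FALSE, c(10, 10, 1)), stack), 0)
})

test_that("infarct size is linear in weights and invariant to uniform rescaling", {
  fx <- annulus_fixture(grid = 32, r_endo = 5, r_epi = 14)
  w <- array(0, dim(fx$stack$voxels))
  w[fx$mask$mask] <- 1
  expect_equal(infarct_size(w, fx$mask, fx$stack)$fraction_pct, 100)
  expect_equal(infarct_size(w * 0, fx$mask, fx$stack)$fraction_pct, 0)

  # half the mask at weight 0.5 -> 25%
  w2 <- array(0, dim(fx$stack$voxels))
  idx <- which(fx$mask$mask)
  w2[idx[seq_len(length(idx) %/% 2)]] <- 0.5
  expect_equal(infarct_size(w2, fx$mask, fx$stack)$fraction_pct,
               100 * 0.5 * (length(idx) %/% 2) / length(idx))

  # linearity
  s1 <- infarct_size(w2, fx$mask, fx$stack)
  s2 <- infarct_size(w2 / 2, fx$mask, fx$stack)
  expect_equal(s2$volume_ml, s1$volume_ml / 2)

  # uniform spacing rescaling leaves the fraction unchanged
  stack2 <- lge_stack(fx$stack$voxels, spacing = 2 * fx$stack$spacing,
                      thickness = fx$stack$thickness)
  mask2 <- lgequant:::new_lge_mask(fx$mask$mask, stack2)
  expect_equal(infarct_size(w2, mask2, stack2)$fraction_pct,
               s1$fraction_pct)

  expect_error(infarct_size(w, lgequant:::new_lge_mask(
    array(FALSE, dim(fx$stack$voxels)), fx$stack), fx$stack), "LV mass")
})
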