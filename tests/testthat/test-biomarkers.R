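test_that("slab and annulus thickness are recovered within one in-plane spacing", {
  for (w in c(2, 5, 10.5)) for (s in c(0.25, 0.5, 1.0)) {
    ph <- make_phantom(phantom_spec("slab", spacing = c(s, s, s), slab_width = w))
    th <- compartment_thickness(ph$mask, 1L, mode = "full_width")
    expect_lte(abs(th$mean_thickness_mm - w), s + 1e-9)
  }
  ph <- make_phantom(phantom_spec("annulus", spacing = c(0.5, 0.5, 0.5),
                                  annulus_inner = 12, annulus_outer = 15))
  th <- compartment_thickness(ph$mask, 1L)
  expect_lte(abs(th$mean_thickness_mm - 3), 0.5)
})

test_that("full width is exactly twice half width; empty masks give NaN", {
  ph <- make_phantom(phantom_spec("slab", spacing = c(0.5, 0.5, 0.5)))
  full <- compartment_thickness(ph$mask, 1L, mode = "full_width")
  half <- compartment_thickness(ph$mask, 1L, mode = "half_width")
  expect_equal(full$mean_thickness_mm, 2 * half$mean_thickness_mm)
  empty <- mask_volume(array(0L, c(8, 8, 2)), c(1, 1, 1))
  expect_warning(res <- compartment_thickness(empty, 1L), "NaN")
  expect_true(is.nan(res$mean_thickness_mm))
})

test_that("thickness and volume scale linearly with spacing on a fixed grid", {
  ph <- make_phantom(phantom_spec("slab", spacing = c(0.5, 0.5, 0.5)))
  m1 <- ph$mask
  m2 <- mask_volume(m1$labels, m1$spacing * 2, m1$label_map)
  t1 <- compartment_thickness(m1, 1L)$mean_thickness_mm
  t2 <- compartment_thickness(m2, 1L)$mean_thickness_mm
  expect_equal(t2, 2 * t1)
  expect_equal(tissue_volume(m2, 1L), 8 * tissue_volume(m1, 1L))
})

test_that("tissue volume is voxel count times voxel volume and additive", {
  arr <- array(0L, c(20, 10, 10))
  arr[1:10, 1:10, 1:10] <- 1L # 1000 voxels
  arr[11:15, 1:10, 1:10] <- 2L
  mv <- mask_volume(arr, c(0.5, 0.5, 1.0))
  expect_equal(tissue_volume(mv, 1L), 0.25)
  expect_equal(tissue_volume(mv, 3L), 0)
  whole <- mask_volume(array((arr > 0) * 9L, dim(arr)), mv$spacing)
  expect_equal(tissue_volume(mv, 1L) + tissue_volume(mv, 2L),
               tissue_volume(whole, 9L))
  pe <- make_phantom(phantom_spec("ellipsoid", spacing = c(0.5, 0.5, 0.5)))
  expect_lt(abs(tissue_volume(pe$mask, 1L) - 4.18879) / 4.18879, 0.02)
})

test_that("disc heights use the cranio-caudal extent and the max across slices", {
  arr <- array(0L, c(40, 20, 1))
  arr[10:29, 5:15, 1] <- 1L # 20 rows at 0.6 mm -> 12.0 mm
  mv <- mask_volume(arr, c(0.6, 0.6, 3))
  dh <- disc_heights(mv, 1L)
  expect_equal(dh$height_mm, 12.0)
  # two stacked rectangles -> two levels, each with its own height
  arr2 <- array(0L, c(60, 20, 1))
  arr2[5:24, 5:15, 1] <- 1L   # 20 px
  arr2[35:49, 5:15, 1] <- 1L  # 15 px
  dh2 <- disc_heights(mask_volume(arr2, c(0.6, 0.6, 3)), 1L)
  expect_equal(sort(dh2$height_mm), c(15, 20) * 0.6)
  # per-level height is the maximum over slices (extents 18, 20, 19 px)
  arr3 <- array(0L, c(40, 20, 3))
  arr3[10:27, 5:15, 1] <- 1L
  arr3[10:29, 5:15, 2] <- 1L
  arr3[10:28, 5:15, 3] <- 1L
  dh3 <- disc_heights(mask_volume(arr3, c(1, 1, 3)), 1L)
  expect_equal(dh3$height_mm, 20)
  expect_equal(dh3$n_slices, 3L)
  # empty mask -> empty result
  expect_equal(nrow(disc_heights(mask_volume(array(0L, c(5, 5, 2)),
                                             c(1, 1, 1)), 1L)), 0L)
})

test_that("disc-stack phantom heights are recovered exactly", {
  ph <- make_phantom(phantom_spec("disc_stack", spacing = c(0.6, 0.6, 3),
                                  disc_height = 12, disc_count = 3L))
  dh <- disc_heights(ph$mask, 1L)
  expect_equal(dh$height_mm, ph$truth$heights_mm)
})

test_that("relaxometry mean clips to range and matches an elementwise oracle", {
  arr <- array(0L, c(3, 1, 1)); arr[] <- 1L
  mv <- mask_volume(arr, c(1, 1, 1))
  pm <- parametric_map(array(c(50, 150, -10), c(3, 1, 1)), c(1, 1, 1))
  expect_equal(relaxometry_mean(pm, mv, 1L), 50.0)
  pm2 <- parametric_map(array(42, c(3, 1, 1)), c(1, 1, 1))
  expect_equal(relaxometry_mean(pm2, mv, 1L), 42.0)
  set.seed(5)
  vol <- array(sample(0:1, 4 * 4 * 3, TRUE), c(4, 4, 3))
  mv3 <- mask_volume(vol, c(1, 1, 1))
  vals <- array(stats::rnorm(48, 60, 40), c(4, 4, 3))
  pm3 <- parametric_map(vals, c(1, 1, 1))
  manual <- mean(pmin(pmax(vals[vol == 1L], 0), 100))
  expect_equal(relaxometry_mean(pm3, mv3, 1L), manual)
  expect_warning(out <- relaxometry_mean(pm3, mv3, 9L), "empty")
  expect_true(is.nan(out))
})

test_that("reference z-scoring is exact and frozen", {
  set.seed(8)
  df <- data.frame(a = stats::rnorm(50, 2, 0.5), b = stats::rnorm(50, 10, 2),
                   healthy = rep(c(TRUE, FALSE), 25))
  ref <- fit_reference(df, c("a", "b"), reference = df$healthy)
  z <- zscore(df[df$healthy, ], ref)
  expect_lt(abs(mean(z$a)), 1e-12)
  expect_equal(stats::sd(z$a), 1)
  ref2 <- fit_reference(data.frame(a = c(1.5, 2, 2.5, 2)), "a")
  expect_equal(ref2$mean[["a"]], 2)
  manual <- zscore(data.frame(a = 3), fit_reference(
    data.frame(a = c(1.5, 2, 2.5)), "a"))
  expect_equal(manual$a, (3 - 2) / 0.5)
  dfc <- data.frame(a = rep(1, 10))
  expect_error(fit_reference(dfc, "a"), "a")
  expect_error(fit_reference(df[1:2, ], "a"), "< 3")
})

test_that("annual change uses consecutive available visits", {
  ch <- annual_change(c(0, 12, 36), c(2.0, 1.9, 1.6))
  expect_equal(ch$annual_change, c(-0.1, -0.15))
  expect_equal(nrow(annual_change(0, 2)), 0L)
})

test_that("extract_biomarkers emits one standardized table per volume", {
  ph <- make_phantom(phantom_spec("slab", spacing = c(0.5, 0.5, 0.5)))
  tab <- extract_biomarkers(ph$mask, "subj1")
  expect_s3_class(tab, "biomarker_table")
  expect_true(all(c("thickness", "volume") %in% tab$biomarker))
  expect_equal(tab$units[tab$biomarker == "volume"], "cm3")
})
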