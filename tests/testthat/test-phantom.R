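test_that("phantom truth masks partition the tissue and nest correctly", {
  for (seed in c(1, 2, 3)) {
    ph <- small_phantom(seed = seed)
    tr <- ph$truth
    expect_true(all(tr$gt_mask[tr$gt_mask] & tr$whole_mask[tr$gt_mask]))
    expect_true(!any(tr$gt_mask & !tr$whole_mask))
    expect_true(!any(tr$st_mask & !tr$whole_mask))
    expect_false(any(tr$gt_mask & tr$st_mask))
    expect_identical(tr$true_n_tubules, nrow(tr$tubule_params))
    # true indices equal mask ratios by construction
    expect_equal(tr$true_gti,
                 100 * sum(tr$gt_mask | tr$st_mask) / sum(tr$whole_mask))
    expect_equal(tr$true_tai, 100 * sum(tr$gt_mask) / sum(tr$whole_mask))
  }
})

test_that("same spec and seed give bit-identical phantoms", {
  a <- small_phantom(seed = 9)
  b <- small_phantom(seed = 9)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  c <- small_phantom(seed = 10)
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("empty-gonad phantom has zero indices and a bare tissue blob", {
  ph <- generate_phantom(phantom_spec(
    height_px = 128, width_px = 128, n_tubules = 0, st_fraction = 0, seed = 3
  ))
  expect_identical(ph$truth$true_n_tubules, 0L)
  expect_equal(ph$truth$true_tai, 0)
  expect_equal(ph$truth$true_gti, 0)
  expect_true(any(ph$truth$whole_mask))
  expect_false(any(ph$truth$gt_mask))
  expect_false(any(ph$truth$st_mask))
})

test_that("tissue_fraction = 1 fills the whole frame", {
  ph <- generate_phantom(phantom_spec(
    height_px = 64, width_px = 64, n_tubules = 2, st_fraction = 0,
    tubule_semi_axis_um = c(log(2), 0.05), microns_per_pixel = 0.25,
    tissue_fraction = 1, seed = 5
  ))
  expect_true(all(ph$truth$whole_mask))
})

test_that("impossible tubule packing fails with an informative error", {
  spec <- phantom_spec(
    height_px = 96, width_px = 96, n_tubules = 30,
    tubule_semi_axis_um = c(log(5), 0.05), microns_per_pixel = 0.25,
    st_fraction = 0, tissue_fraction = 0.4, seed = 1
  )
  expect_error(generate_phantom(spec), "attempts")
})

test_that("invalid specs are rejected at construction", {
  expect_error(phantom_spec(st_fraction = 1), "st_fraction")
  expect_error(phantom_spec(tissue_fraction = 0), "tissue_fraction")
  expect_error(phantom_spec(aspect_ratio_range = c(0.5, 2)), "aspect_ratio_range")
  pal <- default_palette()
  pal$tubule$mean <- c(300, 0, 0)
  expect_error(phantom_spec(class_palette = pal), "Palette")
})

test_that("doubling linear dimensions preserves indices and scales areas by 4", {
  base <- list(n = 4, st = 0.25, seed = 21)
  ph1 <- generate_phantom(phantom_spec(
    height_px = 128, width_px = 128, microns_per_pixel = 2,
    n_tubules = base$n, tubule_semi_axis_um = c(log(12), 0.05),
    st_fraction = base$st, tissue_fraction = 0.7, seed = base$seed
  ))
  # same spec in microns, half the pixel size -> twice the linear resolution
  ph2 <- generate_phantom(phantom_spec(
    height_px = 256, width_px = 256, microns_per_pixel = 1,
    n_tubules = base$n, tubule_semi_axis_um = c(log(12), 0.05),
    st_fraction = base$st, tissue_fraction = 0.7, seed = base$seed
  ))
  expect_equal(ph2$truth$true_gti, ph1$truth$true_gti, tolerance = 0.02)
  expect_equal(ph2$truth$true_tai, ph1$truth$true_tai, tolerance = 0.02)
  # areas in um2 agree (same physical phantom); areas in px scale by 4
  mean_px1 <- ph1$truth$true_mean_tubule_area_um2 / 2^2
  mean_px2 <- ph2$truth$true_mean_tubule_area_um2 / 1^2
  expect_equal(mean_px2 / mean_px1, 4, tolerance = 0.05)
})

test_that("truth_metrics reproduces hand-computed ratios and the disk area", {
  # constructed truth: whole 100x100, GT 1500 px, ST 500 px
  whole <- matrix(TRUE, 100, 100)
  gt <- matrix(FALSE, 100, 100); gt[1:30, 1:50] <- TRUE
  st <- matrix(FALSE, 100, 100); st[61:70, 1:50] <- TRUE
  tr <- structure(
    list(whole_mask = whole, gt_mask = gt, st_mask = st,
         tubule_params = tibble::tibble(), true_gti = 20, true_tai = 15,
         true_n_tubules = 0L, true_mean_tubule_area_um2 = NA_real_),
    class = "phantom_truth"
  )
  m <- truth_metrics(tr, microns_per_pixel = 2)
  expect_equal(m$gti_percent, 20)
  expect_equal(m$tai_percent, 15)
  expect_equal(m$gt_area_um2, 1500 * 4)
  # st_fraction = 0 phantom: gti equals tai
  ph <- small_phantom(seed = 2, st_fraction = 0)
  expect_equal(ph$truth$true_gti, ph$truth$true_tai)
  # one circular tubule radius 20 px at 2 um/px ~ pi * 20^2 * 4 um2
  one <- generate_phantom(phantom_spec(
    height_px = 128, width_px = 128, microns_per_pixel = 2, n_tubules = 1,
    tubule_semi_axis_um = c(log(40), 1e-6), aspect_ratio_range = c(1, 1),
    st_fraction = 0, tissue_fraction = 0.9, seed = 8
  ))
  expect_equal(one$truth$true_mean_tubule_area_um2, pi * 20^2 * 4,
               tolerance = 0.02)
})

test_that("stage presets hit their target gonadal fraction by construction", {
  cases <- list(list(1, "2n", 20), list(1, "3n_beta", 10), list(3, "3n_beta", 23))
  for (cs in cases) {
    ph <- generate_phantom(stage_phantom_spec(cs[[1]], cs[[2]],
                                              height_px = 512, width_px = 512,
                                              seed = 31))
    expect_equal(ph$truth$true_gti, cs[[3]], tolerance = 0.05)
  }
  expect_error(stage_phantom_spec(2, "2n"), "preset")
})
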