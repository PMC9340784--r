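# Brute-force region oracle: area and centroid by direct pixel enumeration.
brute_region <- function(mask) {
  ij <- which(mask, arr.ind = TRUE)
  list(area = nrow(ij), centroid = colMeans(ij))
}

test_that("labeling counts components, honours min size, uses 8-connectivity", {
  m <- matrix(FALSE, 40, 40)
  m[2:11, 2:11] <- TRUE     # 100 px
  m[25:34, 25:34] <- TRUE   # 100 px
  lab <- label_tubules(m, min_area_px = 50)
  expect_identical(attr(lab, "n_labels"), 2L)
  small <- matrix(FALSE, 20, 20)
  small[5, 5:9] <- TRUE; small[6, 5:9] <- TRUE  # 10 px
  expect_identical(attr(label_tubules(small, 50), "n_labels"), 0L)
  # diagonal touch is one component under 8-connectivity
  diagm <- matrix(FALSE, 10, 10)
  diagm[cbind(1:5, 1:5)] <- TRUE
  expect_identical(attr(label_tubules(diagm, 1), "n_labels"), 1L)
  # labels follow raster order of first pixels
  two <- matrix(FALSE, 10, 10)
  two[8, 1] <- TRUE; two[1, 9] <- TRUE
  lab2 <- label_tubules(two, 1)
  expect_identical(lab2[1, 9], 1L)
  expect_identical(lab2[8, 1], 2L)
})

test_that("phantom tubules above min size are labeled exactly once each", {
  ph <- small_phantom(seed = 40, n_tubules = 10, margin = 6, size = 320)
  lab <- label_tubules(ph$truth$gt_mask, min_area_px = 30)
  expect_identical(attr(lab, "n_labels"), 10L)
})

test_that("pixel conservation: labeled plus discarded pixels equal the mask", {
  ph <- small_phantom(seed = 41)
  gt <- ph$truth$gt_mask
  # salt the mask with specks so some components are discarded
  gt[cbind(c(2, 5, 9), c(2, 120, 250))] <- TRUE
  lab <- label_tubules(gt, min_area_px = 30)
  expect_identical(sum(lab > 0) + attr(lab, "px_discarded"), sum(gt))
  expect_gte(attr(lab, "n_discarded"), 1L)
})

test_that("disk morphometry matches analytic values", {
  d <- 201
  disk <- outer(seq_len(d) - 101, seq_len(d) - 101,
                function(y, x) x^2 + y^2 <= 50^2)
  rec <- measure_tubules(label_tubules(disk, 30), microns_per_pixel = 2)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$area_px, sum(disk))
  expect_equal(rec$area_um2, sum(disk) * 4)
  expect_equal(rec$perimeter_px, 2 * pi * 50, tolerance = 0.02)
  expect_gte(rec$circularity, 0.95); expect_lte(rec$circularity, 1.02)
  expect_gte(rec$gravelius_k, 0.98); expect_lte(rec$gravelius_k, 1.05)
  expect_false(rec$touches_border)
  expect_equal(rec$centroid_row, 101); expect_equal(rec$centroid_col, 101)
})

test_that("ellipse axes come out of the second moments at ratio 2", {
  m <- outer(seq_len(201) - 101, seq_len(241) - 121,
             function(y, x) (x / 80)^2 + (y / 40)^2 <= 1)
  rec <- measure_tubules(label_tubules(m, 30), 1)
  expect_equal(rec$major_axis_px / rec$minor_axis_px, 2, tolerance = 0.05)
  expect_equal(rec$major_axis_px, 160, tolerance = 0.02 * 160)
})

test_that("single pixel and border regions are measured, flagged", {
  m <- matrix(FALSE, 5, 5); m[1, 3] <- TRUE
  rec <- measure_tubules(label_tubules(m, 1), 1)
  expect_identical(rec$area_px, 1L)
  expect_true(rec$touches_border)
  m2 <- matrix(FALSE, 5, 5); m2[3, 3] <- TRUE
  expect_false(measure_tubules(label_tubules(m2, 1), 1)$touches_border)
})

test_that("gravelius matches the circle identity and Ramanujan ellipses", {
  expect_equal(gravelius(2 * pi * 7, pi * 49), 1)
  ram <- function(a, b) pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  expect_equal(gravelius(ram(2, 1), 2 * pi), 1.0902, tolerance = 1e-3)
  expect_equal(gravelius(ram(8, 1), 8 * pi), 1.8422, tolerance = 1e-3)
  expect_error(gravelius(0, 10), "positive")
  expect_error(gravelius(10, -1), "positive")
})

test_that("measured K on rasterized disks converges to 1 with radius", {
  ks <- sapply(c(50, 100), function(r) {
    d <- 2 * r + 21
    disk <- outer(seq_len(d) - (r + 11), seq_len(d) - (r + 11),
                  function(y, x) x^2 + y^2 <= r^2)
    measure_tubules(label_tubules(disk, 1), 1)$gravelius_k
  })
  expect_lte(abs(ks[2] - 1), 0.02)
  expect_lte(abs(ks[2] - 1), abs(ks[1] - 1) + 5e-3)
})

test_that("the K filter is strict at the boundary, order-preserving, idempotent", {
  rec <- tibble::tibble(label = 1:4, gravelius_k = c(1.0, 1.69, 1.70, 1.84))
  kept <- filter_circular(rec)
  expect_identical(kept$label, 1:2)
  expect_identical(filter_circular(kept), kept)
  expect_identical(nrow(filter_circular(rec[0, ])), 0L)
})

test_that("area and centroid equal brute-force enumeration on random blobs", {
  withr::with_seed(7, {
    for (i in 1:60) {
      m <- matrix(FALSE, 15, 15)
      seedpt <- c(sample(3:13, 1), sample(3:13, 1))
      px <- seedpt
      cur <- seedpt
      for (s in seq_len(sample(5:99, 1))) {
        step <- cur + sample(c(-1L, 0L, 1L), 2, TRUE)
        step <- pmin(pmax(step, 1L), 15L)
        px <- rbind(px, step); cur <- step
      }
      m[px] <- TRUE
      rec <- measure_tubules(label_tubules(m, 1), 1)
      oracle <- brute_region(m)
      expect_identical(rec$area_px, oracle$area)
      expect_equal(rec$centroid_row, oracle$centroid[["row"]])
      expect_equal(rec$centroid_col, oracle$centroid[["col"]])
    }
  })
})

test_that("representativeness test behaves across regular and degenerate input", {
  # all kept: zero variance -> degenerate no-difference
  allkept <- data.frame(animal = 1:3, kept = c(10, 12, 8), total = c(10, 12, 8))
  r1 <- representativeness(allkept)
  expect_true(r1$degenerate_flag)
  expect_equal(r1$p_value, 1)
  # proportions close to the pooled value -> no significant difference
  d <- data.frame(animal = 1:3, kept = c(90, 92, 88), total = c(100, 100, 100))
  r2 <- representativeness(d)
  expect_gt(r2$p_value, 0.05)
  # closed-form check of the one-sample t statistic
  props <- c(0.9, 0.92, 0.88); pooled <- 0.9
  tref <- (mean(props) - pooled) / (sd(props) / sqrt(3))
  expect_equal(r2$t_statistic, tref, tolerance = 1e-10)
  # zero-total animal excluded with a warning
  d0 <- rbind(d, data.frame(animal = 4, kept = 0, total = 0))
  expect_warning(r3 <- representativeness(d0), "zero tubules")
  expect_identical(r3$n_animals, 3L)
  expect_error(representativeness(data.frame(animal = 1, kept = 2, total = 1)),
               "kept")
})
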