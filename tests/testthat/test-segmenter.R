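# Initialization, mask extraction, the full evolution loop, and skull
# stripping.

test_that("binary initialization covers exactly the box", {
  box <- bounding_box(5, 12, 7, 15)
  phi <- initialize_lsf(box, c(20, 20), c0 = 2)
  expect_true(all(phi %in% c(-2, 2)))
  expect_true(all(phi[5:11, 7:14] == -2))
  expect_equal(sum(phi == -2), 7 * 8)
  expect_equal(extract_mask(phi)[5:11, 7:14], matrix(1, 7, 8))
  expect_equal(sum(extract_mask(phi)), 7 * 8)

  expect_error(initialize_lsf(bounding_box(1, 5, 2, 5), c(20, 20)),
               "strictly inside")
  expect_error(initialize_lsf(bounding_box(2, 25, 2, 5), c(20, 20)),
               "strictly inside")
  expect_error(bounding_box(5, 5, 2, 8), "non-empty")
})

test_that("extract_mask thresholds at zero and disks have the right area", {
  expect_equal(sum(extract_mask(matrix(2, 5, 5))), 0)
  r <- 10
  phi <- sdf_circle(c(40, 40), r)
  area <- sum(extract_mask(phi))
  expect_lt(abs(area - pi * r^2), 4 * r)
})

test_that("max_iter = 0 returns the initial box mask", {
  ph <- make_disk_phantom()
  fit <- run_segmentation(ph$image, ph$box,
                          evolution_params(max_iter = 0))
  expect_equal(fit$mask, extract_mask(initialize_lsf(ph$box, dim(ph$image))))
  expect_equal(fit$iterations, 0L)
})

test_that("the disk phantom is segmented accurately and deterministically", {
  ph <- make_disk_phantom()
  fit <- run_segmentation(ph$image, ph$box, box_mode = "seed")
  expect_gte(dice(fit$mask, ph$truth), 0.95)
  expect_lte(fit$iterations, 500)
  expect_equal(fit$status, "converged")

  fit2 <- run_segmentation(ph$image, ph$box, box_mode = "seed")
  expect_identical(fit$mask, fit2$mask)
  expect_identical(fit$phi, fit2$phi)

  # growing max_iter does not invalidate a converged result
  fit3 <- run_segmentation(ph$image, ph$box,
                           evolution_params(max_iter = 2000),
                           box_mode = "seed")
  expect_identical(fit$mask, fit3$mask)
})

test_that("dice is non-decreasing in boundary contrast", {
  dices <- vapply(c(20, 50, 100), function(contrast) {
    ph <- make_disk_phantom(inside_val = 120 - contrast, outside_val = 120)
    fit <- run_segmentation(ph$image, ph$box, box_mode = "seed")
    dice(fit$mask, ph$truth)
  }, numeric(1))
  expect_true(all(diff(dices) >= -1e-12))
})

test_that("weak-boundary ventricles favor the region-augmented flow", {
  ph <- make_ventricle_phantom()
  fit_mod <- run_segmentation(ph$image, ph$box, box_mode = "around")
  fit_drl <- run_segmentation(ph$image, ph$box, method = "drlse",
                              box_mode = "around")
  d_mod <- dice(fit_mod$mask, ph$truth)
  d_drl <- dice(fit_drl$mask, ph$truth)
  expect_gt(d_mod, d_drl + 0.05)
  expect_gt(d_mod, 0.7)
})

test_that("pure-noise images do not crash the loop", {
  I <- pmin(pmax(withr::with_seed(42, matrix(rnorm(64^2, 128, 30), 64, 64)),
                 0), 255)
  box <- centered_box(c(64, 64), 0.4)
  expect_no_error(suppressWarnings(
    fit <- run_segmentation(I, box, evolution_params(max_iter = 120))))
  expect_true(fit$status %in% c("converged", "max_iter", "contour_vanished"))
})

test_that("a structureless constant image reports contour vanishing", {
  ph <- make_disk_phantom(inside_val = 90, outside_val = 90)
  expect_warning(fit <- run_segmentation(ph$image, ph$box,
                                         method = "drlse",
                                         box_mode = "seed"),
                 "vanished")
  expect_equal(fit$status, "contour_vanished")
  expect_equal(sum(fit$mask), 0)
})

test_that("history records areas and the box constraint holds", {
  ph <- make_ventricle_phantom()
  fit <- run_segmentation(ph$image, ph$box, box_mode = "around")
  expect_s3_class(fit$history, "tbl_df")
  expect_equal(nrow(fit$history), fit$iterations)
  outside <- !ventseg:::box_mask(ph$box, dim(ph$image))
  expect_true(all(fit$mask[outside] == 0))
})

test_that("skull strip recovers a bright ellipse on black background", {
  shape <- c(96, 96)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ell <- ((rows - 48) / 35)^2 + ((cols - 48) / 28)^2 < 1
  I <- ifelse(ell, 180, 5)
  # punch a hole and add a small bright speck elsewhere
  I[46:50, 46:50] <- 5
  I[5:7, 5:7] <- 200
  m <- skull_strip(I)
  band <- EBImage::dilate(ell * 1, EBImage::makeBrush(5, "disc")) > 0
  core <- EBImage::erode(ell * 1, EBImage::makeBrush(5, "disc")) > 0
  expect_true(all(m[core] == 1))        # ellipse interior kept, hole filled
  expect_true(all(m[!band] == 0))       # speck removed, background clean
  expect_error(skull_strip(matrix(0, 20, 20)), "foreground")
})

test_that("skull strip mask contains the raw thresholded component", {
  shape <- c(64, 64)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ell <- ((rows - 32) / 22)^2 + ((cols - 32) / 18)^2 < 1
  I <- ifelse(ell, 150, 0)
  I[30:34, 30:34] <- 0                 # interior hole
  m <- skull_strip(I)
  bright <- I > 75                     # the raw foreground
  expect_true(all(m[bright] == 1))     # closing/filling only grow the mask
  expect_true(all(m[30:34, 30:34] == 1))  # hole filled
})
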