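test_that("ellipse_mask area approaches the analytic ellipse area", {
  # 19 x 8 mm ellipse on 0.85 mm pixels: counted area must lie within one
  # pixel-diagonal band around the perimeter of pi*a*b.
  sp <- c(0.85, 0.85, 1)
  roi <- roi_spec(center = c(25, 25))
  m <- ellipse_mask(c(60, 60, 1), sp, roi)
  counted <- sum(m) * sp[1] * sp[2]
  a <- 19 / 2; b <- 8 / 2
  analytic <- pi * a * b
  # Ramanujan perimeter approximation x pixel diagonal
  per <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  band <- per * sqrt(2) * sp[1]
  expect_lt(abs(counted - analytic), band)
})

test_that("ellipse_mask degenerate and symmetry cases", {
  sp <- c(1, 1, 1)
  # circle with diameter one voxel centered on a voxel center -> 1 voxel
  roi <- roi_spec(center = c(5, 5), major_axis = 1, minor_axis = 1)
  expect_equal(sum(ellipse_mask(c(11, 11), sp, roi)), 1L)
  # orientation 90 degrees swaps the bounding-box extents
  roi0 <- roi_spec(center = c(10, 10), major_axis = 12, minor_axis = 4)
  roi90 <- roi_spec(center = c(10, 10), major_axis = 12, minor_axis = 4,
                    orientation = 90)
  bbox <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    c(diff(range(idx[, 1])), diff(range(idx[, 2])))
  }
  expect_equal(bbox(ellipse_mask(c(21, 21), sp, roi90)),
               rev(bbox(ellipse_mask(c(21, 21), sp, roi0))))
  # ROI entirely outside the grid -> error
  expect_error(ellipse_mask(c(10, 10), sp, roi_spec(center = c(100, 100))),
               "outside")
})

test_that("opening_volume reproduces the hand-counted worked example", {
  # control ROI: population mean 100, sd 5 -> threshold 115; treated ROI
  # holds 30 voxels at 200 in one slice -> 30 * 0.7225 mm^3.
  sp <- c(0.85, 0.85, 1)
  img <- array(100, dim = c(80, 40, 3))
  # control region values alternating 95/105: population sd exactly 5
  cmask <- ellipse_mask(c(80, 40), sp, roi_spec(center = c(50, 15)))
  ci <- which(cmask)
  img[, , 1][ci] <- rep(c(95, 105), length.out = length(ci))
  img[, , 2][ci] <- rep(c(95, 105), length.out = length(ci))
  img[, , 3][ci] <- rep(c(95, 105), length.out = length(ci))
  stopifnot(length(ci) %% 2 == 0)
  tmask <- ellipse_mask(c(80, 40), sp, roi_spec(center = c(12, 15)))
  ti <- which(tmask)[1:30]
  sl2 <- img[, , 2]; sl2[ti] <- 200; img[, , 2] <- sl2
  vol <- image_volume(img, sp)
  res <- opening_volume(vol, roi_spec(center = c(12, 15)),
                        roi_spec(center = c(50, 15)),
                        sd_type = "population")
  expect_equal(res$threshold, 115)
  expect_equal(res$n_voxels_max_slice, 30L)
  expect_equal(res$opening_volume, 30 * 0.85 * 0.85 * 1)
  expect_equal(res$max_slice, 2L)
  # max-slice rule: 30 beats the 0 of the other slices, total = max here
  expect_equal(res$total_volume, res$opening_volume)
})

test_that("opening_volume applies the max-slice rule and strict inequality", {
  sp <- c(1, 1, 1)
  img <- array(0, dim = c(40, 20, 2))
  tmask <- ellipse_mask(c(40, 20), sp, roi_spec(c(8, 10), 10, 6))
  s1 <- img[, , 1]; s1[which(tmask)[1:10]] <- 50; img[, , 1] <- s1
  s2 <- img[, , 2]; s2[which(tmask)[1:25]] <- 50; img[, , 2] <- s2
  # control ROI of constant 0 with a single 10 to give nonzero sd
  cmask <- ellipse_mask(c(40, 20), sp, roi_spec(c(30, 10), 10, 6))
  ci <- which(cmask)
  s1 <- img[, , 1]; s1[ci[1]] <- 10; img[, , 1] <- s1
  vol <- image_volume(img, sp)
  res <- opening_volume(vol, roi_spec(c(8, 10), 10, 6),
                        roi_spec(c(30, 10), 10, 6))
  expect_equal(res$opening_volume, 25)        # max over slices, 1 mm^3 voxels
  expect_equal(res$per_slice_volume, c(`1` = 10, `2` = 25))
  expect_equal(res$total_volume, 35)
  # identical distributions -> 0 mm^3, not an error
  img0 <- array(100, dim = c(40, 20, 2))
  s1 <- img0[, , 1]; s1[ci[1]] <- 110; img0[, , 1] <- s1
  res0 <- opening_volume(image_volume(img0, sp), roi_spec(c(8, 10), 10, 6),
                         roi_spec(c(30, 10), 10, 6))
  expect_equal(res0$opening_volume, 0)
  # voxels exactly at the threshold are excluded (strict >)
  imgt <- array(0, dim = c(40, 20, 1))
  st <- imgt[, , 1]
  st[ci] <- rep(c(-5, 5), length.out = length(ci))
  cv <- st[ci]
  thr <- mean(cv) + 3 * sqrt(mean((cv - mean(cv))^2))
  st[which(tmask)[1:4]] <- thr                         # exactly at threshold
  imgt[, , 1] <- st
  rest <- opening_volume(image_volume(imgt, sp), roi_spec(c(8, 10), 10, 6),
                         roi_spec(c(30, 10), 10, 6), sd_type = "population")
  expect_equal(rest$opening_volume, 0)
  # overlapping ROIs rejected
  expect_error(opening_volume(vol, roi_spec(c(8, 10), 10, 6),
                              roi_spec(c(9, 10), 10, 6)), "overlap")
})

test_that("opening volume is monotone non-increasing in the threshold multiplier", {
  sm <- synth_mri(shape = c(48, 48, 6), contrast = 12, bg_sd = 5, seed = 21)
  tr <- roi_spec(center = c(20, 20))
  ct <- roi_spec(center = c(20, 20) + c(0, 19))
  vols <- vapply(c(2, 3, 4, 5), function(k)
    opening_volume(sm$volume, tr, ct, k = k)$opening_volume, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("synth_mri plants a recoverable lesion and is seeded", {
  sm <- synth_mri(seed = 7)
  sm2 <- synth_mri(seed = 7)
  expect_identical(sm$volume$intensities, sm2$volume$intensities)
  expect_false(identical(sm$volume$intensities,
                         synth_mri(seed = 8)$volume$intensities))
  # contrast 0 -> empty ground truth; negative contrast -> error
  expect_equal(sum(synth_mri(contrast = 0, seed = 1)$lesion_mask), 0L)
  expect_error(synth_mri(contrast = -1), "contrast")
  # high contrast (12 sd) with the midpoint threshold (k = 6): both the
  # background and lesion tails sit 6 sd from the threshold, so the
  # planted voxel count is recovered exactly (per-voxel odds ~1e-9)
  for (seed in 1:10) {
    sm <- synth_mri(shape = c(64, 64, 8), bg_sd = 5, contrast = 60,
                    lesion_center = c(17, 17, 3.5), lesion_axes = c(8, 6, 4),
                    seed = seed)
    tr <- roi_spec(center = c(17, 17))
    ct <- roi_spec(center = c(17, 42))
    res <- opening_volume(sm$volume, tr, ct, k = 6)
    counts <- apply(sm$lesion_mask, 3, sum)
    expect_equal(res$n_voxels_max_slice, max(counts))
    expect_equal(res$opening_volume, max(counts) * prod(sm$volume$spacing))
  }
})

test_that("quantification is equivariant under whole-voxel translation", {
  shift <- c(4, 3)  # voxels
  sp <- c(0.85, 0.85, 1)
  base <- synth_mri(shape = c(64, 64, 6), contrast = 60,
                    lesion_center = c(15, 15, 2.5), seed = 3)
  # same noise field, lesion and ROIs moved together by whole voxels
  mov <- synth_mri(shape = c(64, 64, 6), contrast = 60,
                   lesion_center = c(15, 15, 2.5) + c(shift * sp[1:2], 0),
                   seed = 3)
  r1 <- opening_volume(base$volume, roi_spec(c(15, 15)), roi_spec(c(15, 44)),
                       k = 6)
  r2 <- opening_volume(mov$volume,
                       roi_spec(c(15, 15) + shift * sp[1:2]),
                       roi_spec(c(15, 44)), k = 6)
  expect_equal(r1$n_voxels_max_slice, r2$n_voxels_max_slice)
})

test_that("red_pixel_area matches hand counts and the per-pixel loop oracle", {
  mk <- function(r, g, b, h = 10, w = 10) {
    img <- array(0, dim = c(h, w, 3))
    img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
    img
  }
  # pure-red ROI of 100 pixels at 0.01 mm/pixel -> 0.01 mm^2
  expect_equal(red_pixel_area(mk(1, 0, 0), pixel_size = 0.01)$area_mm2, 0.01)
  # pure blue -> 0
  expect_equal(red_pixel_area(mk(0, 0, 1), pixel_size = 0.01)$area_mm2, 0)
  expect_error(red_pixel_area(matrix(0.5, 10, 10)), "three channels")
  # half red half white: only the 100 red pixels count
  img <- mk(1, 1, 1, 10, 20)
  img[, 1:10, 2] <- 0; img[, 1:10, 3] <- 0
  res <- red_pixel_area(img, pixel_size = 0.1)
  expect_equal(res$n_red, 100L)
  expect_equal(res$area_mm2, 100 * 0.1^2)
  # loop oracle on a seeded synthetic section (<= 64 x 64)
  sh <- synth_histology(shape = c(32, 32), seed = 5)
  res <- red_pixel_area(sh$image, pixel_size = 0.02)
  loop <- 0L
  for (i in 1:32) for (j in 1:32) {
    hsv <- grDevices::rgb2hsv(matrix(sh$image[i, j, ], 3, 1),
                              maxColorValue = 1)
    hue <- hsv[1] * 360
    if ((hue >= 340 || hue <= 20) && hsv[2] >= 0.3 && hsv[3] >= 0.2)
      loop <- loop + 1L
  }
  expect_equal(res$n_red, loop)
  # the planted red patch is exactly what is recovered
  expect_equal(res$red_mask, sh$red_mask)
  # ROI mask restricts the count
  half <- matrix(FALSE, 32, 32); half[1:16, ] <- TRUE
  res_half <- red_pixel_area(sh$image, mask = half, pixel_size = 0.02)
  expect_equal(res_half$n_red, sum(sh$red_mask[1:16, ]))
})
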