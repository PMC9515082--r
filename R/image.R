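#' 3-D image volume with physical voxel spacing
#'
#' Thin container for a contrast-enhanced T1-weighted volume: a 3-D
#' intensity array plus voxel spacing in mm. The protocol scan resolution
#' is 0.85 x 0.85 mm in-plane with 1 mm slice thickness; slices are the
#' third array axis. Physical coordinates are measured at voxel centers,
#' with voxel (1,1,1) centered at (0, 0, 0) mm.
#'
#' @param intensities 3-D numeric array.
#' @param spacing Numeric length-3 voxel spacing (dx, dy, dz) in mm,
#'   strictly positive. Default `c(0.85, 0.85, 1)`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(intensities, spacing = c(0.85, 0.85, 1)) {
  if (length(dim(intensities)) != 3)
    stop("intensities must be a 3-D array", call. = FALSE)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)", call. = FALSE)
  structure(list(intensities = intensities, spacing = as.numeric(spacing)),
            class = "image_volume")
}

#' Elliptical region-of-interest specification
#'
#' An elliptical ROI in the image plane, applied to a range of slices.
#' The protocol ROI has a 19 mm major axis and an 8 mm minor axis, placed
#' manually over the treated (or control) site.
#'
#' @param center Numeric length-2 physical center (x, y) in mm.
#' @param major_axis Full major axis length, mm. Default 19.
#' @param minor_axis Full minor axis length, mm. Default 8. Must satisfy
#'   `major_axis >= minor_axis > 0`.
#' @param orientation Rotation of the major axis, degrees
#'   counter-clockwise from the x axis. Default 0.
#' @param slices Integer slice indices the ROI applies to (1-based along
#'   the third axis); `NULL` means all slices.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center, major_axis = 19, minor_axis = 8,
                     orientation = 0, slices = NULL) {
  if (length(center) != 2)
    stop("center must be (x, y) in mm", call. = FALSE)
  if (!(major_axis >= minor_axis && minor_axis > 0))
    stop("need major_axis >= minor_axis > 0", call. = FALSE)
  structure(list(center = as.numeric(center), major_axis = major_axis,
                 minor_axis = minor_axis, orientation = orientation,
                 slices = if (is.null(slices)) NULL else as.integer(slices)),
            class = "roi_spec")
}

#' In-plane boolean mask of an elliptical ROI
#'
#' A voxel belongs to the ROI iff its center satisfies the rotated-ellipse
#' inequality `(u/a)^2 + (v/b)^2 <= 1` with semi-axes `a = major/2`,
#' `b = minor/2`, where (u, v) are the voxel-center coordinates in the
#' ellipse frame. Voxel centers sit at `(i-1)*dx, (j-1)*dy`.
#'
#' @param dim Integer length-2 (nx, ny) grid dimensions (or length-3; the
#'   third entry is ignored).
#' @param spacing Voxel spacing; only the first two entries are used.
#' @param roi A [roi_spec()].
#' @return Logical nx x ny matrix.
#' @export
ellipse_mask <- function(dim, spacing, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  nx <- dim[1]; ny <- dim[2]
  dx <- spacing[1]; dy <- spacing[2]
  a <- roi$major_axis / 2
  b <- roi$minor_axis / 2
  ext_x <- (nx - 1) * dx
  ext_y <- (ny - 1) * dy
  r <- max(a, b)
  if (roi$center[1] + r < 0 || roi$center[1] - r > ext_x ||
      roi$center[2] + r < 0 || roi$center[2] - r > ext_y)
    stop("ROI lies outside the image grid", call. = FALSE)
  x <- ((seq_len(nx) - 1) * dx) - roi$center[1]
  y <- ((seq_len(ny) - 1) * dy) - roi$center[2]
  th <- roi$orientation * pi / 180
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  u <- cos(th) * X + sin(th) * Y
  v <- -sin(th) * X + cos(th) * Y
  (u / a)^2 + (v / b)^2 <= 1
}

roi_slices <- function(roi, nz) {
  s <- if (is.null(roi$slices)) seq_len(nz) else roi$slices
  if (any(s < 1 | s > nz)) stop("ROI slice range outside volume", call. = FALSE)
  s
}

#' Blood-brain-barrier opening volume from a contrast-enhanced volume
#'
#' Implements the opening-volume readout: a voxel in the treated ROI
#' counts as BBB opening when its intensity exceeds the mean of the
#' non-treated (control) ROI by more than `k` standard deviations
#' (k = 3 in the protocol). Supra-threshold voxels are counted per slice
#' and converted to mm^3 with the voxel volume `dx*dy*dz`; the slice with
#' the maximum contrast enhancement represents the opening volume.
#'
#' @param volume An [image_volume()] (post-contrast scan).
#' @param treated_roi,control_roi [roi_spec()]s for the FUS-treated and
#'   non-treated sites. They must not overlap on shared slices.
#' @param k Threshold multiplier on the control-ROI standard deviation.
#'   Default 3.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return An object of class `opening_result`: `threshold`,
#'   `per_slice_volume` (mm^3, named by slice), `opening_volume` (mm^3,
#'   max over slices), `n_voxels_max_slice`, `max_slice`,
#'   `total_volume` (all-slice sum, reported for transparency),
#'   `control_mean`, `control_sd`.
#' @export
opening_volume <- function(volume, treated_roi, control_roi, k = 3,
                           sd_type = c("sample", "population")) {
  stopifnot(inherits(volume, "image_volume"))
  sd_type <- match.arg(sd_type)
  img <- volume$intensities
  d <- dim(img)
  tmask <- ellipse_mask(d, volume$spacing, treated_roi)
  cmask <- ellipse_mask(d, volume$spacing, control_roi)
  ts <- roi_slices(treated_roi, d[3])
  cs <- roi_slices(control_roi, d[3])
  if (any(tmask & cmask) && length(intersect(ts, cs)) > 0)
    stop("treated and control ROIs overlap", call. = FALSE)
  cvals <- unlist(lapply(cs, function(z) img[, , z][cmask]))
  if (length(cvals) == 0) stop("control ROI is empty", call. = FALSE)
  mu <- mean(cvals)
  sdv <- stats::sd(cvals)
  if (sd_type == "population")
    sdv <- sqrt(mean((cvals - mu)^2))
  thr <- mu + k * sdv
  vox_vol <- prod(volume$spacing)
  counts <- vapply(ts, function(z) sum(img[, , z][tmask] > thr), integer(1))
  per_slice <- counts * vox_vol
  names(per_slice) <- as.character(ts)
  imax <- which.max(per_slice)
  structure(list(
    threshold = thr,
    per_slice_volume = per_slice,
    opening_volume = if (length(per_slice)) max(per_slice) else 0,
    n_voxels_max_slice = counts[imax],
    max_slice = ts[imax],
    total_volume = sum(per_slice),
    control_mean = mu, control_sd = sdv
  ), class = "opening_result")
}

#' Synthetic contrast-enhanced T1-weighted volume
#'
#' Generates a Gaussian-background volume with an ellipsoidal
#' hyper-enhancing focus of stated contrast, emulating the extravasation
#' of MRI contrast agent after BBB opening. Optionally plants bright
#' "ventricle" voxels (a labelled box) that ROIs should avoid. Returns
#' the exact set of lesion voxels for recovery tests.
#'
#' @param shape Integer length-3 grid dimensions. Default `c(64, 64, 10)`.
#' @param spacing Voxel spacing in mm. Default `c(0.85, 0.85, 1)`.
#' @param bg_mean,bg_sd Background Gaussian intensity mean and sd.
#'   Defaults 100 and 5.
#' @param lesion_center Physical lesion center (x, y, z) in mm; default
#'   the grid center.
#' @param lesion_axes Full axes of the lesion ellipsoid (mm).
#'   Default `c(6, 4, 3)`.
#' @param contrast Intensity added inside the lesion. Must be >= 0;
#'   0 plants nothing.
#' @param ventricle Optional list `(lo, hi)` of 1-based voxel index
#'   corners of a box set to `bg_mean + 10 * bg_sd` and flagged in the
#'   returned `ventricle_mask`.
#' @param seed Integer seed; identical seeds give identical volumes.
#' @return A list: `volume` ([image_volume()]), `lesion_mask` (logical
#'   array of planted voxels), `ventricle_mask` (logical array),
#'   `params` (the arguments).
#' @export
synth_mri <- function(shape = c(64, 64, 10), spacing = c(0.85, 0.85, 1),
                      bg_mean = 100, bg_sd = 5,
                      lesion_center = NULL, lesion_axes = c(6, 4, 3),
                      contrast = 50, ventricle = NULL, seed = 1L) {
  if (contrast < 0) stop("lesion contrast must be >= 0", call. = FALSE)
  shape <- as.integer(shape)
  if (is.null(lesion_center))
    lesion_center <- (shape - 1) / 2 * spacing
  withr::local_seed(as.integer(seed))
  img <- array(stats::rnorm(prod(shape), bg_mean, bg_sd), dim = shape)
  x <- (seq_len(shape[1]) - 1) * spacing[1] - lesion_center[1]
  y <- (seq_len(shape[2]) - 1) * spacing[2] - lesion_center[2]
  z <- (seq_len(shape[3]) - 1) * spacing[3] - lesion_center[3]
  a <- lesion_axes / 2
  q <- outer(outer((x / a[1])^2, (y / a[2])^2, `+`), (z / a[3])^2, `+`)
  lesion <- q <= 1 & contrast > 0
  img[lesion] <- img[lesion] + contrast
  vmask <- array(FALSE, dim = shape)
  if (!is.null(ventricle)) {
    lo <- pmax(as.integer(ventricle$lo), 1L)
    hi <- pmin(as.integer(ventricle$hi), shape)
    vmask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    img[vmask] <- bg_mean + 10 * bg_sd
  }
  list(volume = image_volume(img, spacing), lesion_mask = lesion,
       ventricle_mask = vmask,
       params = list(shape = shape, spacing = spacing, bg_mean = bg_mean,
                     bg_sd = bg_sd, lesion_center = lesion_center,
                     lesion_axes = lesion_axes, contrast = contrast,
                     seed = as.integer(seed)))
}

#' Surrogate mapping from maintain-phase pressure to lesion extent
#'
#' Links the controller to the outcome quantifier for end-to-end tests:
#' the steady maintaining-phase pressure is mapped to the axes of the
#' hyper-enhancing lesion planted by [synth_mri()]. The mapping is a
#' simple affine surrogate (opening extent grows with the pressure
#' sustained above the dummy level), not a dosimetric model; it exists so
#' that a higher TCL produces a larger quantified opening volume, the
#' qualitative in vivo observation.
#'
#' @param mean_pressure Mean maintaining-phase pressure, MPa.
#' @param p0 Pressure at which the lesion extent vanishes, MPa.
#'   Default 0.3 (the dummy pressure: no opening without exceeding it).
#' @param gain Lesion diameter gained per MPa above `p0`, mm/MPa.
#' @return Numeric length-3 lesion axes (mm) for [synth_mri()]; all zero
#'   when `mean_pressure <= p0`.
#' @export
lesion_surrogate <- function(mean_pressure, p0 = 0.3, gain = 600) {
  d <- max(0, (mean_pressure - p0)) * gain
  c(d, 0.7 * d, 0.5 * d)
}

#' Red-pixel area of an H&E section
#'
#' Quantifies the area covered by red blood cells by summing all pixels
#' whose HSV hue falls in the red window, inside an optional ROI mask,
#' and converting the count to mm^2 with the pixel size. Hue is in
#' degrees in `[0, 360)`; the default red window is `[0, 20] U [340, 360)`
#' with configurable saturation/value floors to exclude washed-out and
#' near-black pixels.
#'
#' @param rgb_image Numeric h x w x 3 array with channels in `[0, 1]`.
#' @param mask Optional logical h x w ROI mask; `NULL` means the whole
#'   image.
#' @param pixel_size Pixel edge length in mm.
#' @param hue_window Numeric length-2 `(lo, hi)` in degrees; when
#'   `lo > hi` the window wraps around 0/360 (default `c(340, 20)`).
#' @param sat_min,val_min Saturation and value floors in `[0, 1]`.
#' @return A list: `area_mm2`, `n_red`, `n_roi`, and the logical
#'   `red_mask`.
#' @export
red_pixel_area <- function(rgb_image, mask = NULL, pixel_size = 0.01,
                           hue_window = c(340, 20),
                           sat_min = 0.3, val_min = 0.2) {
  d <- dim(rgb_image)
  if (length(d) != 3 || d[3] < 3)
    stop("rgb_image must have three channels", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  h <- d[1]; w <- d[2]
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  rgbm <- rbind(as.vector(rgb_image[, , 1]),
                as.vector(rgb_image[, , 2]),
                as.vector(rgb_image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  hue <- hsv[1, ] * 360
  red <- if (hue_window[1] > hue_window[2])
    (hue >= hue_window[1] | hue <= hue_window[2])
  else
    (hue >= hue_window[1] & hue <= hue_window[2])
  red <- red & hsv[2, ] >= sat_min & hsv[3, ] >= val_min
  red_mask <- matrix(red, h, w) & mask
  n_red <- sum(red_mask)
  list(area_mm2 = n_red * pixel_size^2, n_red = n_red, n_roi = sum(mask),
       red_mask = red_mask)
}

#' Synthetic H&E-style section with planted red pixels
#'
#' Builds an RGB image with an eosin-pink background and a planted patch
#' of blood-red pixels, returning the exact red mask for recovery tests.
#'
#' @param shape Integer (height, width). Default `c(64, 64)`.
#' @param red_mask Logical h x w matrix of pixels to paint blood-red;
#'   `NULL` plants a centered disc of radius `shape[1]/8` pixels.
#' @param seed Integer seed for the slight background texture.
#' @return A list: `image` (h x w x 3 array in `[0,1]`), `red_mask`.
#' @export
synth_histology <- function(shape = c(64, 64), red_mask = NULL, seed = 1L) {
  shape <- as.integer(shape)
  withr::local_seed(as.integer(seed))
  h <- shape[1]; w <- shape[2]
  if (is.null(red_mask)) {
    r <- h / 8
    cx <- (h + 1) / 2; cy <- (w + 1) / 2
    red_mask <- outer(seq_len(h), seq_len(w),
                      function(i, j) (i - cx)^2 + (j - cy)^2 <= r^2)
  }
  stopifnot(identical(dim(red_mask), c(h, w)))
  img <- array(0, dim = c(h, w, 3))
  # eosin-pink background: high value, low saturation, hue ~ 330 but
  # saturation below the default floor so it never counts as red
  tex <- matrix(stats::runif(h * w, -0.03, 0.03), h, w)
  img[, , 1] <- 0.95 + tex
  img[, , 2] <- 0.80 + tex
  img[, , 3] <- 0.85 + tex
  # blood red: hue 0, high saturation
  rch <- img[, , 1]; gch <- img[, , 2]; bch <- img[, , 3]
  rch[red_mask] <- 0.75
  gch[red_mask] <- 0.10
  bch[red_mask] <- 0.12
  img[, , 1] <- pmin(pmax(rch, 0), 1)
  img[, , 2] <- pmin(pmax(gch, 0), 1)
  img[, , 3] <- pmin(pmax(bch, 0), 1)
  list(image = img, red_mask = red_mask)
}

#' @export
print.opening_result <- function(x, ...) {
  cat("BBB-opening quantification\n")
  cat(sprintf("  threshold: %.4g (control mean %.4g + k * sd %.4g)\n",
              x$threshold, x$control_mean, x$control_sd))
  cat(sprintf("  opening volume (max slice %s): %.4g mm^3 (%d voxels)\n",
              x$max_slice, x$opening_volume, x$n_voxels_max_slice))
  cat(sprintf("  all-slice total: %.4g mm^3\n", x$total_volume))
  invisible(x)
}
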