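#' Triple-energy-window scheme
#'
#' Defines the Lu-177 acquisition windows: photopeak at 208 keV (15% width)
#' flanked by scatter windows at 170 keV (15%) and 240 keV (10%). Absolute
#' widths in keV are centre times fractional width.
#'
#' @param photopeak,lower_scatter,upper_scatter Length-2 numeric vectors
#'   `c(centre_keV, fractional_width)`.
#' @return Object of class `energy_windows` with absolute widths in keV.
#' @export
energy_windows <- function(photopeak = c(208, 0.15),
                           lower_scatter = c(170, 0.15),
                           upper_scatter = c(240, 0.10)) {
  win <- function(x, name) {
    if (length(x) != 2L || any(x <= 0)) {
      mdose_error("mdose_domain_error", sprintf("window `%s` must be c(centre_keV, fraction) with positive entries", name))
    }
    list(centre_kev = x[1L], fraction = x[2L], width_kev = x[1L] * x[2L])
  }
  structure(list(photopeak = win(photopeak, "photopeak"),
                 lower_scatter = win(lower_scatter, "lower_scatter"),
                 upper_scatter = win(upper_scatter, "upper_scatter")),
            class = "energy_windows")
}

#' Planar study (anterior/posterior, three energy windows)
#'
#' @param anterior,posterior Named lists with count matrices `peak`, `lower`,
#'   `upper`; all six matrices must share dimensions and be non-negative.
#' @param duration_s Acquisition duration (s).
#' @param pixel_mm Pixel size (mm).
#' @param time_h Acquisition time (h post-injection).
#' @return Object of class `planar_study`.
#' @export
planar_study <- function(anterior, posterior, duration_s, pixel_mm, time_h) {
  need <- c("peak", "lower", "upper")
  for (side in list(anterior = anterior, posterior = posterior)) {
    if (!all(need %in% names(side))) {
      mdose_error("mdose_domain_error", "each view needs `peak`, `lower` and `upper` count images")
    }
  }
  mats <- c(anterior[need], posterior[need])
  d <- dim(mats[[1L]])
  for (m in mats) {
    if (!identical(dim(m), d)) mdose_error("mdose_shape_error", "all six window images must share dimensions")
    if (any(m < 0)) mdose_error("mdose_domain_error", "count images must be non-negative")
  }
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(pixel_mm, "pixel_mm")
  structure(list(anterior = anterior[need], posterior = posterior[need],
                 duration_s = duration_s, pixel_mm = pixel_mm, time_h = time_h),
            class = "planar_study")
}

#' Triple-energy-window scatter correction
#'
#' Per pixel, the scatter estimate in the photopeak is the standard
#' trapezoidal TEW estimator
#' `(C_lower / w_lower + C_upper / w_upper) * w_peak / 2` with `w` the
#' absolute window widths in keV; the corrected image is the photopeak minus
#' this estimate, floored at zero.
#'
#' @param study A `planar_study`.
#' @param windows An `energy_windows` scheme.
#' @return List with scatter-corrected `anterior` and `posterior` photopeak
#'   count matrices.
#' @export
tew_scatter_correct <- function(study, windows = energy_windows()) {
  w_p <- windows$photopeak$width_kev
  w_l <- windows$lower_scatter$width_kev
  w_u <- windows$upper_scatter$width_kev
  corr <- function(side) {
    scatter <- (side$lower / w_l + side$upper / w_u) * w_p / 2
    pmax(side$peak - scatter, 0)
  }
  list(anterior = corr(study$anterior), posterior = corr(study$posterior))
}

#' Bilinear HU-to-mu calibration at 208 keV
#'
#' Fits two least-squares line segments, constrained to meet at HU = 0, to
#' attenuation-rod anchor points (Gammex-style phantom scan). Evaluation
#' clamps HU outside the supported range (default -688 to 1127), avoiding
#' extrapolation into the air/metal regimes.
#'
#' @param hu Hounsfield units of the anchor points; at least two points with
#'   HU < 0 and two with HU > 0.
#' @param mu Linear attenuation coefficients at 208 keV (1/mm).
#' @param hu_range Validity range for evaluation clamping.
#' @return Object of class `mu_calibration` (elements `mu0`, `slope_neg`,
#'   `slope_pos`, `hu_range`); evaluate with [predict.mu_calibration()].
#' @export
fit_mu_calibration <- function(hu, mu, hu_range = c(-688, 1127)) {
  if (sum(hu < 0) < 2L || sum(hu > 0) < 2L) {
    mdose_error("mdose_calibration_error",
                "need at least two anchor points on each side of HU = 0")
  }
  X <- cbind(1, pmin(hu, 0), pmax(hu, 0))
  cf <- stats::lm.fit(X, mu)$coefficients
  cal <- structure(list(mu0 = cf[[1L]], slope_neg = cf[[2L]], slope_pos = cf[[3L]],
                        hu_range = hu_range),
                   class = "mu_calibration")
  ends <- predict(cal, hu_range)
  if (any(c(ends, cal$mu0) < 0)) {
    mdose_error("mdose_calibration_error",
                "calibration yields negative mu within its stated HU range")
  }
  cal
}

#' @rdname fit_mu_calibration
#' @param object A `mu_calibration`.
#' @param newdata HU values to evaluate.
#' @param ... Unused.
#' @export
predict.mu_calibration <- function(object, newdata, ...) {
  h <- pmin(pmax(newdata, object$hu_range[1L]), object$hu_range[2L])
  object$mu0 + ifelse(h < 0, object$slope_neg * h, object$slope_pos * h)
}

# Separable discrete Gaussian convolution with zero padding; kernel
# truncated at +/- 6 sigma and normalised to unit sum.
gaussian_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(6 * sigma_px))
  x <- (-r):r
  k <- exp(-0.5 * (x / sigma_px)^2)
  k / sum(k)
}

convolve_dim1 <- function(m, k) {
  n <- nrow(m)
  r <- (length(k) - 1L) %/% 2L
  pad <- matrix(0, r, ncol(m))
  p <- rbind(pad, m, pad)
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(k)) {
    out <- out + k[i] * p[i:(i + n - 1L), , drop = FALSE]
  }
  out
}

#' Gaussian blur of a 2D map
#'
#' @param mat Numeric matrix.
#' @param sigma_px Gaussian sigma in pixels; `sigma_px = FWHM / 2.355 /
#'   pixel_mm` for a camera resolution given as FWHM in mm.
#' @return Blurred matrix (zero-padded boundaries).
#' @export
gaussian_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  k <- gaussian_kernel(sigma_px)
  t(convolve_dim1(t(convolve_dim1(mat, k)), k))
}

#' Projected attenuation map for conjugate-view correction
#'
#' Builds the 2D map of path-integrated attenuation (dimensionless optical
#' depth) by summing mu along the ventral axis of a CT-derived mu volume.
#' Pixels without CT coverage (arms, legs, part of the head in a torso CT)
#' take per-segment default optical depths; the finished map is blurred with
#' a Gaussian approximating the camera resolution (FWHM 11 mm by default for
#' a medium-energy collimator at 10 cm).
#'
#' @param mu_volume 3D array of mu values (1/mm), ventral axis = third
#'   dimension; `NA` planes mark pixels without CT coverage.
#' @param voxel_depth_mm Voxel extent along the ventral axis (mm).
#' @param segment_map Optional 2D character/factor matrix labelling every
#'   pixel without CT coverage.
#' @param segment_defaults Named numeric vector of default optical depths per
#'   segment label.
#' @param blur_fwhm_mm Gaussian blur FWHM in mm (0 disables).
#' @param pixel_mm Pixel size (mm), needed when blurring.
#' @return Object of class `mu_projection` with elements `optical_depth`
#'   (matrix) and `provenance` (`"ct"` or `"default"` per pixel).
#' @export
build_mu_projection <- function(mu_volume, voxel_depth_mm,
                                segment_map = NULL, segment_defaults = NULL,
                                blur_fwhm_mm = 0, pixel_mm = NULL) {
  assert_scalar_pos(voxel_depth_mm, "voxel_depth_mm")
  covered <- apply(!is.na(mu_volume), c(1, 2), any)
  depth <- apply(mu_volume, c(1, 2), function(v) sum(v, na.rm = TRUE)) * voxel_depth_mm
  provenance <- matrix("ct", nrow(depth), ncol(depth))
  if (any(!covered)) {
    if (is.null(segment_map)) {
      mdose_error("mdose_missing_segment",
                  "pixels without CT coverage but no segment map supplied")
    }
    labs <- unique(segment_map[!covered])
    labs <- labs[!is.na(labs)]
    missing <- setdiff(labs, names(segment_defaults))
    if (length(missing)) {
      mdose_error("mdose_missing_segment",
                  sprintf("no default optical depth for segment(s): %s",
                          paste(missing, collapse = ", ")),
                  segments = missing)
    }
    idx <- which(!covered)
    depth[idx] <- segment_defaults[segment_map[idx]]
    provenance[idx] <- "default"
  }
  if (any(depth < 0)) mdose_error("mdose_domain_error", "optical depths must be non-negative")
  if (blur_fwhm_mm > 0) {
    assert_scalar_pos(pixel_mm, "pixel_mm")
    depth <- gaussian_blur(depth, blur_fwhm_mm / 2.355 / pixel_mm)
  }
  structure(list(optical_depth = depth, provenance = provenance),
            class = "mu_projection")
}

#' Conjugate-view quantification
#'
#' Combines anterior and posterior scatter-corrected photopeak images by
#' geometric averaging and corrects for attenuation using the projected
#' optical depth: per pixel,
#' `rate = sqrt(ant * post) / duration / sqrt(exp(-optical_depth))`.
#' Pixels with zero counts in either view map to zero.
#'
#' @param ant,post Scatter-corrected count matrices.
#' @param mu_map A `mu_projection`, or an optical-depth matrix.
#' @param duration_s Acquisition duration (s).
#' @return Attenuation-corrected count-rate matrix (cps).
#' @export
conjugate_view <- function(ant, post, mu_map, duration_s) {
  od <- if (inherits(mu_map, "mu_projection")) mu_map$optical_depth else mu_map
  if (!identical(dim(ant), dim(post)) || !identical(dim(ant), dim(od))) {
    mdose_error("mdose_shape_error", "anterior, posterior and mu map must share dimensions")
  }
  if (any(ant < 0) || any(post < 0) || any(od < 0)) {
    mdose_error("mdose_domain_error", "counts and optical depths must be non-negative")
  }
  assert_scalar_pos(duration_s, "duration_s")
  sqrt(ant * post) / duration_s * exp(od / 2)
}

#' SPECT-anchored planar calibration
#'
#' One whole-body planar image per time point is calibrated against the
#' quantitative SPECT of the same session: the calibration factor (Bq/cps)
#' is the SPECT field-of-view activity divided by the count rate of the
#' planar region covering that field of view.
#'
#' @param planar_roi_rate Planar count rate over the SPECT field of view (cps).
#' @param spect_fov_activity SPECT field-of-view activity (Bq).
#' @param anchor_time_h Acquisition time (h p.i.), carried for bookkeeping.
#' @return Object of class `planar_calibration` with `factor_bq_per_cps`.
#' @export
calibrate_planar <- function(planar_roi_rate, spect_fov_activity, anchor_time_h = NA_real_) {
  if (!is.numeric(planar_roi_rate) || length(planar_roi_rate) != 1L || planar_roi_rate <= 0) {
    mdose_error("mdose_calibration_error", "planar ROI count rate must be positive")
  }
  if (!is.numeric(spect_fov_activity) || length(spect_fov_activity) != 1L || spect_fov_activity <= 0) {
    mdose_error("mdose_calibration_error", "SPECT field-of-view activity must be positive")
  }
  structure(list(factor_bq_per_cps = spect_fov_activity / planar_roi_rate,
                 anchor_time_h = anchor_time_h),
            class = "planar_calibration")
}

#' Percent-isocontour volume of interest
#'
#' Selects all voxels inside a bounding region whose value reaches a given
#' fraction of the regional maximum. Typical Lu-177 SPECT levels: 30-40% for
#' kidneys and spleen, 10-15% for a (metastasis-bearing) liver, 40% for
#' tumours.
#'
#' @param volume 3D activity (or concentration) array.
#' @param bounding_region Logical array of the same shape, non-empty.
#' @param percent Isocontour level as a fraction of the regional maximum,
#'   strictly between 0 and 1.
#' @param label Optional organ/tumour label carried on the mask.
#' @return Object of class `voi_mask`: logical array plus `label` and
#'   `percent` attributes.
#' @export
percent_isocontour_voi <- function(volume, bounding_region, percent, label = NULL) {
  if (!identical(dim(volume), dim(bounding_region))) {
    mdose_error("mdose_shape_error", "volume and bounding region must share dimensions")
  }
  assert_fraction(percent, "percent")
  if (!any(bounding_region)) {
    mdose_error("mdose_empty_region", "bounding region is empty")
  }
  m <- max(volume[bounding_region])
  if (m <= 0) {
    mdose_error("mdose_empty_region", "bounding region contains no signal")
  }
  mask <- bounding_region & (volume >= percent * m)
  structure(mask, label = label, percent = percent, class = c("voi_mask", class(mask)))
}

#' Activity in a volume of interest
#'
#' Sums a calibrated activity-concentration volume (Bq/ml) over a VOI mask.
#' An `exclude` mask (e.g. tumour VOIs inside the liver) is removed from the
#' VOI first, yielding the healthy-organ activity.
#'
#' @param volume 3D concentration array (Bq/ml).
#' @param voi Logical VOI array.
#' @param voxel_ml Voxel volume (ml).
#' @param exclude Optional logical array of voxels to remove from `voi`.
#' @return Total activity (Bq).
#' @export
voi_activity <- function(volume, voi, voxel_ml, exclude = NULL) {
  if (!identical(dim(volume), dim(voi))) {
    mdose_error("mdose_shape_error", "volume and VOI must share dimensions")
  }
  if (!is.null(exclude)) voi <- voi & !exclude
  if (!any(voi)) mdose_error("mdose_empty_region", "VOI is empty")
  assert_scalar_pos(voxel_ml, "voxel_ml")
  sum(volume[voi]) * voxel_ml
}
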