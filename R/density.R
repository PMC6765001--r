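#' Detect nuclei as 3D fluorescence maxima
#'
#' The H2b-reporter counting recipe: 3D median filter, rolling-ball
#' background subtraction (radius 25), outlier removal (radius 5, threshold
#' 1), intensity-band masking (the threshold step: voxels outside
#' \[threshold_min, threshold_max\] are zeroed), a second outlier-removal
#' pass, then 3D maximum finding with ellipsoidal exclusion radii and a
#' noise floor, one detection per nucleus. A capsule-proximal margin (low-y
#' side) can be excluded, since the capsule approximates a curved 2D sheet
#' rather than a 3D density.
#'
#' @param volume A [voxel_volume()] or 3D array (nuclei channel).
#' @param channel Channel name when multi-channel.
#' @param spacing_um Spacing override for bare arrays.
#' @param preprocess Apply the `nuclei_density` recipe first.
#' @param threshold_min,threshold_max Intensity band retained by the mask.
#' @param maxima_radii Exclusion radii in voxels, `c(z, y, x)`.
#' @param noise Noise floor for a maximum.
#' @param exclude_margin_um Capsule margin thickness (y < margin excluded).
#' @return A `nucleus_detections` tibble (`z`, `y`, `x` in µm, voxel
#'   indices, intensity) carrying the volume geometry as attributes.
#' @export
count_nuclei <- function(volume, channel = "nuclei", spacing_um = NULL,
                         preprocess = TRUE, threshold_min = 10,
                         threshold_max = 255,
                         maxima_radii = c(3L, 10L, 10L), noise = 10,
                         exclude_margin_um = 0) {
  arr <- get_channel(volume, if (is.array(volume)) NULL else channel)
  sp <- if (inherits(volume, "voxel_volume")) volume$spacing else spacing_um
  if (is.null(sp)) abort("supply `spacing_um` for a bare array.")
  d <- dim(arr)
  if (preprocess) arr <- preprocess_volume(arr, "nuclei_density")
  arr[arr < threshold_min | arr > threshold_max] <- 0
  arr <- array(cpp_remove_outliers(as.numeric(arr), d, 5L, 1), d)
  idx <- cpp_local_maxima(as.numeric(arr), d, maxima_radii[1],
                          maxima_radii[2], maxima_radii[3], max(noise, 1e-9))
  pos <- arrayInd(idx, d)
  out <- tibble(vz = pos[, 1], vy = pos[, 2], vx = pos[, 3],
                z = (pos[, 1] - 1) * sp[1], y = (pos[, 2] - 1) * sp[2],
                x = (pos[, 3] - 1) * sp[3],
                intensity = arr[idx])
  if (exclude_margin_um > 0) out <- out[out$y >= exclude_margin_um, ]
  structure(out, dim_vox = d, spacing = sp,
            exclude_margin_um = exclude_margin_um,
            class = c("nucleus_detections", class(out)))
}

#' Nuclei density over the counted volume
#'
#' @param dets A `nucleus_detections` from [count_nuclei()].
#' @param compartment Optional compartment label carried into the result.
#' @return A tibble: `count`, `volume_mm3` (margin excluded),
#'   `density_per_mm3`, `compartment`.
#' @export
nucleus_density <- function(dets, compartment = NA_character_) {
  d <- attr(dets, "dim_vox")
  sp <- attr(dets, "spacing")
  margin <- attr(dets, "exclude_margin_um")
  ext <- d * sp
  counted_um3 <- ext[1] * max(ext[2] - margin, 0) * ext[3]
  if (counted_um3 <= 0) abort("counted volume is zero.")
  vol_mm3 <- counted_um3 * 1e-9
  tibble(count = nrow(dets), volume_mm3 = vol_mm3,
         density_per_mm3 = nrow(dets) / vol_mm3,
         compartment = compartment)
}

#' Welch two-sample comparison of per-volume values
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return A tibble: `t`, `p`, `mean_a`, `mean_b`, `df`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("need >= 2 values per group.")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, p = 1, mean_a = mean(a), mean_b = mean(b),
                    df = NA_real_))
    }
    return(tibble(t = Inf * sign(mean(a) - mean(b)), p = 0,
                  mean_a = mean(a), mean_b = mean(b), df = NA_real_))
  }
  ht <- t.test(a, b, var.equal = FALSE)
  tibble(t = unname(ht$statistic), p = ht$p.value, mean_a = mean(a),
         mean_b = mean(b), df = unname(ht$parameter))
}

#' EdU labeling index over detected nuclei
#'
#' A nucleus counts as labeled when its mean EdU intensity within a ball
#' around its centre exceeds a threshold: adaptive (Otsu over the
#' per-nucleus means, guarded by an absolute noise floor so volumes without
#' positives are not split inside the noise band) or fixed.
#'
#' @param dets A `nucleus_detections`, or a data frame with µm columns
#'   `z`, `y`, `x` (e.g. ground-truth nucleus centres).
#' @param edu 3D EdU channel aligned to the detections' volume.
#' @param spacing_um Spacing override when `dets` carries none.
#' @param radius_um Sampling-ball radius around each centre.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Fixed threshold (required for `method = "fixed"`).
#' @param floor Minimum admissible threshold for the adaptive method.
#' @return A `labeling_index` tibble: `labeled`, `total`,
#'   `percent_labeled`, plus the threshold used.
#' @export
labeling_index <- function(dets, edu, spacing_um = NULL, radius_um = 3,
                           method = c("otsu", "fixed"), threshold = NULL,
                           floor = 25) {
  method <- match.arg(method)
  sp <- attr(dets, "spacing")
  if (is.null(sp)) sp <- spacing_um
  if (is.null(sp)) abort("supply `spacing_um`.")
  if (nrow(dets) == 0) abort("zero nuclei; labeling index undefined.")
  d <- dim(edu)
  means <- vapply(seq_len(nrow(dets)), function(i) {
    ctr <- c(dets$z[i], dets$y[i], dets$x[i])
    idx <- ellipsoid_indices(d, sp, ctr, rep(radius_um, 3))
    if (!length(idx)) return(0)
    mean(edu[idx])
  }, numeric(1))
  thr <- if (method == "fixed") {
    if (is.null(threshold)) abort("fixed method needs `threshold`.")
    threshold
  } else {
    ot <- tryCatch(otsu_threshold(means), error = function(e) floor)
    max(ot, floor)
  }
  labeled <- sum(means > thr)
  out <- tibble(labeled = labeled, total = length(means),
                percent_labeled = 100 * labeled / length(means),
                threshold = thr)
  structure(out, nucleus_means = means,
            class = c("labeling_index", class(out)))
}

#' Pool labeling indices over image volumes
#'
#' The headline statistic is pooled labeled nuclei over pooled total nuclei;
#' per-volume percentages are kept for dispersion.
#'
#' @param results A list of `labeling_index` results.
#' @return A tibble: pooled `labeled`, `total`, `percent_labeled`, and the
#'   per-volume percentages as a list column.
#' @export
pool_labeling_index <- function(results) {
  lab <- sum(vapply(results, function(r) r$labeled, numeric(1)))
  tot <- sum(vapply(results, function(r) r$total, numeric(1)))
  per <- vapply(results, function(r) r$percent_labeled, numeric(1))
  tibble(labeled = lab, total = tot, percent_labeled = 100 * lab / tot,
         per_volume = list(per))
}
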