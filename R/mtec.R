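#' Segment a field of mTEC by seeded 3D watershed
#'
#' The medullary compartment is densely packed, so single cells are isolated
#' by: preprocessing (background subtraction, median and minimum filtering),
#' Gaussian-smoothed local-maxima seed detection, a seeded watershed on the
#' lightly smoothed image with seed and image intensity thresholds,
#' edge-object exclusion, a lower volume filter (an absolute µm³ cutoff, or
#' the mean nucleus volume + 3 sd when a nuclei channel is supplied —
#' objects smaller than a nucleus cannot be whole cells), and an upper
#' filter dropping objects in the top 5% of feret diameter, compactness or
#' volume:ellipsoid ratio (likely fusions of several cells).
#'
#' @param volume A [voxel_volume()] or 3D array (one reporter color).
#' @param channel Reporter channel name when multi-channel.
#' @param nuclei Optional nuclei channel (name or array) used to derive the
#'   lower volume filter.
#' @param spacing_um Spacing override for bare arrays.
#' @param preprocess Apply the `mtec_segmentation` recipe first.
#' @param rollball_radius Background-subtraction ball radius in pixels; it
#'   must be wider than the largest cell, so the default (40) suits the
#'   synthetic 0.5 µm xy spacing.
#' @param seed_radii_um Exclusion radii (z, y, x, µm) for seed maxima.
#' @param seed_sigma_um Gaussian sigma (µm) of the seed-detection smoothing.
#' @param seed_noise Noise floor for a local maximum on the smoothed seed
#'   image.
#' @param seeds_threshold Minimum watershed-image intensity at a seed; dimmer
#'   seeds are discarded.
#' @param image_threshold Watershed image threshold; dimmer voxels stay
#'   background.
#' @param min_volume_um3 Lower volume filter when no nuclei channel is given.
#' @param top_fraction Upper-tail fraction excluded per shape parameter.
#' @return A list of class `mtec_segmentation`: `objects`
#'   ([labeled_objects()], relabeled after filtering) and `shapes` (tibble
#'   of descriptors for the surviving objects).
#' @export
segment_mtec_field <- function(volume, channel = NULL, nuclei = NULL,
                               spacing_um = NULL, preprocess = TRUE,
                               rollball_radius = 40,
                               seed_radii_um = c(4, 5, 5),
                               seed_sigma_um = 2, seed_noise = 30,
                               seeds_threshold = 50, image_threshold = 20,
                               min_volume_um3 = 532, top_fraction = 0.05) {
  arr <- get_channel(volume, channel)
  sp <- if (inherits(volume, "voxel_volume")) volume$spacing else spacing_um
  if (is.null(sp)) abort("supply `spacing_um` for a bare array.")
  d <- dim(arr)
  work <- if (preprocess) {
    a <- contrast_stretch(arr, 0.01)
    a <- array(cpp_rollball_subtract(as.numeric(a), d, rollball_radius,
                                     TRUE), d)
    array(cpp_median3d(as.numeric(a), d, 1L, 2L, 2L), d)
  } else arr
  eroded <- array(cpp_min3d(as.numeric(work), d, 1L, 2L, 2L), d)
  sig <- seed_sigma_um / sp
  seed_img <- array(cpp_gauss3d(as.numeric(eroded), d, sig[1], sig[2],
                                sig[3]), d)
  rv <- pmax(round(seed_radii_um / sp), 1L)
  seeds <- cpp_local_maxima(as.numeric(seed_img), d, rv[1], rv[2], rv[3],
                            seed_noise)
  ws_img <- array(cpp_gauss3d(as.numeric(work), d, 0.5, 0.5, 0.5), d)
  seeds <- seeds[ws_img[seeds] >= seeds_threshold]
  empty <- function() {
    warn("no watershed seeds found; empty segmentation.")
    list(objects = labeled_objects(array(0L, d), sp),
         shapes = measure_shape(labeled_objects(array(1L, c(1, 1, 1)), sp))[0, ])
  }
  if (!length(seeds)) return(structure(empty(), class = "mtec_segmentation"))
  lab <- array(cpp_watershed_seeded(as.numeric(ws_img), d, seeds,
                                    seq_along(seeds), image_threshold), d)
  obj <- labeled_objects(lab, sp)
  keep <- which(!obj$edge_touching & obj$sizes > 0)
  # lower volume filter
  vox_vol <- prod(sp)
  lower <- min_volume_um3
  if (!is.null(nuclei)) {
    nuc <- get_channel(volume, nuclei)
    nthr <- otsu_threshold(as.numeric(nuc))
    nlab <- array(cpp_label3d(as.logical(nuc > nthr), d, 26L), d)
    nsz <- tabulate(nlab[nlab > 0]) * vox_vol
    nsz <- nsz[nsz > 20]  # discard speckle
    if (length(nsz) >= 2) lower <- mean(nsz) + 3 * sd(nsz)
  }
  keep <- keep[obj$sizes[keep] * vox_vol > lower]
  if (!length(keep)) return(structure(empty(), class = "mtec_segmentation"))
  relabel <- function(lab_arr, old_ids) {
    lut <- integer(max(lab_arr) + 1L)
    lut[old_ids + 1L] <- seq_along(old_ids)
    array(lut[lab_arr + 1L], d)
  }
  obj2 <- labeled_objects(relabel(lab, keep), sp)
  shapes <- measure_shape(obj2)
  # upper filter: extreme in ANY of the three discriminatory parameters
  up <- function(v) v > quantile(v, 1 - top_fraction, na.rm = TRUE)
  drop <- up(shapes$feret_um) | up(shapes$compactness) |
    up(dplyr::coalesce(shapes$volume_ellipsoid_ratio, 0))
  final_ids <- shapes$label[!drop]
  obj3 <- labeled_objects(relabel(obj2$labels, final_ids), sp)
  shapes <- shapes[!drop, , drop = FALSE]
  shapes$label <- seq_len(nrow(shapes))
  structure(list(objects = obj3, shapes = shapes),
            class = "mtec_segmentation")
}

#' @export
print.mtec_segmentation <- function(x, ...) {
  cat("<mtec_segmentation> ", x$objects$n, " cells retained\n", sep = "")
  invisible(x)
}

#' @method tidy mtec_segmentation
#' @export
tidy.mtec_segmentation <- function(x, ...) as_tibble(x$shapes)
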