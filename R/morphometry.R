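#' Preprocess a volume with a named filter recipe
#'
#' Applies, in recipe order, the image-cleaning chain used before
#' segmentation or counting: percentile contrast stretch, rolling-ball (or
#' sliding-paraboloid) background subtraction, 3D median filtering,
#' median-based outlier removal, and 3D minimum filtering. The three recipes
#' correspond to single-cTEC reporter cleanup (`ctec_confetti`), mTEC
#' watershed preparation (`mtec_segmentation`) and nuclei counting
#' (`nuclei_density`), with the radii each uses.
#'
#' @param volume A [voxel_volume()] or 3D array.
#' @param recipe One of `"ctec_confetti"`, `"mtec_segmentation"`,
#'   `"nuclei_density"`.
#' @param channel Channel name when `volume` is multi-channel.
#' @param saturation Fraction of pixels saturated by the contrast stretch.
#' @param rollball_radius Override for the background-subtraction radius in
#'   pixels (recipe default when `NULL`: 10 for `mtec_segmentation`, 25 for
#'   `nuclei_density`). The rolling ball must be wider than the largest
#'   foreground object, so match this to the pixel size of the data.
#' @return The filtered 3D array.
#' @export
preprocess_volume <- function(volume, recipe = c("ctec_confetti",
                                                 "mtec_segmentation",
                                                 "nuclei_density"),
                              channel = NULL, saturation = 0.01,
                              rollball_radius = NULL) {
  recipe <- match.arg(recipe)
  arr <- get_channel(volume, channel)
  d <- dim(arr)
  if (recipe == "ctec_confetti") {
    arr <- contrast_stretch(arr, saturation)
    arr <- array(cpp_median3d(as.numeric(arr), d, 1L, 2L, 2L), d)
  } else if (recipe == "mtec_segmentation") {
    r <- rollball_radius %||% 10
    arr <- contrast_stretch(arr, saturation)
    arr <- array(cpp_rollball_subtract(as.numeric(arr), d, r, TRUE), d)
    arr <- array(cpp_median3d(as.numeric(arr), d, 1L, 2L, 2L), d)
    arr <- array(cpp_min3d(as.numeric(arr), d, 1L, 2L, 2L), d)
  } else {
    r <- rollball_radius %||% 25
    arr <- array(cpp_median3d(as.numeric(arr), d, 2L, 2L, 2L), d)
    arr <- array(cpp_rollball_subtract(as.numeric(arr), d, r, FALSE), d)
    arr <- array(cpp_remove_outliers(as.numeric(arr), d, 5L, 1), d)
  }
  arr
}

# percentile contrast stretch onto [0, 255]; flat images pass through
contrast_stretch <- function(arr, saturation = 0.01) {
  qs <- quantile(arr, c(saturation / 2, 1 - saturation / 2), names = FALSE)
  if (qs[2] <= qs[1]) return(arr)
  pmin(pmax((arr - qs[1]) / (qs[2] - qs[1]) * 255, 0), 255)
}

# Otsu threshold on a numeric vector (256-bin histogram)
otsu_threshold <- function(x, levels = 256L) {
  r <- range(x)
  if (r[2] <= r[1]) abort("cannot threshold a constant image.")
  breaks <- seq(r[1], r[2], length.out = levels + 1)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = levels)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Labeled 3D objects
#'
#' @param labels Integer array (0 = background), labels contiguous from 1.
#' @param spacing_um Voxel spacing (z, y, x) in µm.
#' @return A `labeled_objects` with per-object voxel counts and
#'   edge-touching flags.
#' @export
labeled_objects <- function(labels, spacing_um) {
  n <- max(labels)
  sizes <- tabulate(labels[labels > 0], nbins = n)
  d <- dim(labels)
  edge <- logical(n)
  border <- c(labels[c(1, d[1]), , ], labels[, c(1, d[2]), ],
              labels[, , c(1, d[3])])
  hit <- unique(border[border > 0])
  edge[hit] <- TRUE
  structure(list(labels = labels, spacing = as.numeric(spacing_um),
                 n = n, sizes = sizes, edge_touching = edge),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat("<labeled_objects> ", x$n, " objects; ", sum(x$edge_touching),
      " touching the volume edge\n", sep = "")
  invisible(x)
}

#' Segment one reporter-labeled cell from a single-color channel
#'
#' Automatic global (Otsu) thresholding followed by retention of the largest
#' 26-connected foreground component (the purify step); lymphocyte voids
#' remain background inside the mask so they can be counted afterwards.
#'
#' @param volume A [voxel_volume()] or 3D array, already preprocessed.
#' @param channel Channel name when multi-channel.
#' @param spacing_um Spacing override when `volume` is a bare array.
#' @return A [labeled_objects()] holding exactly one object.
#' @export
segment_single_cell <- function(volume, channel = NULL, spacing_um = NULL) {
  arr <- get_channel(volume, channel)
  sp <- if (inherits(volume, "voxel_volume")) volume$spacing else spacing_um
  if (is.null(sp)) abort("supply `spacing_um` for a bare array.")
  if (all(arr == 0)) abort("channel is empty; nothing to segment.")
  thr <- otsu_threshold(as.numeric(arr))
  mask <- arr > thr
  if (!any(mask)) abort("empty foreground after thresholding.")
  lab <- array(cpp_label3d(as.logical(mask), dim(arr), 26L), dim(arr))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  out <- array(0L, dim(arr))
  out[lab == keep] <- 1L
  labeled_objects(out, sp)
}

#' Segment well-separated nuclei by global thresholding
#'
#' Otsu threshold on the (raw) nuclei channel followed by 26-connected
#' labelling, edge exclusion and a speckle volume filter. Suited to shape
#' measurement of H2b-reporter nuclei, which are well separated; for dense
#' counting use [count_nuclei()] instead.
#'
#' @param volume A [voxel_volume()] or 3D array.
#' @param channel Channel name when multi-channel.
#' @param spacing_um Spacing override for bare arrays.
#' @param min_volume_um3 Minimum object volume retained.
#' @param exclude_edges Drop objects touching the volume border.
#' @return A [labeled_objects()] of the retained nuclei, relabeled 1..n.
#' @export
segment_nuclei <- function(volume, channel = "nuclei", spacing_um = NULL,
                           min_volume_um3 = 50, exclude_edges = TRUE) {
  arr <- get_channel(volume, if (is.array(volume)) NULL else channel)
  sp <- if (inherits(volume, "voxel_volume")) volume$spacing else spacing_um
  if (is.null(sp)) abort("supply `spacing_um` for a bare array.")
  thr <- otsu_threshold(as.numeric(arr))
  lab <- array(cpp_label3d(as.logical(arr > thr), dim(arr), 26L), dim(arr))
  obj <- labeled_objects(lab, sp)
  keep <- which(obj$sizes * prod(sp) >= min_volume_um3)
  if (exclude_edges) keep <- setdiff(keep, which(obj$edge_touching))
  lut <- integer(obj$n + 1L)
  lut[keep + 1L] <- seq_along(keep)
  labeled_objects(array(lut[lab + 1L], dim(arr)), sp)
}

object_mask <- function(obj, id = 1L) {
  if (inherits(obj, "labeled_objects")) obj$labels == id else obj
}

#' Count background cavities fully enclosed by an object
#'
#' Labels the background 6-connected (the complement of the 26-connected
#' foreground) and counts the components that do not touch the volume
#' border — in a cTEC these are the lymphocyte-filled voids of the
#' intracellular labyrinth.
#'
#' @param obj A [labeled_objects()] or logical mask array.
#' @param id Object label when `obj` is labeled.
#' @return Integer void count.
#' @export
count_voids <- function(obj, id = 1L) {
  mask <- object_mask(obj, id)
  d <- dim(mask)
  bg <- array(cpp_label3d(as.logical(!mask), d, 6L), d)
  border <- unique(c(bg[c(1, d[1]), , ], bg[, c(1, d[2]), ],
                     bg[, , c(1, d[3])]))
  border <- border[border > 0]
  sum(!seq_len(max(bg, 0)) %in% border)
}

# boundary voxels: foreground with at least one 6-neighbour outside the mask
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  full <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(inner & !full, arr.ind = TRUE)
}

# convex-hull candidate points (physical µm, voxel centres): the union over
# z-slices of each slice's 2D hull vertices contains every 3D hull vertex
hull_candidates <- function(mask, spacing) {
  bv <- boundary_voxels(mask)
  if (nrow(bv) == 0) return(matrix(numeric(0), 0, 3))
  pts <- cbind((bv[, 1] - 1) * spacing[1], (bv[, 2] - 1) * spacing[2],
               (bv[, 3] - 1) * spacing[3])
  keep <- lapply(split(seq_len(nrow(pts)), bv[, 1]), function(ii) {
    if (length(ii) <= 3) return(ii)
    sub <- pts[ii, c(2, 3), drop = FALSE]
    h <- tryCatch(grDevices::chull(sub[, 1], sub[, 2]),
                  error = function(e) seq_along(ii))
    ii[h]
  })
  pts[unlist(keep, use.names = FALSE), , drop = FALSE]
}

# Khachiyan's algorithm for the minimum-volume enclosing ellipsoid
mvee <- function(pts, tol = 1e-3, max_iter = 1000L) {
  n <- nrow(pts)
  d <- ncol(pts)
  Q <- t(cbind(pts, 1))
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))
    M <- colSums(Q * solve(X, Q))
    j <- which.max(M)
    step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    if (!is.finite(step) || step < tol) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  center <- drop(crossprod(pts, u))
  S <- crossprod(pts, u * pts) - tcrossprod(center)
  A <- tryCatch(solve(S) / d, error = function(e) NULL)
  if (is.null(A)) return(list(center = center, A = NULL, volume = NA_real_))
  detA <- det(A)
  vol <- if (detA > 0) (4 / 3) * pi / sqrt(detA) else NA_real_
  list(center = center, A = A, volume = vol)
}

#' Measure 3D shape descriptors of a segmented object
#'
#' Volume is voxel count times voxel volume; surface area counts exposed
#' voxel faces in physical units (exact for axis-aligned shapes); feret
#' diameter is the maximum pairwise distance over convex-hull vertices of
#' the surface voxel centres; compactness is the surface-area-to-volume
#' ratio; the volume:ellipsoid ratio divides the object volume by the volume
#' of the minimum-volume enclosing ellipsoid (Khachiyan iteration) of the
#' hull vertices.
#'
#' @param obj A [labeled_objects()] or logical mask.
#' @param spacing_um Spacing override for bare masks.
#' @param id Object label to measure (default all labels when `obj` is
#'   labeled with several).
#' @return A tibble, one row per object: `label`, `n_voxels`, `volume_um3`,
#'   `surface_area_um2`, `feret_um`, `compactness`,
#'   `volume_ellipsoid_ratio`, `edge_touching`.
#' @export
measure_shape <- function(obj, spacing_um = NULL, id = NULL) {
  if (inherits(obj, "labeled_objects")) {
    sp <- obj$spacing
    ids <- if (is.null(id)) seq_len(obj$n) else id
    fg <- which(obj$labels > 0)
    pos_all <- arrayInd(fg, dim(obj$labels))
    by_label <- split(seq_along(fg), obj$labels[fg])
    get_pos <- function(i) pos_all[by_label[[as.character(i)]], , drop = FALSE]
    full_dim <- dim(obj$labels)
  } else {
    sp <- spacing_um
    if (is.null(sp)) abort("supply `spacing_um` for a bare mask.")
    ids <- 1L
    get_pos <- function(i) which(obj, arr.ind = TRUE)
    full_dim <- dim(obj)
  }
  rows <- lapply(ids, function(i) {
    w <- get_pos(i)
    nv <- nrow(w)
    if (nv == 0) abort(paste0("object ", i, " is empty."))
    # crop to the bounding box (1-voxel pad) for tractability
    lo <- pmax(apply(w, 2, min) - 1L, 1L)
    hi <- pmin(apply(w, 2, max) + 1L, full_dim)
    sub <- array(FALSE, hi - lo + 1L)
    sub[cbind(w[, 1] - lo[1] + 1L, w[, 2] - lo[2] + 1L,
              w[, 3] - lo[3] + 1L)] <- TRUE
    vox_vol <- prod(sp)
    vol <- nv * vox_vol
    sa <- exposed_face_area(sub, sp)
    pts <- hull_candidates(sub, sp)
    feret <- if (nrow(pts) >= 2) cpp_max_pairwise_dist(pts) else 0
    ver <- NA_real_
    if (nrow(pts) >= 4) {
      mv <- mvee(pts, tol = 1e-3)
      if (is.finite(mv$volume) && mv$volume > 0) ver <- vol / mv$volume
    }
    edge <- if (inherits(obj, "labeled_objects")) obj$edge_touching[i] else NA
    tibble(label = i, n_voxels = nv, volume_um3 = vol,
           surface_area_um2 = sa, feret_um = feret,
           compactness = sa / vol, volume_ellipsoid_ratio = ver,
           edge_touching = edge)
  })
  dplyr::bind_rows(rows)
}

# exposed voxel-face area in µm² (anisotropic spacing)
exposed_face_area <- function(mask, sp) {
  d <- dim(mask)
  count_axis <- function(axis) {
    perm <- switch(axis, `1` = mask, `2` = aperm(mask, c(2, 1, 3)),
                   `3` = aperm(mask, c(3, 1, 2)))
    n <- dim(perm)[1]
    m <- matrix(perm, nrow = n)
    up <- rbind(FALSE, m[-n, , drop = FALSE])
    dn <- rbind(m[-1, , drop = FALSE], FALSE)
    sum(m & !up) + sum(m & !dn)
  }
  areas <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  count_axis(1) * areas[1] + count_axis(2) * areas[2] +
    count_axis(3) * areas[3]
}
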