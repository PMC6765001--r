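#' Configuration for the 3D volume simulator
#'
#' Describes a synthetic multi-channel confocal-like volume of thymic tissue.
#' Phenotypes set morphology defaults: `young_cortex` renders a cTEC as a
#' slightly flattened ovoid (long axis 75 +/- 10 µm, radially aligned along
#' y) whose interior labyrinth is modelled as 20-30 spherical lymphocyte
#' voids; `aged_cortex` contracts the cell and adds broad-spectrum
#' autofluorescent age pigment; `regenerated_cortex` restores size with high
#' cell-to-cell variability; `medulla` packs hundreds of filled ovoid mTEC,
#' one nucleus each.
#'
#' @param phenotype One of `"young_cortex"`, `"aged_cortex"`,
#'   `"regenerated_cortex"`, `"medulla"`.
#' @param shape_vox Volume dimensions in voxels (z, y, x); phenotype default
#'   when `NULL`.
#' @param spacing_um Voxel spacing in µm (z, y, x).
#' @param n_cells Number of cells; phenotype default when `NULL`.
#' @param ctec_long_axis_um Length-2 `c(mean, sd)` of the cTEC long axis in
#'   µm; phenotype default when `NULL`.
#' @param voids_per_ctec Integer range (length 2) of lymphocyte voids carved
#'   into each cTEC.
#' @param lymphocytes_per_void Integer range of lymphoid cells recorded per
#'   void.
#' @param nucleus_feret_um Long axis (feret diameter) of a TEC nucleus in µm.
#' @param edu_rate Fraction of TEC nuclei labelled by the S-phase pulse;
#'   phenotype default when `NULL` (young cortex 1/1024, medulla 4.5%).
#' @param pigment_density Age-pigment bodies per µm³; phenotype default when
#'   `NULL` (zero in young tissue).
#' @param capsule_margin_um Thickness of the capsule-proximal margin (low-y
#'   side) recorded for exclusion from density counting.
#' @param channels Channels to render, a subset of
#'   `c("reporter", "nuclei", "edu", "autofluor")`.
#' @param seed Integer seed.
#' @return A `volume_sim_config`.
#' @export
volume_sim_config <- function(phenotype = c("young_cortex", "aged_cortex",
                                            "regenerated_cortex", "medulla"),
                              shape_vox = NULL,
                              spacing_um = c(1, 0.5, 0.5),
                              n_cells = NULL,
                              ctec_long_axis_um = NULL,
                              voids_per_ctec = c(20L, 30L),
                              lymphocytes_per_void = c(2L, 10L),
                              nucleus_feret_um = 11,
                              edu_rate = NULL,
                              pigment_density = NULL,
                              capsule_margin_um = 0,
                              channels = c("reporter", "nuclei", "edu",
                                           "autofluor"),
                              seed = 1L) {
  phenotype <- match.arg(phenotype)
  defaults <- list(
    young_cortex = list(shape = c(56L, 224L, 144L), n_cells = 1L,
                        long = c(75, 10), edu = 1 / 1024, pigment = 0),
    aged_cortex = list(shape = c(48L, 176L, 112L), n_cells = 1L,
                       long = c(45, 8), edu = 0, pigment = 5e-5),
    regenerated_cortex = list(shape = c(56L, 224L, 144L), n_cells = 1L,
                              long = c(70, 18), edu = 0, pigment = 5e-5),
    medulla = list(shape = c(64L, 248L, 248L), n_cells = NA_integer_,
                   long = c(75, 10), edu = 0.045, pigment = 0)
  )[[phenotype]]
  if (is.null(shape_vox)) shape_vox <- defaults$shape
  if (is.null(n_cells)) n_cells <- defaults$n_cells
  if (is.null(ctec_long_axis_um)) ctec_long_axis_um <- defaults$long
  if (is.null(edu_rate)) edu_rate <- defaults$edu
  if (is.null(pigment_density)) pigment_density <- defaults$pigment
  shape_vox <- as.integer(shape_vox)
  if (length(shape_vox) != 3 || any(shape_vox < 1)) {
    abort("`shape_vox` must be 3 positive integers (z, y, x).")
  }
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3 || any(spacing_um <= 0)) {
    abort("`spacing_um` must be 3 positive values.")
  }
  if (diff(voids_per_ctec) < 0 || diff(lymphocytes_per_void) < 0) {
    abort("ranges must be nonempty (min <= max).")
  }
  if (edu_rate < 0 || edu_rate > 1) abort("`edu_rate` must be in [0,1].")
  if (pigment_density < 0) abort("`pigment_density` must be >= 0.")
  if (capsule_margin_um < 0) abort("`capsule_margin_um` must be >= 0.")
  channels <- match.arg(channels, c("reporter", "nuclei", "edu", "autofluor"),
                        several.ok = TRUE)
  structure(list(phenotype = phenotype, shape = shape_vox,
                 spacing = spacing_um, n_cells = n_cells,
                 ctec_long_axis = ctec_long_axis_um,
                 voids_per_ctec = as.integer(voids_per_ctec),
                 lymphocytes_per_void = as.integer(lymphocytes_per_void),
                 nucleus_feret = nucleus_feret_um,
                 edu_rate = edu_rate, pigment_density = pigment_density,
                 capsule_margin = capsule_margin_um,
                 channels = channels, seed = as.integer(seed)),
            class = "volume_sim_config")
}

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
rand_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qrd)
  R <- R %*% diag(sign(diag(qr.R(qrd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# support radius of a rotated ellipsoid along unit direction u
support_radius <- function(semi, R, u) {
  sqrt(sum((semi * drop(crossprod(R, u)))^2))
}

# linear voxel indices of an (optionally rotated) ellipsoid; with
# `profile = TRUE` also the normalized squared radius q in [0, 1] per voxel
ellipsoid_indices <- function(dim, spacing, center, semi, R = NULL,
                              profile = FALSE) {
  reach <- if (is.null(R)) semi else {
    vapply(1:3, function(k) {
      u <- c(0, 0, 0)
      u[k] <- 1
      support_radius(semi, R, u)
    }, numeric(1))
  }
  rng <- lapply(1:3, function(k) {
    co <- axis_coords(dim[k], spacing[k])
    which(co >= center[k] - reach[k] - spacing[k] &
          co <= center[k] + reach[k] + spacing[k])
  })
  if (any(lengths(rng) == 0)) return(integer(0))
  dz <- axis_coords(dim[1], spacing[1])[rng[[1]]] - center[1]
  dy <- axis_coords(dim[2], spacing[2])[rng[[2]]] - center[2]
  dx <- axis_coords(dim[3], spacing[3])[rng[[3]]] - center[3]
  nz <- length(dz)
  ny <- length(dy)
  nx <- length(dx)
  Z <- rep(dz, times = ny * nx)
  Y <- rep(rep(dy, each = nz), times = nx)
  X <- rep(dx, each = nz * ny)
  if (is.null(R)) {
    q <- (Z / semi[1])^2 + (Y / semi[2])^2 + (X / semi[3])^2
  } else {
    U1 <- R[1, 1] * Z + R[2, 1] * Y + R[3, 1] * X
    U2 <- R[1, 2] * Z + R[2, 2] * Y + R[3, 2] * X
    U3 <- R[1, 3] * Z + R[2, 3] * Y + R[3, 3] * X
    q <- (U1 / semi[1])^2 + (U2 / semi[2])^2 + (U3 / semi[3])^2
  }
  inside <- q <= 1
  if (!any(inside)) {
    return(if (profile) list(idx = integer(0), q = numeric(0))
           else integer(0))
  }
  iz <- rep(rng[[1]], times = ny * nx)[inside]
  iy <- rep(rep(rng[[2]], each = nz), times = nx)[inside]
  ix <- rep(rng[[3]], each = nz * ny)[inside]
  idx <- iz + dim[1] * (iy - 1L) + dim[1] * dim[2] * (ix - 1L)
  if (profile) list(idx = idx, q = q[inside]) else idx
}

# draw a nucleus with a centre-bright chromatin profile (one clean maximum)
render_nucleus <- function(target, dim3, sp, center, semi, R = NULL,
                           peak = 185) {
  pr <- ellipsoid_indices(dim3, sp, center, semi, R, profile = TRUE)
  target[pr$idx] <- target[pr$idx] + peak * (1 - 0.45 * pr$q)
  target
}

# uniform point in a sphere
runif_sphere <- function(radius) {
  repeat {
    p <- runif(3, -1, 1)
    if (sum(p^2) <= 1) return(p * radius)
  }
}

# one cTEC: ovoid shell geometry with interior lymphocyte voids.
# A draw from the long-axis law that cannot fit the canvas is redrawn a few
# times (truncating a negligible upper tail) before becoming an error.
make_ctec <- function(cfg, extent, center, cell_id, wall, void_scale = 1) {
  L <- NA_real_
  semi <- NULL
  for (try in 1:8) {
    L <- max(rnorm(1, cfg$ctec_long_axis[1], cfg$ctec_long_axis[2]), 30)
    semi <- c(0.24, 0.5, 0.30) * L  # long axis along y (radial)
    if (all(center - semi >= 0.5) && all(center + semi <= extent - 0.5)) {
      break
    }
    semi <- NULL
  }
  if (is.null(semi)) {
    abort(paste0("cTEC with long axis ", round(L, 1),
                 " um does not fit in the volume; enlarge `shape_vox`."))
  }
  nuc_semi <- c(cfg$nucleus_feret / 2 * 0.73, cfg$nucleus_feret / 2,
                cfg$nucleus_feret / 2 * 0.73)[c(1, 2, 3)]
  nuc_semi <- c(nuc_semi[1], nuc_semi[2], nuc_semi[1])
  n_void <- sample(seq(cfg$voids_per_ctec[1], cfg$voids_per_ctec[2]), 1)
  rs <- runif(n_void, 3.0, 4.2) * void_scale * L / 75
  centers <- matrix(NA_real_, 0, 3)
  radii <- numeric(0)
  for (i in seq_len(n_void)) {
    placed <- FALSE
    for (att in seq_len(400)) {
      lim <- semi - rs[i] - wall
      if (any(lim <= 0)) break
      s <- runif_sphere(1)
      d <- s * lim
      # clearance from the nucleus (which sits at the cell centre)
      if (sqrt(sum(d^2)) < rs[i] + max(nuc_semi) + 1.5) next
      ok <- TRUE
      if (nrow(centers)) {
        dd <- sqrt(rowSums(sweep(centers, 2, d)^2))
        if (any(dd < radii + rs[i] + 1.0)) ok <- FALSE
      }
      if (ok) {
        centers <- rbind(centers, d)
        radii <- c(radii, rs[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) next
  }
  lymph <- list()
  for (v in seq_along(radii)) {
    k <- sample(seq(cfg$lymphocytes_per_void[1],
                    cfg$lymphocytes_per_void[2]), 1)
    pts <- t(vapply(seq_len(k), function(i) {
      runif_sphere(max(radii[v] - 0.3, 0.2))
    }, numeric(3)))
    lymph[[v]] <- tibble(cell = cell_id, void = v,
                         z = center[1] + centers[v, 1] + pts[, 1],
                         y = center[2] + centers[v, 2] + pts[, 2],
                         x = center[3] + centers[v, 3] + pts[, 3])
  }
  list(cell = cell_id, L = L, semi = semi, center = center,
       nuc_semi = nuc_semi,
       voids = if (length(radii)) {
         tibble(cell = cell_id, void = seq_along(radii),
                z = center[1] + centers[, 1], y = center[2] + centers[, 2],
                x = center[3] + centers[, 3], radius = radii)
       } else {
         tibble(cell = integer(), void = integer(), z = numeric(),
                y = numeric(), x = numeric(), radius = numeric())
       },
       lymphocytes = dplyr::bind_rows(lymph))
}

#' Simulate a multi-channel 3D tissue volume with ground truth
#'
#' Renders the configured phenotype into reporter, nuclei (H2b-style), EdU
#' and autofluorescence channels, on the 8-bit intensity scale, with
#' moderate Gaussian noise on the reporter and nuclei channels. The EdU and
#' autofluorescence channels carry signal only where biology puts it, so a
#' zero labeling rate or zero pigment density yields an identically zero
#' channel. Ground truth records per-cell geometry, the cell label mask,
#' void and enclosed-lymphocyte bookkeeping, nucleus centres and EdU labels.
#'
#' @param config A [volume_sim_config()].
#' @return A list of class `volume_simulation`: `volume` (a
#'   [voxel_volume()]) and `truth`.
#' @export
simulate_volume <- function(config) {
  stopifnot(inherits(config, "volume_sim_config"))
  set.seed(config$seed)
  dim3 <- config$shape
  sp <- config$spacing
  extent <- (dim3 - 1) * sp
  nvox <- prod(dim3)
  zero <- function() array(0, dim3)
  reporter <- zero()
  nuclei <- zero()
  edu <- zero()
  autofluor <- zero()
  labels <- array(0L, dim3)

  cells <- list()
  nuclei_tb <- list()
  voids_tb <- list()
  lymph_tb <- list()

  cortex <- config$phenotype != "medulla"
  render_reporter <- "reporter" %in% config$channels

  if (cortex && render_reporter) {
    n_cells <- max(config$n_cells, 1L)
    wall <- if (config$phenotype == "aged_cortex") 1.6 else 2.0
    for (ci in seq_len(n_cells)) {
      center <- if (n_cells == 1) extent / 2 else {
        c(runif(1, extent[1] * 0.3, extent[1] * 0.7),
          runif(1, extent[2] * 0.35, extent[2] * 0.65),
          runif(1, extent[3] * 0.3, extent[3] * 0.7))
      }
      ct <- make_ctec(config, extent, center, ci, wall)
      body <- ellipsoid_indices(dim3, sp, ct$center, ct$semi)
      mask <- logical(nvox)
      mask[body] <- TRUE
      if (nrow(ct$voids)) {
        for (v in seq_len(nrow(ct$voids))) {
          vi <- ellipsoid_indices(dim3, sp,
                                  c(ct$voids$z[v], ct$voids$y[v],
                                    ct$voids$x[v]),
                                  rep(ct$voids$radius[v], 3))
          mask[vi] <- FALSE
        }
      }
      idx <- which(mask)
      reporter[idx] <- reporter[idx] + 175 + runif(1, -15, 15)
      labels[idx] <- ci
      # nucleus at the cell centre, long axis radial
      nuclei <- render_nucleus(nuclei, dim3, sp, ct$center, ct$nuc_semi)
      labeled <- runif(1) < config$edu_rate
      if (labeled) {
        edu <- render_nucleus(edu, dim3, sp, ct$center, ct$nuc_semi,
                              peak = 170)
      }
      cells[[ci]] <- tibble(cell = ci, z = ct$center[1], y = ct$center[2],
                            x = ct$center[3], long_axis_um = ct$L,
                            semi_z = ct$semi[1], semi_y = ct$semi[2],
                            semi_x = ct$semi[3],
                            void_count = nrow(ct$voids),
                            enclosed_lymphocytes = nrow(ct$lymphocytes))
      nuclei_tb[[ci]] <- tibble(cell = ci, z = ct$center[1],
                                y = ct$center[2], x = ct$center[3],
                                feret_um = config$nucleus_feret,
                                edu = labeled)
      voids_tb[[ci]] <- ct$voids
      lymph_tb[[ci]] <- ct$lymphocytes
    }
  } else if (cortex) {
    # nuclei-only cortex volume (density / labeling-index studies)
    n_cells <- config$n_cells
    nuc_semi <- c(config$nucleus_feret / 2 * 0.73, config$nucleus_feret / 2,
                  config$nucleus_feret / 2 * 0.73)
    centers <- matrix(NA_real_, 0, 3)
    for (ci in seq_len(n_cells)) {
      placed <- FALSE
      for (att in seq_len(2000)) {
        cand <- c(runif(1, 6, extent[1] - 6), runif(1, 6, extent[2] - 6),
                  runif(1, 6, extent[3] - 6))
        if (!nrow(centers) ||
            all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= 12)) {
          centers <- rbind(centers, cand)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0("could not place ", n_cells,
                     " nuclei without overlap; enlarge the volume."))
      }
      R <- rand_rotation()
      nuclei <- render_nucleus(nuclei, dim3, sp, cand, nuc_semi, R)
      labeled <- runif(1) < config$edu_rate
      if (labeled) edu <- render_nucleus(edu, dim3, sp, cand, nuc_semi, R,
                                         peak = 170)
      cells[[ci]] <- tibble(cell = ci, z = cand[1], y = cand[2], x = cand[3],
                            long_axis_um = NA_real_, semi_z = NA_real_,
                            semi_y = NA_real_, semi_x = NA_real_,
                            void_count = NA_integer_,
                            enclosed_lymphocytes = NA_integer_)
      nuclei_tb[[ci]] <- tibble(cell = ci, z = cand[1], y = cand[2],
                                x = cand[3],
                                feret_um = config$nucleus_feret, edu = labeled)
    }
  } else {
    # medulla: jittered-grid packing of filled ovoid mTEC, one nucleus each
    pitch <- 15
    margin <- 8
    if (any(extent < 2 * margin)) {
      abort("volume too small for the medulla packing grid; enlarge it.")
    }
    gz <- seq(margin, extent[1] - margin, by = pitch)
    gy <- seq(margin, extent[2] - margin, by = pitch)
    gx <- seq(margin, extent[3] - margin, by = pitch)
    slots <- expand.grid(z = gz, y = gy, x = gx)
    capacity <- nrow(slots)
    n_cells <- config$n_cells
    if (is.na(n_cells)) n_cells <- capacity
    if (n_cells > capacity) {
      abort(paste0(n_cells, " cells exceed the ", capacity,
                   " that fit this volume at the packing pitch."))
    }
    slots <- slots[sample(capacity, n_cells), , drop = FALSE]
    placed_centers <- matrix(NA_real_, 0, 3)
    placed_semi <- list()
    placed_R <- list()
    for (ci in seq_len(n_cells)) {
      base <- as.numeric(slots[ci, ])
      ok <- FALSE
      for (att in seq_len(15)) {
        jit <- runif(3, -1.2, 1.2)
        cand <- base + jit
        R <- rand_rotation()
        semi <- c(runif(1, 6.2, 7.0), runif(1, 5.0, 6.2), runif(1, 5.0, 6.2))
        clear <- TRUE
        if (nrow(placed_centers)) {
          dd <- sweep(placed_centers, 2, cand)
          dist <- sqrt(rowSums(dd^2))
          near <- which(dist < 18)
          for (j in near) {
            u <- -dd[j, ] / dist[j]
            if (support_radius(semi, R, u) +
                support_radius(placed_semi[[j]], placed_R[[j]], -u) + 0.8 >
                dist[j]) {
              clear <- FALSE
              break
            }
          }
        }
        if (clear) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {  # shrink until it fits its slot unjittered
        cand <- base
        R <- diag(3)
        semi <- c(6.2, 5.0, 5.0)
      }
      placed_centers <- rbind(placed_centers, cand)
      placed_semi[[ci]] <- semi
      placed_R[[ci]] <- R
      idx <- ellipsoid_indices(dim3, sp, cand, semi, R)
      if (render_reporter) {
        reporter[idx] <- reporter[idx] + 170 + runif(1, -20, 20)
      }
      labels[idx] <- ci
      nuc_semi <- c(min(config$nucleus_feret / 2, semi[1] - 0.5), 4, 4)
      nuclei <- render_nucleus(nuclei, dim3, sp, cand, nuc_semi, R)
      labeled <- runif(1) < config$edu_rate
      if (labeled) edu <- render_nucleus(edu, dim3, sp, cand, nuc_semi, R,
                                         peak = 170)
      cells[[ci]] <- tibble(cell = ci, z = cand[1], y = cand[2], x = cand[3],
                            long_axis_um = 2 * semi[1], semi_z = semi[1],
                            semi_y = semi[2], semi_x = semi[3],
                            void_count = 0L, enclosed_lymphocytes = 0L)
      nuclei_tb[[ci]] <- tibble(cell = ci, z = cand[1], y = cand[2],
                                x = cand[3], feret_um = 2 * nuc_semi[1],
                                edu = labeled)
    }
  }

  # age pigment: broad-spectrum emitters polluting reporter and autofluor
  pigment <- tibble(z = numeric(), y = numeric(), x = numeric(),
                    radius = numeric())
  n_pig <- if (config$pigment_density > 0) {
    stats::rpois(1, config$pigment_density * prod(extent))
  } else 0
  if (n_pig > 0) {
    for (i in seq_len(n_pig)) {
      pc <- c(runif(1, 1, extent[1] - 1), runif(1, 1, extent[2] - 1),
              runif(1, 1, extent[3] - 1))
      pr <- runif(1, 0.8, 1.8)
      pidx <- ellipsoid_indices(dim3, sp, pc, rep(pr, 3))
      autofluor[pidx] <- autofluor[pidx] + 150
      reporter[pidx] <- reporter[pidx] + 150
      pigment <- dplyr::bind_rows(pigment,
                                  tibble(z = pc[1], y = pc[2], x = pc[3],
                                         radius = pr))
    }
  }

  # read noise + background on the imaging channels that always carry light
  reporter <- pmin(pmax(reporter + rnorm(nvox, 6, 3), 0), 255)
  nuclei <- pmin(pmax(nuclei + rnorm(nvox, 6, 3), 0), 255)
  edu <- pmin(edu, 255)
  autofluor <- pmin(autofluor, 255)

  chans <- list(reporter = reporter, nuclei = nuclei, edu = edu,
                autofluor = autofluor)[config$channels]
  truth <- list(
    cells = dplyr::bind_rows(cells),
    nuclei = dplyr::bind_rows(nuclei_tb),
    voids = dplyr::bind_rows(voids_tb),
    lymphocytes = dplyr::bind_rows(lymph_tb),
    pigment = pigment,
    cell_labels = labels,
    capsule_margin_um = config$capsule_margin,
    phenotype = config$phenotype
  )
  structure(list(volume = voxel_volume(chans, sp), truth = truth,
                 config = config),
            class = "volume_simulation")
}

#' @export
print.volume_simulation <- function(x, ...) {
  cat("<volume_simulation> ", x$truth$phenotype, ", ",
      nrow(x$truth$cells), " cells, ",
      paste(x$config$shape, collapse = "x"), " voxels, seed=",
      x$config$seed, "\n", sep = "")
  invisible(x)
}
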