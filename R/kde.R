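#' Kernel density estimate of a shape distribution with probability regions
#'
#' Gaussian product-kernel KDE over selected shape descriptors with
#' Silverman plug-in bandwidths, plus highest-density regions: the 10%
#' region is the densest region containing 10% of probability mass (the
#' "dark" limit), the 90% region contains 90% (the "light" limit); the 10%
#' region is nested inside the 90% one by construction.
#'
#' @param data Data frame of per-object descriptors (e.g. the `shapes` table
#'   from [segment_mtec_field()]).
#' @param dims Column names to use as KDE dimensions.
#' @param n_grid Grid points per dimension for the density evaluation.
#' @param mass Probability masses of the reported regions.
#' @return A `shape_kde`: points, bandwidths, grid axes, density array,
#'   per-point densities, HDR thresholds (`levels`), HDR grid masks, and the
#'   number of density modes found on the grid.
#' @export
kde_shape_distribution <- function(data,
                                   dims = c("feret_um", "compactness",
                                            "volume_ellipsoid_ratio"),
                                   n_grid = 24L, mass = c(0.10, 0.90)) {
  miss <- setdiff(dims, names(data))
  if (length(miss)) {
    abort(paste0("missing descriptor columns: ", paste(miss, collapse = ", ")))
  }
  X <- as.matrix(data[, dims, drop = FALSE])
  X <- X[complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  d <- ncol(X)
  if (n < d + 1) abort("need more observations than dimensions.")
  if (n < 50) warn("KDE on fewer than 50 observations is unstable.")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) abort("a descriptor has zero variance.")
  h <- sds * (4 / ((d + 2) * n))^(1 / (d + 4))
  axes <- lapply(seq_len(d), function(k) {
    seq(min(X[, k]) - 3 * h[k], max(X[, k]) + 3 * h[k], length.out = n_grid)
  })
  names(axes) <- dims
  grid <- as.matrix(expand.grid(axes))
  dens <- cpp_kde_eval(X, grid, h)
  dens_arr <- array(dens, rep(n_grid, d))
  point_dens <- cpp_kde_eval(X, X, h)
  levels <- vapply(mass, function(m) {
    quantile(point_dens, 1 - m, names = FALSE)
  }, numeric(1))
  names(levels) <- paste0("p", round(100 * mass))
  masks <- lapply(levels, function(lv) dens_arr >= lv)
  structure(list(points = X, dims = dims, h = h, axes = axes,
                 density = dens_arr, point_density = point_dens,
                 levels = levels, masks = masks,
                 n_modes = count_grid_modes(dens_arr)),
            class = "shape_kde")
}

# local maxima of the gridded density (full diagonal neighbourhood),
# above 5% of the peak to ignore numerical ripple
count_grid_modes <- function(dens) {
  d <- dim(dens)
  nd <- length(d)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  idx <- which(dens >= 0.05 * max(dens))
  pos <- arrayInd(idx, d)
  is_mode <- vapply(seq_along(idx), function(i) {
    for (r in seq_len(nrow(offs))) {
      p <- pos[i, ] + offs[r, ]
      if (any(p < 1 | p > d)) next
      if (dens[matrix(p, 1)] > dens[idx[i]]) return(FALSE)
    }
    TRUE
  }, logical(1))
  sum(is_mode)
}

#' @export
print.shape_kde <- function(x, ...) {
  cat("<shape_kde> ", nrow(x$points), " objects over ",
      paste(x$dims, collapse = ", "), "; ", x$n_modes, " mode(s)\n",
      sep = "")
  invisible(x)
}

#' @method glance shape_kde
#' @export
glance.shape_kde <- function(x, ...) {
  tibble(n = nrow(x$points), n_dims = length(x$dims), n_modes = x$n_modes,
         frac_in_p90 = mean(x$point_density >= x$levels[["p90"]]),
         frac_in_p10 = mean(x$point_density >= x$levels[["p10"]]))
}

#' Plot the first two KDE dimensions with probability limits
#'
#' @param object A `shape_kde`.
#' @param ... Unused.
#' @return A ggplot with filled density and the 10%/90% HDR contours.
#' @method autoplot shape_kde
#' @export
autoplot.shape_kde <- function(object, ...) {
  d2 <- apply(object$density, c(1, 2), sum)
  df <- expand.grid(x = object$axes[[1]], y = object$axes[[2]])
  df$z <- as.vector(d2)
  pts <- as.data.frame(object$points[, 1:2, drop = FALSE])
  names(pts) <- c("px", "py")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$z), color = "white",
                          bins = 6) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$px, y = .data$py),
                        inherit.aes = FALSE, size = 0.3, alpha = 0.4) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = object$dims[1], y = object$dims[2], fill = "density") +
    ggplot2::theme_minimal()
}
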