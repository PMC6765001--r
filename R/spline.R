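#' Robust natural-cubic-spline smoothing of regeneration time courses
#'
#' Fits, per gene, a natural cubic spline over the integer-day axis with
#' interior knots at days 6 and 17 (boundary knots at the observed day range),
#' by iteratively reweighted least squares with Hampel weights computed from
#' MAD-scaled residuals. Replicates enter as independent observations. The
#' `"young"` condition is not part of the spline axis and is ignored here.
#'
#' @param object A [signal_matrix()] (one fraction; every gene is fitted), or
#'   a numeric vector of observation days for the default method.
#' @param ... Passed to methods.
#' @return A `spline_fit` with per-gene coefficients, fitted values on the
#'   unique observed days, robustness weights per observation, and the basis
#'   definition needed for prediction at new days.
#' @export
fit_robust_spline <- function(object, ...) UseMethod("fit_robust_spline")

hampel_weights <- function(u, a = 2, b = 4, c = 8) {
  w <- rep(1, length(u))
  mid <- u > a & u <= b
  out <- u > b & u <= c
  w[mid] <- a / u[mid]
  w[out] <- a * (c - u[out]) / (u[out] * (c - b))
  w[u > c] <- 0
  w
}

spline_basis <- function(days, knots, boundary) {
  inner <- knots[knots > boundary[1] & knots < boundary[2]]
  cbind(`(Intercept)` = 1,
        splines::ns(days, knots = inner, Boundary.knots = boundary))
}

fit_one_series <- function(X, y, tol = 1e-8, max_iter = 50L) {
  w <- rep(1, length(y))
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fit <- lm.wfit(X, y, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol) {
      converged <- TRUE
      break
    }
    r <- y - drop(X %*% beta)
    s <- mad(r)
    if (s < 1e-12) {
      converged <- TRUE
      break
    }
    w <- hampel_weights(abs(r) / s)
    if (all(w == 0)) w <- rep(1, length(y))  # degenerate; fall back to OLS
  }
  list(beta = beta, w = w, converged = converged)
}

#' @rdname fit_robust_spline
#' @param values For the default method, observed values aligned to `object`
#'   (the observation days).
#' @param knots Interior knot positions (days).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum IRLS iterations.
#' @export
fit_robust_spline.default <- function(object, values, knots = c(6, 17),
                                      tol = 1e-8, max_iter = 50L, ...) {
  days <- as.numeric(object)
  stopifnot(length(days) == length(values))
  vals <- matrix(values, nrow = 1, dimnames = list("series", NULL))
  fit_spline_matrix(vals, days, knots, tol, max_iter)
}

#' @rdname fit_robust_spline
#' @export
fit_robust_spline.signal_matrix <- function(object, knots = c(6, 17),
                                            tol = 1e-8, max_iter = 50L, ...) {
  dn <- day_numeric(object$samples$day)
  keep <- !is.na(dn)
  fit_spline_matrix(object$values[, keep, drop = FALSE], dn[keep], knots,
                    tol, max_iter)
}

fit_spline_matrix <- function(vals, days, knots, tol, max_iter) {
  udays <- sort(unique(days))
  boundary <- range(days)
  X <- spline_basis(days, knots, boundary)
  if (length(udays) < ncol(X)) {
    abort(paste0("rank deficiency: ", length(udays),
                 " distinct days for a basis of dimension ", ncol(X), "."))
  }
  ng <- nrow(vals)
  Xu <- spline_basis(udays, knots, boundary)
  coefs <- matrix(NA_real_, ng, ncol(X),
                  dimnames = list(rownames(vals), colnames(X)))
  weights <- matrix(NA_real_, ng, length(days),
                    dimnames = list(rownames(vals), NULL))
  converged <- logical(ng)
  for (i in seq_len(ng)) {
    f <- fit_one_series(X, vals[i, ], tol, max_iter)
    coefs[i, ] <- f$beta
    weights[i, ] <- f$w
    converged[i] <- f$converged
  }
  fitted <- coefs %*% t(Xu)
  colnames(fitted) <- as.character(udays)
  structure(list(days = udays, obs_days = days, fitted = fitted,
                 coefficients = coefs, weights = weights,
                 converged = converged, knots = knots, boundary = boundary),
            class = "spline_fit")
}

#' Evaluate a fitted spline at arbitrary days
#'
#' @param object A `spline_fit`.
#' @param days Days at which to evaluate (within or outside the fitted range;
#'   natural splines extrapolate linearly).
#' @param ... Unused.
#' @return Genes x days matrix of fitted values.
#' @export
predict.spline_fit <- function(object, days = object$days, ...) {
  Xu <- spline_basis(as.numeric(days), object$knots, object$boundary)
  out <- object$coefficients %*% t(Xu)
  colnames(out) <- as.character(days)
  out
}

#' @export
print.spline_fit <- function(x, ...) {
  cat("<spline_fit> ", nrow(x$coefficients), " series, ",
      length(x$days), " days, interior knots at ",
      paste(x$knots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy spline_fit
#' @export
tidy.spline_fit <- function(x, ...) {
  tibble(gene = rep(rownames(x$fitted), times = ncol(x$fitted)),
         day = rep(colnames(x$fitted), each = nrow(x$fitted)),
         fitted = as.vector(x$fitted))
}

#' @method glance spline_fit
#' @export
glance.spline_fit <- function(x, ...) {
  tibble(n_series = nrow(x$coefficients),
         n_days = length(x$days),
         n_converged = sum(x$converged),
         min_weight = min(x$weights),
         mean_weight = mean(x$weights))
}
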