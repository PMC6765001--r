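#' Expressed-gene filter from detection calls and chip medians
#'
#' A gene is kept when, at any timepoint with three or more independent
#' replicates, either a strict majority of its detection calls are non-absent
#' (Present or Marginal), or a strict majority of its signal values lie above
#' the corresponding chip medians. This is the permissive
#' (minimum-false-negative) definition of "expressed in the thymus".
#'
#' @param tissue A [signal_matrix()] of tissue samples.
#' @param calls Character matrix of P/M/A detection calls, aligned to the
#'   genes and samples of `tissue`.
#' @param min_replicates Minimum replicates for a timepoint to be eligible.
#' @return Character vector of expressed gene identifiers.
#' @export
detection_filter <- function(tissue, calls, min_replicates = 3L) {
  stopifnot(inherits(tissue, "signal_matrix"))
  if (!identical(dim(calls), dim(tissue$values))) {
    abort("`calls` must be aligned to `tissue` (same genes x samples).")
  }
  bad <- setdiff(unique(as.vector(calls)), c("P", "M", "A"))
  if (length(bad)) {
    abort(paste0("detection calls must be P, M or A; found: ",
                 paste(bad, collapse = ", ")))
  }
  day <- tissue$samples$day
  tab <- table(day)
  eligible <- names(tab)[tab >= min_replicates]
  if (!length(eligible)) {
    abort(paste0("no timepoint has >= ", min_replicates, " replicates; ",
                 "supply more replicates or lower `min_replicates`."))
  }
  keep <- rep(FALSE, nrow(tissue$values))
  for (d in eligible) {
    idx <- which(day == d)
    n <- length(idx)
    sub_calls <- calls[, idx, drop = FALSE]
    nonabsent <- rowSums(sub_calls != "A") > n / 2
    sub_sig <- tissue$values[, idx, drop = FALSE]
    meds <- apply(tissue$values[, idx, drop = FALSE], 2, median)
    above <- rowSums(sweep(sub_sig, 2, meds, `>`)) > n / 2
    keep <- keep | nonabsent | above
  }
  rownames(tissue$values)[keep]
}

#' Estimate the per-day lymphoid proportion from marker genes
#'
#' For lymphoid-specific genes the tissue signal is purely the lymphoid
#' admixture, so the tissue:lymphoid signal ratio equals the lymphoid
#' proportion p. p is estimated per day as the mean of that ratio over a
#' curated marker list, computed on spline-fitted values for the integer-day
#' axis and on measured replicate means for the `"young"` condition.
#'
#' @param tissue,lymphoid [signal_matrix()]s sharing the gene index.
#' @param markers Character vector of lymphoid-specific gene identifiers.
#' @param knots Interior knots for the spline fits.
#' @return A tibble with columns `day` and `p`, p clamped to (0, 1 - 1e-6].
#' @export
estimate_lymphoid_proportion <- function(tissue, lymphoid, markers,
                                         knots = c(6, 17)) {
  if (length(markers) == 0) abort("marker list is empty.")
  markers <- unique(as.character(markers))
  missing_m <- setdiff(markers, intersect(rownames(tissue$values),
                                          rownames(lymphoid$values)))
  if (length(missing_m)) {
    abort(paste0("markers absent from the matrices: ",
                 paste(head(missing_m, 5), collapse = ", ")))
  }
  t_sub <- sm_subset_genes(tissue, markers)
  l_sub <- sm_subset_genes(lymphoid, markers)
  tf <- fit_robust_spline(t_sub, knots = knots)
  lf <- fit_robust_spline(l_sub, knots = knots)
  zero_l <- rownames(lf$fitted)[apply(lf$fitted <= 0, 1, any)]
  if (length(zero_l)) {
    warn(paste0("excluding markers with nonpositive lymphoid signal: ",
                paste(zero_l, collapse = ", ")))
    ok <- setdiff(markers, zero_l)
    if (!length(ok)) abort("no markers left after zero-signal exclusion.")
    tf$fitted <- tf$fitted[ok, , drop = FALSE]
    lf$fitted <- lf$fitted[ok, , drop = FALSE]
    markers <- ok
  }
  ratio <- tf$fitted / lf$fitted
  p <- colMeans(ratio)
  out <- tibble(day = colnames(tf$fitted), p = unname(p))
  # young condition: measured replicate means in place of spline fits
  young_t <- tissue$samples$day == "young"
  young_l <- lymphoid$samples$day == "young"
  if (any(young_t) && any(young_l)) {
    mt <- rowMeans(tissue$values[markers, young_t, drop = FALSE])
    ml <- rowMeans(lymphoid$values[markers, young_l, drop = FALSE])
    ok <- ml > 0
    if (!all(ok)) {
      warn("excluding markers with zero young lymphoid signal.")
    }
    out <- dplyr::bind_rows(
      tibble(day = "young", p = mean(mt[ok] / ml[ok])), out)
  }
  out$p <- pmin(pmax(out$p, 1e-9), 1 - 1e-6)
  out
}

as_p_vector <- function(p) {
  if (is.data.frame(p)) setNames(p$p, p$day) else p
}

#' Deconvolve stromal expression from the tissue/lymphoid mixture
#'
#' Applies, per day, `stromal = (tissue - lymphoid * p) / (1 - p)` — the
#' inversion of the mixture `tissue = p * lymphoid + (1 - p) * stromal`.
#' Negative results are floored at zero and counted.
#'
#' @param tissue_fit,lymphoid_fit `spline_fit` objects, or plain
#'   genes x days matrices (e.g. measured young values), sharing gene index
#'   and day columns.
#' @param p Lymphoid proportion per day: the tibble returned by
#'   [estimate_lymphoid_proportion()] or a named numeric vector.
#' @return A `stromal_estimate` with the stromal genes x days matrix, the
#'   proportions used, and the count of floored negatives.
#' @export
deconvolve_stromal <- function(tissue_fit, lymphoid_fit, p) {
  Tm <- if (inherits(tissue_fit, "spline_fit")) tissue_fit$fitted else tissue_fit
  Lm <- if (inherits(lymphoid_fit, "spline_fit")) lymphoid_fit$fitted else lymphoid_fit
  if (!identical(rownames(Tm), rownames(Lm))) {
    abort("tissue and lymphoid fits must share the same gene index.")
  }
  days <- intersect(colnames(Tm), colnames(Lm))
  if (!length(days)) abort("no shared days between the fits.")
  pv <- as_p_vector(p)
  if (!all(days %in% names(pv))) {
    abort(paste0("`p` missing for days: ",
                 paste(setdiff(days, names(pv)), collapse = ", ")))
  }
  pv <- pv[days]
  if (any(pv >= 1)) {
    abort(paste0("lymphoid proportion >= 1 at day ",
                 paste(days[pv >= 1], collapse = ", "),
                 "; deconvolution undefined."))
  }
  S <- sweep(Tm[, days, drop = FALSE] -
               sweep(Lm[, days, drop = FALSE], 2, pv, `*`),
             2, 1 - pv, `/`)
  n_neg <- sum(S < 0)
  S[S < 0] <- 0
  structure(list(values = S, p = pv, n_floored = n_neg,
                 renormalized = FALSE),
            class = "stromal_estimate")
}

#' @export
print.stromal_estimate <- function(x, ...) {
  cat("<stromal_estimate> ", nrow(x$values), " genes x ", ncol(x$values),
      " days; ", x$n_floored, " negative values floored",
      if (x$renormalized) "; quantile-renormalized", "\n", sep = "")
  invisible(x)
}

#' @method tidy stromal_estimate
#' @export
tidy.stromal_estimate <- function(x, ...) {
  tibble(gene = rep(rownames(x$values), times = ncol(x$values)),
         day = rep(colnames(x$values), each = nrow(x$values)),
         stromal = as.vector(x$values))
}

#' @method glance stromal_estimate
#' @export
glance.stromal_estimate <- function(x, ...) {
  tibble(n_genes = nrow(x$values), n_days = ncol(x$values),
         n_floored = x$n_floored, renormalized = x$renormalized,
         p_min = min(x$p), p_max = max(x$p))
}

#' Quantile-renormalize stromal estimates to a per-day reference
#'
#' Per day, maps the ranked stromal values onto the sorted reference (tissue
#' spline-fit) values, so the output multiset per day equals the reference
#' multiset. Ties are broken by stable gene order.
#'
#' @param stromal A `stromal_estimate`.
#' @param reference A `spline_fit` or genes x days matrix with matching days
#'   and gene count.
#' @return A renormalized `stromal_estimate`.
#' @export
quantile_renormalize <- function(stromal, reference) {
  R <- if (inherits(reference, "spline_fit")) reference$fitted else reference
  S <- stromal$values
  days <- colnames(S)
  if (!all(days %in% colnames(R))) {
    abort("reference lacks some stromal days.")
  }
  if (nrow(R) != nrow(S)) abort("gene count mismatch with the reference.")
  out <- S
  for (d in days) {
    idx <- order(S[, d], seq_len(nrow(S)))   # stable under ties
    out[idx, d] <- sort(R[, d])
  }
  stromal$values <- out
  stromal$renormalized <- TRUE
  stromal
}

#' Confidence-thresholded stromal gene list
#'
#' The tissue:lymphoid ratio of a lymphoid-specific gene estimates the
#' lymphoid proportion, so ratios well above the marker distribution indicate
#' genuine stromal expression. The threshold is `mean + k * sd` of the marker
#' ratios (`k = 2.5` minimizes false positives, `k = 2.0` false negatives).
#' A gene is included when its ratio statistic over the evaluated days
#' exceeds the threshold: by default the mean ratio across days (the
#' least-false-positive choice, in keeping with the purpose of the list);
#' `days = "any"` instead admits a gene whose ratio exceeds the threshold on
#' any single day, and a character vector restricts evaluation to those
#' days.
#'
#' @param tissue,lymphoid [signal_matrix()]s (spline-fitted internally) or
#'   plain genes x days matrices used as-is.
#' @param markers Character vector of lymphoid-specific genes (>= 2).
#' @param k Stringency multiplier (> 0).
#' @param days `"mean"`, `"any"`, or specific day labels.
#' @param knots Interior knots when spline fitting is needed.
#' @return A `stromal_gene_list`: tibble of included genes with their ratio
#'   statistic, carrying `k` and the threshold as attributes.
#' @export
stromal_gene_list <- function(tissue, lymphoid, markers, k = 2.5,
                              days = "mean", knots = c(6, 17)) {
  if (k <= 0) abort("`k` must be > 0.")
  markers <- unique(as.character(markers))
  if (length(markers) < 2) {
    abort("need >= 2 markers for a standard deviation.")
  }
  if (inherits(tissue, "signal_matrix")) {
    Tm <- fit_robust_spline(tissue, knots = knots)$fitted
  } else Tm <- tissue
  if (inherits(lymphoid, "signal_matrix")) {
    Lm <- fit_robust_spline(lymphoid, knots = knots)$fitted
  } else Lm <- lymphoid
  if (!all(markers %in% rownames(Tm)) || !all(markers %in% rownames(Lm))) {
    abort("markers must be present in both matrices.")
  }
  ratio <- Tm / pmax(Lm, 1e-12)
  stat_any <- identical(days, "any")
  if (!stat_any && !identical(days, "mean")) {
    missing_d <- setdiff(days, colnames(ratio))
    if (length(missing_d)) {
      abort(paste0("days not in the data: ",
                   paste(missing_d, collapse = ", ")))
    }
    ratio <- ratio[, days, drop = FALSE]
  }
  mr <- as.vector(ratio[markers, , drop = FALSE])
  threshold <- mean(mr) + k * sd(mr)
  stat <- if (stat_any) apply(ratio, 1, max) else rowMeans(ratio)
  genes <- names(stat)[stat > threshold]
  out <- tibble(gene = genes, ratio_statistic = unname(stat[genes]))
  structure(out, k = k, threshold = threshold,
            class = c("stromal_gene_list", class(out)))
}

#' @export
print.stromal_gene_list <- function(x, ...) {
  cat("<stromal_gene_list> ", nrow(x), " genes at k=", attr(x, "k"),
      " (threshold ", signif(attr(x, "threshold"), 4), ")\n", sep = "")
  NextMethod()
}

#' Flag genes with dynamic trajectories
#'
#' A gene is dynamic when its maximum over days divided by its minimum
#' (floored at a small epsilon) reaches the fold threshold; the study's
#' criterion for "dynamically regulated" is a 2-fold or greater change.
#'
#' @param stromal A `stromal_estimate` or genes x days matrix.
#' @param fold Fold-change threshold (>= 1).
#' @param eps Floor applied to the per-gene minimum.
#' @return Tibble with `gene`, `min`, `max`, `fold_change`, `dynamic`.
#' @export
flag_dynamic_genes <- function(stromal, fold = 2, eps = 1e-8) {
  if (fold < 1) abort("`fold` must be >= 1.")
  S <- if (inherits(stromal, "stromal_estimate")) stromal$values else stromal
  if (ncol(S) < 2) abort("need >= 2 days to assess dynamics.")
  mx <- apply(S, 1, max)
  mn <- apply(S, 1, min)
  fc <- mx / pmax(mn, eps)
  tibble(gene = rownames(S), min = unname(mn), max = unname(mx),
         fold_change = unname(fc), dynamic = unname(fc >= fold))
}
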