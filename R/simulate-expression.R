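#' Configuration for the expression time-course simulator
#'
#' Describes a paired tissue/lymphoid microarray time course over a
#' castration-induced regeneration axis (integer days) plus a distinguished
#' `"young"` condition. Defaults mirror the sampling design of the study the
#' generator emulates: twenty serial time points with extra replicates at the
#' key inflection points of the regrowth curve.
#'
#' @param n_genes Total number of genes simulated.
#' @param n_marker_genes Number of lymphoid-specific marker genes; these have
#'   zero stromal expression, so in tissue their signal is purely the lymphoid
#'   admixture.
#' @param days Character vector of timepoints; integers as text plus
#'   optionally `"young"`.
#' @param replicates_per_day Named integer vector mapping day to replicate
#'   count; days absent from the map get `default_replicates`.
#' @param default_replicates Replicate count for unlisted days.
#' @param p_trajectory Lymphoid proportion per day, in (0, 1). Either a single
#'   value recycled to every day or a named vector over `days`.
#' @param noise_sd Multiplicative Gaussian noise, as a fraction of signal.
#' @param frac_dynamic Fraction of stromal-expressed genes given temporal
#'   patterns (early dip with late restoration, or early rise with late fall).
#' @param compartment Compartment label attached to the samples.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return An `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_genes = 2000,
                            n_marker_genes = 50,
                            days = c("young", as.character(0:23)),
                            replicates_per_day = c(young = 5, "0" = 4,
                                                   "6" = 3, "7" = 2,
                                                   "12" = 3, "16" = 2,
                                                   "17" = 3, "20" = 3),
                            default_replicates = 1,
                            p_trajectory = 0.85,
                            noise_sd = 0.05,
                            frac_dynamic = 0.4,
                            compartment = "cortex",
                            seed = 1L) {
  days <- as.character(days)
  if (n_genes < 1 || n_marker_genes < 0 || n_marker_genes > n_genes) {
    abort("need 0 <= n_marker_genes <= n_genes and n_genes >= 1.")
  }
  unknown <- setdiff(names(replicates_per_day), days)
  if (length(unknown)) {
    abort(paste0("replicate map references days not in `days`: ",
                 paste(unknown, collapse = ", ")))
  }
  reps <- setNames(rep(as.integer(default_replicates), length(days)), days)
  reps[names(replicates_per_day)] <- as.integer(replicates_per_day)
  if (any(reps < 1)) abort("replicate counts must be >= 1.")
  if (length(p_trajectory) == 1 && is.null(names(p_trajectory))) {
    p <- setNames(rep(p_trajectory, length(days)), days)
  } else {
    if (!all(days %in% names(p_trajectory))) {
      abort("`p_trajectory` must cover every day (or be a single value).")
    }
    p <- p_trajectory[days]
  }
  if (any(p <= 0 | p >= 1)) abort("all lymphoid proportions must be in (0,1).")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (frac_dynamic < 0 || frac_dynamic > 1) {
    abort("`frac_dynamic` must be in [0,1].")
  }
  structure(list(n_genes = n_genes, n_marker_genes = n_marker_genes,
                 days = days, replicates = reps, p = p,
                 noise_sd = noise_sd, frac_dynamic = frac_dynamic,
                 compartment = compartment, seed = as.integer(seed)),
            class = "expr_sim_config")
}

# prototype temporal shapes projected onto the natural-cubic-spline basis
# (interior knots 6 and 17) so that noise-free trajectories live exactly in
# the span the smoother uses
span_shapes <- function(dn) {
  dsort <- sort(unique(dn))
  if (length(dsort) < 4) {
    z <- matrix(0, length(dsort), 2,
                dimnames = list(as.character(dsort), c("dip", "rise")))
    return(z)
  }
  B <- cbind(1, splines::ns(dsort, knots = c(6, 17),
                            Boundary.knots = range(dsort)))
  proto <- -exp(-((dsort - 8) / 5)^2)           # transient dip around day 8
  f <- B %*% qr.coef(qr(B), proto)
  f <- (f - max(f)) / (max(f) - min(f))          # in [-1, 0], 0 at extremes
  cbind(dip = as.numeric(f), rise = as.numeric(-f))
}

#' Simulate a paired tissue/lymphoid expression time course
#'
#' Generates linear-scale signal matrices obeying the mixture identity
#' `tissue = p * lymphoid + (1 - p) * stromal` exactly before noise, plus
#' Affymetrix-style detection calls (Present above 1.2x the chip median,
#' Absent below 0.8x, Marginal in between) and a full ground-truth record.
#' Marker genes have stromal expression identically zero; dynamic stromal
#' genes follow smooth early-dip/late-restoration or early-rise/late-fall
#' trajectories with fold changes drawn log-uniformly in \[2, 6\].
#'
#' @param config An [expr_sim_config()].
#' @return A list of class `expr_simulation` with elements `tissue` and
#'   `lymphoid` ([signal_matrix()]s), `calls` (character matrix of
#'   P/M/A aligned to the tissue samples), and `truth` (true stromal and
#'   lymphoid matrices per day, true `p`, marker list, dynamic-gene labels,
#'   expression flags).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  set.seed(config$seed)
  days <- config$days
  dn <- day_numeric(days)
  num_days <- days[!is.na(dn)]
  ng <- config$n_genes
  nm <- config$n_marker_genes
  genes <- sprintf("G%05d", seq_len(ng))
  markers <- character(0)
  if (nm > 0) {
    markers <- sprintf("MK%04d", seq_len(nm))
    genes[seq_len(nm)] <- markers
  }
  other <- setdiff(genes, markers)

  # gene classes for the non-marker genes
  cls <- sample(c("both", "stromal_only", "lymphoid_only", "unexpressed"),
                length(other), replace = TRUE,
                prob = c(0.60, 0.15, 0.10, 0.15))
  names(cls) <- other
  stromal_expr <- other[cls %in% c("both", "stromal_only")]
  lymph_expr <- other[cls %in% c("both", "lymphoid_only")]

  base_s <- setNames(rlnorm(ng, log(120), 1), genes)
  base_l <- setNames(rlnorm(ng, log(120), 1), genes)
  floor_sig <- setNames(runif(ng, 2, 8), genes)

  shapes <- span_shapes(day_numeric(num_days))

  # dynamic stromal genes
  n_dyn <- round(config$frac_dynamic * length(stromal_expr))
  dyn_genes <- sample(stromal_expr, n_dyn)
  dyn_class <- sample(c("neg_early_restored_late", "pos_early_depleted_late"),
                      n_dyn, replace = TRUE)
  dyn_fold <- exp(runif(n_dyn, log(2), log(6)))
  names(dyn_class) <- names(dyn_fold) <- dyn_genes

  # per-gene temporal multiplier over numeric days (rows genes, cols days)
  curve_for <- function(gene_set, dyn_set, dcl, dfl) {
    cv <- matrix(1, length(gene_set), length(num_days),
                 dimnames = list(gene_set, num_days))
    for (g in intersect(gene_set, dyn_set)) {
      if (dcl[g] == "neg_early_restored_late") {
        a <- 1 - 1 / dfl[g]
        cv[g, ] <- 1 + a * shapes[, "dip"]
      } else {
        cv[g, ] <- 1 + (dfl[g] - 1) * shapes[, "rise"]
      }
    }
    cv
  }

  S <- matrix(0, ng, length(days), dimnames = list(genes, days))
  L <- matrix(0, ng, length(days), dimnames = list(genes, days))
  # stromal truth
  S[other, ] <- floor_sig[other]
  cv_s <- curve_for(stromal_expr, dyn_genes, dyn_class, dyn_fold)
  S[stromal_expr, num_days] <- base_s[stromal_expr] * cv_s
  # lymphoid truth: stable marker expression, mildly dynamic otherwise
  L[other, ] <- floor_sig[other]
  n_ldyn <- round(0.2 * length(lymph_expr))
  ldyn <- sample(lymph_expr, n_ldyn)
  lcl <- sample(c("neg_early_restored_late", "pos_early_depleted_late"),
                n_ldyn, replace = TRUE)
  lfl <- exp(runif(n_ldyn, log(2), log(4)))
  names(lcl) <- names(lfl) <- ldyn
  cv_l <- curve_for(lymph_expr, ldyn, lcl, lfl)
  L[lymph_expr, num_days] <- base_l[lymph_expr] * cv_l
  if (length(markers)) {
    L[markers, ] <- 2 * base_l[markers]   # well-expressed, stable
    S[markers, ] <- 0
  }
  # young condition: separate level, no spline involvement
  if ("young" %in% days) {
    yf_s <- setNames(1 + runif(length(stromal_expr), -0.2, 0.4), stromal_expr)
    yf_l <- setNames(1 + runif(length(lymph_expr), -0.2, 0.4), lymph_expr)
    S[stromal_expr, "young"] <- base_s[stromal_expr] * yf_s
    L[lymph_expr, "young"] <- base_l[lymph_expr] * yf_l
  }

  p <- config$p
  Tm <- sweep(L, 2, p, `*`) + sweep(S, 2, 1 - p, `*`)

  # replicate observations with multiplicative noise
  make_obs <- function(truth, fraction) {
    cols <- list()
    meta <- list()
    for (d in days) {
      for (r in seq_len(config$replicates[[d]])) {
        noise <- if (config$noise_sd > 0) {
          1 + rnorm(ng, 0, config$noise_sd)
        } else rep(1, ng)
        cols[[length(cols) + 1L]] <- pmax(truth[, d] * noise, 0)
        meta[[length(meta) + 1L]] <- tibble(
          sample = paste0(fraction, "_d", d, "_r", r),
          compartment = config$compartment, fraction = fraction,
          day = d, replicate = r)
      }
    }
    vals <- do.call(cbind, cols)
    rownames(vals) <- genes
    signal_matrix(vals, dplyr::bind_rows(meta))
  }
  tissue <- make_obs(Tm, "tissue")
  lymphoid <- make_obs(L, "lymphoid")

  # detection calls from the tissue signal, per chip
  calls <- apply(tissue$values, 2, function(v) {
    md <- median(v)
    ifelse(v > 1.2 * md, "P", ifelse(v < 0.8 * md, "A", "M"))
  })
  rownames(calls) <- genes

  truth <- list(
    stromal = S, lymphoid = L, tissue = Tm, p = p, markers = markers,
    dynamic = tibble(gene = dyn_genes, class = unname(dyn_class),
                     fold = unname(dyn_fold)),
    expressed = tibble(
      gene = genes,
      stromal_expressed = genes %in% stromal_expr,
      lymphoid_expressed = genes %in% c(lymph_expr, markers))
  )
  structure(list(tissue = tissue, lymphoid = lymphoid, calls = calls,
                 truth = truth, config = config),
            class = "expr_simulation")
}

#' @export
print.expr_simulation <- function(x, ...) {
  cat("<expr_simulation> ", x$config$n_genes, " genes, ",
      length(x$config$days), " timepoints, noise_sd=", x$config$noise_sd,
      ", seed=", x$config$seed, "\n", sep = "")
  invisible(x)
}
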