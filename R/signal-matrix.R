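#' Gene-by-sample signal matrix with sample metadata
#'
#' A light container pairing a nonnegative gene x sample matrix of normalized
#' signal values with a metadata table describing each sample (compartment,
#' fraction, day, replicate). Days are stored as character so that the
#' distinguished out-of-axis label `"young"` can sit alongside the integer
#' days of the regeneration time course.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene
#'   identifiers), samples in columns.
#' @param samples Data frame with one row per column of `values` and columns
#'   `sample`, `compartment` (`"cortex"` or `"medulla"`), `fraction`
#'   (`"tissue"` or `"lymphoid"`), `day` (character: `"young"` or an integer
#'   day as text) and `replicate`.
#' @return A `signal_matrix` object.
#' @export
signal_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values))) abort("`values` must have gene rownames.")
  if (anyDuplicated(rownames(values))) {
    abort("duplicate gene rows are not allowed.")
  }
  if (any(!is.finite(values))) abort("`values` must be finite.")
  if (any(values < 0)) abort("`values` must be nonnegative.")
  samples <- as_tibble(samples)
  need <- c("sample", "compartment", "fraction", "day", "replicate")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    abort(paste0("`samples` lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(samples) != ncol(values)) {
    abort("`samples` must have one row per column of `values`.")
  }
  if (anyNA(samples[need])) abort("every sample needs complete metadata.")
  samples$day <- as.character(samples$day)
  colnames(values) <- samples$sample
  structure(list(values = values, samples = samples),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("<signal_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", paste(unique(x$samples$fraction), collapse = "/"),
      ", ", paste(unique(x$samples$compartment), collapse = "/"),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

#' Tidy a signal matrix into a long tibble
#'
#' @param x A [signal_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `compartment`, `fraction`,
#'   `day`, `replicate`, `signal`.
#' @method tidy signal_matrix
#' @export
tidy.signal_matrix <- function(x, ...) {
  long <- tibble(
    gene = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(x$samples$sample, each = nrow(x$values)),
    signal = as.vector(x$values)
  )
  dplyr::left_join(long, x$samples, by = "sample")
}

# numeric day values, NA for "young"
day_numeric <- function(day) suppressWarnings(as.numeric(day))

# subset genes, keeping metadata
sm_subset_genes <- function(x, genes) {
  signal_matrix(x$values[genes, , drop = FALSE], x$samples)
}
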