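#' Gene-set collection
#'
#' Named gene sets (GMT-style) with a background universe against which
#' over-representation is tested.
#'
#' @param sets Either a named list of character vectors, or a tibble with
#'   columns `set`, `gene` (one row per membership) and optionally
#'   `description`.
#' @param universe Character vector: the background gene universe. Members
#'   outside the universe are ignored at test time.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.data.frame(sets)) {
    sets_list <- split(sets$gene, sets$set)
  } else {
    sets_list <- sets
  }
  if (is.null(names(sets_list)) || any(names(sets_list) == "")) {
    abort("every gene set needs a name.")
  }
  sets_list <- lapply(sets_list, function(g) unique(as.character(g)))
  if (any(lengths(sets_list) == 0)) abort("gene sets must be nonempty.")
  universe <- unique(as.character(universe))
  structure(list(sets = sets_list, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", length(x$sets), " sets over a universe of ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' @method tidy gene_set_collection
#' @export
tidy.gene_set_collection <- function(x, ...) {
  tibble(set = rep(names(x$sets), lengths(x$sets)),
         gene = unlist(x$sets, use.names = FALSE))
}

#' One-sided Fisher exact test for over-representation
#'
#' Exact hypergeometric upper tail on the 2x2 table (in-list/in-set against
#' their complements within the background): the probability of an overlap at
#' least as large as observed.
#'
#' @param list_genes Character vector: the gene list (subset of background).
#' @param set_genes Character vector: the gene set.
#' @param background Character vector: the universe.
#' @return Tibble with `overlap`, `list_size`, `set_size`, `universe`,
#'   `odds_ratio`, `p`, and `direction` (+1 over-, -1 under-represented
#'   relative to expectation).
#' @export
fisher_overrep <- function(list_genes, set_genes, background) {
  background <- unique(as.character(background))
  list_genes <- unique(intersect(list_genes, background))
  set_genes <- unique(intersect(set_genes, background))
  if (!length(set_genes)) {
    abort("gene set has no members inside the background.")
  }
  N <- length(background)
  K <- length(set_genes)
  n <- length(list_genes)
  k <- length(intersect(list_genes, set_genes))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  a <- k
  b <- n - k
  c2 <- K - k
  d <- N - K - n + k
  or <- (a * d) / max(b * c2, .Machine$double.eps)
  expected <- n * K / N
  tibble(overlap = k, list_size = n, set_size = K, universe = N,
         odds_ratio = or, p = min(p, 1),
         direction = sign(k - expected))
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up BH adjustment: q-values are monotone nondecreasing in p-rank and
#' never smaller than the raw p.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as `pvals`.
#' @export
bh_fdr <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Time-resolved over-representation of per-day gene lists
#'
#' For each day's stromal gene list, tests every retained gene set by the
#' one-sided Fisher exact test with BH correction across sets, then expresses
#' each set's trajectory as the change in statistical significance relative
#' to day 0: `sign * (-log10 p_day + log10 p_day0)`, positive when
#' over-represented. Sets are filtered by minimum membership and an optional
#' substring match on the set name (the study extracts cell-projection
#' ontologies with at least 10 members).
#'
#' @param lists_per_day Named list (names are days; `"0"` must be present) of
#'   character gene vectors, or a tibble with columns `day` and `gene`.
#' @param collection A [gene_set_collection()].
#' @param min_size Minimum number of set members inside the universe.
#' @param name_filter Substring (case-insensitive) a set name must contain;
#'   `NULL` disables the filter.
#' @return An `enrichment_series`: tibble with `set`, `day`, `overlap`, `p`,
#'   `q`, `direction`, `normalized`.
#' @export
enrichment_timecourse <- function(lists_per_day, collection, min_size = 10,
                                  name_filter = "projection") {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.data.frame(lists_per_day)) {
    lists_per_day <- split(lists_per_day$gene,
                           as.character(lists_per_day$day))
  }
  days <- names(lists_per_day)
  if (!"0" %in% days) abort("day 0 must be present (normalization anchor).")
  sets <- collection$sets
  sizes <- vapply(sets, function(g) length(intersect(g, collection$universe)),
                  integer(1))
  keep <- sizes >= min_size
  if (!is.null(name_filter)) {
    keep <- keep & stringr::str_detect(
      stringr::str_to_lower(names(sets)),
      stringr::fixed(stringr::str_to_lower(name_filter)))
  }
  if (!any(keep)) {
    warn("no gene set passes the size/name filters; empty series.")
    out <- tibble(set = character(), day = character(), overlap = integer(),
                  p = numeric(), q = numeric(), direction = numeric(),
                  normalized = numeric())
    return(structure(out, class = c("enrichment_series", class(out))))
  }
  sets <- sets[keep]
  rows <- purrr::map(days, function(d) {
    lst <- lists_per_day[[d]]
    res <- purrr::map(names(sets), function(s) {
      r <- fisher_overrep(lst, sets[[s]], collection$universe)
      dplyr::mutate(r, set = s, day = d)
    })
    res <- dplyr::bind_rows(res)
    res$q <- bh_fdr(res$p)
    res
  })
  out <- dplyr::bind_rows(rows)
  p0 <- out[out$day == "0", c("set", "p")]
  names(p0)[2] <- "p_day0"
  out <- dplyr::left_join(out, p0, by = "set")
  out$normalized <- ifelse(out$direction == 0, 0, out$direction) *
    (-log10(out$p) + log10(out$p_day0))
  out <- dplyr::select(out, "set", "day", "overlap", "p", "q", "direction",
                       "normalized")
  structure(out, class = c("enrichment_series", class(out)))
}

#' Pathway over-representation with size and keyword filters
#'
#' Hypergeometric over-representation per pathway, restricted to pathways
#' with at most `max_size` genes whose name matches one of the keywords
#' (default: "signaling" and its spelling variant), BH-corrected and sorted
#' ascending by q then p — the procedure behind "top signaling pathways"
#' rankings.
#'
#' @param list_genes Nonempty character gene list.
#' @param collection A [gene_set_collection()].
#' @param max_size Maximum pathway size (members inside the universe).
#' @param keywords Character vector; a pathway is kept when its name contains
#'   any of them (case-insensitive). `NULL` disables the filter.
#' @return Tibble: `set`, `overlap`, `set_size`, `p`, `q`, sorted by q then p.
#' @export
pathway_enrich <- function(list_genes, collection, max_size = 200,
                           keywords = c("signaling", "signalling")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!length(list_genes)) abort("gene list is empty.")
  sets <- collection$sets
  sizes <- vapply(sets, function(g) length(intersect(g, collection$universe)),
                  integer(1))
  keep <- sizes <= max_size & sizes > 0
  if (!is.null(keywords)) {
    lower <- stringr::str_to_lower(names(sets))
    hit <- Reduce(`|`, lapply(stringr::str_to_lower(keywords), function(k) {
      stringr::str_detect(lower, stringr::fixed(k))
    }))
    keep <- keep & hit
  }
  sets <- sets[keep]
  if (!length(sets)) {
    return(tibble(set = character(), overlap = integer(),
                  set_size = integer(), p = numeric(), q = numeric()))
  }
  res <- purrr::map(names(sets), function(s) {
    r <- fisher_overrep(list_genes, sets[[s]], collection$universe)
    tibble(set = s, overlap = r$overlap, set_size = r$set_size, p = r$p)
  })
  out <- dplyr::bind_rows(res)
  out$q <- bh_fdr(out$p)
  dplyr::arrange(out, .data$q, .data$p)
}

#' Classify a set's normalized significance trajectory
#'
#' The study observed two dominant temporal patterns: depletion of negative
#' regulators early followed by restoration later, or enrichment of positive
#' regulators early followed by depletion later. A trajectory is classified by
#' the sign of its mean normalized value in an early window against a late
#' window.
#'
#' @param days Numeric days of the trajectory (>= 3).
#' @param normalized Day-0-normalized signed significance values.
#' @param early,late Length-2 numeric windows (inclusive).
#' @return One of `"neg_early_restored_late"`, `"pos_early_depleted_late"`,
#'   `"other"`.
#' @export
classify_temporal_pattern <- function(days, normalized,
                                      early = c(1, 11), late = c(12, 23)) {
  days <- as.numeric(days)
  if (length(days) < 3) abort("need >= 3 days to classify a pattern.")
  if (all(normalized == 0)) return("other")
  e <- normalized[days >= early[1] & days <= early[2]]
  l <- normalized[days >= late[1] & days <= late[2]]
  if (!length(e) || !length(l)) return("other")
  me <- mean(e)
  ml <- mean(l)
  if (me < 0 && ml >= 0) return("neg_early_restored_late")
  if (me > 0 && ml <= 0) return("pos_early_depleted_late")
  "other"
}

#' Heatmap of an enrichment time course
#'
#' @param object An `enrichment_series`.
#' @param ... Unused.
#' @return A ggplot: sets x days, fill = day-0-normalized significance.
#' @method autoplot enrichment_series
#' @export
autoplot.enrichment_series <- function(object, ...) {
  df <- as_tibble(object)
  df$day <- factor(df$day, levels = unique(df$day[order(
    suppressWarnings(as.numeric(df$day)))]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$set,
                                   fill = .data$normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "day post-castration", y = NULL,
                  fill = expression(Delta ~ -log[10] ~ p)) +
    ggplot2::theme_minimal()
}
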