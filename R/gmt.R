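#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate members within a set are removed with a
#' warning; lines with fewer than three fields raise an error naming the
#' line.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `set`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(paste0("malformed GMT line ", i, ": expected name, description ",
                   "and at least one member gene."))
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(paste0("GMT set '", f[1], "' (line ", i,
                  ") has duplicate members; deduplicated."))
      genes <- unique(genes)
    }
    rows[[i]] <- tibble(set = f[1], description = f[2], gene = genes)
  }
  dplyr::bind_rows(rows)
}

#' Write gene sets to a GMT file
#'
#' @param sets Tibble with columns `set`, `gene` and optionally
#'   `description`, or a named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (!is.data.frame(sets)) {
    sets <- tibble(set = rep(names(sets), lengths(sets)),
                   gene = unlist(sets, use.names = FALSE))
  }
  if (!"description" %in% names(sets)) sets$description <- ""
  by_set <- split(sets, sets$set)
  lines <- vapply(by_set, function(d) {
    paste(c(d$set[1], d$description[1], unique(d$gene)), collapse = "\t")
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}
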