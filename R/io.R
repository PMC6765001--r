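#' Write / read a signal matrix as TSV
#'
#' The values go to `path` (first column `gene`, then one column per
#' sample); sample metadata goes to a sidecar TSV (`<path>.samples.tsv` by
#' default), so the pair round-trips through [read_signal_tsv()] at full
#' precision.
#'
#' @param x A [signal_matrix()].
#' @param path Output TSV path.
#' @param metadata_path Sidecar path for the sample table.
#' @return `path`, invisibly.
#' @export
write_signal_tsv <- function(x, path,
                             metadata_path = paste0(path, ".samples.tsv")) {
  stopifnot(inherits(x, "signal_matrix"))
  df <- as_tibble(x$values, rownames = "gene")
  readr::write_tsv(df, path)
  readr::write_tsv(x$samples, metadata_path)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @export
read_signal_tsv <- function(path,
                            metadata_path = paste0(path, ".samples.tsv")) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene
  samples <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                             col_types = readr::cols(
                               day = readr::col_character()))
  signal_matrix(vals, samples)
}

#' Write a detection-call matrix as TSV
#'
#' @param calls Character matrix (P/M/A), gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  df <- as_tibble(calls, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' Write / read a multi-channel volume as TIFF with a spacing sidecar
#'
#' Each channel goes to `<prefix>_<channel>.tif` as a multi-page (one page
#' per z-plane) 32-bit float TIFF on a 0-1 scale (intensity / 255); the
#' voxel spacing and channel names go to `<prefix>_spacing.json`.
#'
#' @param volume A [voxel_volume()].
#' @param prefix Output path prefix.
#' @return The sidecar path, invisibly.
#' @export
write_volume_tiff <- function(volume, prefix) {
  stopifnot(inherits(volume, "voxel_volume"))
  for (ch in names(volume$channels)) {
    arr <- volume$channels[[ch]]
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / 255)
    tiff::writeTIFF(pages, paste0(prefix, "_", ch, ".tif"),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  sidecar <- paste0(prefix, "_spacing.json")
  jsonlite::write_json(list(spacing_um = volume$spacing,
                            channels = names(volume$channels),
                            dim = volume$dim),
                       sidecar, auto_unbox = FALSE, digits = NA)
  invisible(sidecar)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_spacing.json"),
                              simplifyVector = TRUE)
  chans <- lapply(meta$channels, function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    arr <- array(0, meta$dim)
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * 255
    arr
  })
  names(chans) <- meta$channels
  voxel_volume(chans, meta$spacing_um)
}
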