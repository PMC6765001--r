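#' Multi-channel 3D intensity volume with physical spacing
#'
#' Voxel data are numeric arrays indexed `(z, y, x)` (0-based in physical
#' terms, 1-based in R), with anisotropic voxel spacing in micrometres.
#' Intensities follow the 8-bit grayscale convention (0-255) but are stored
#' as doubles.
#'
#' @param channels A named list of 3D numeric arrays sharing the same
#'   dimensions, or a single array (named `"ch1"`).
#' @param spacing_um Numeric length-3: voxel spacing in µm along (z, y, x).
#' @return A `voxel_volume`.
#' @export
voxel_volume <- function(channels, spacing_um) {
  if (is.array(channels) && length(dim(channels)) == 3) {
    channels <- list(ch1 = channels)
  }
  if (is.null(names(channels)) || any(names(channels) == "")) {
    abort("channels must be named.")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, integer(1)) != 3)) {
    abort("each channel must be a 3D array (z, y, x).")
  }
  if (length(unique(lapply(dims, identical, dims[[1]]))) != 1 ||
      !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("all channels must share the same dimensions.")
  }
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3 || any(spacing_um <= 0)) {
    abort("`spacing_um` must be 3 positive values (z, y, x).")
  }
  for (ch in channels) {
    if (any(!is.finite(ch)) || any(ch < 0)) {
      abort("intensities must be finite and nonnegative.")
    }
  }
  structure(list(channels = channels, spacing = spacing_um,
                 dim = dims[[1]]),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(x$dim, collapse = " x "), " voxels (z,y,x), ",
      "spacing ", paste(signif(x$spacing, 3), collapse = "/"), " um, ",
      "channels: ", paste(names(x$channels), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) x$dim

# pull one channel as an array, accepting a name or an array directly
get_channel <- function(volume, channel) {
  if (is.array(channel)) return(channel)
  if (inherits(volume, "voxel_volume")) {
    if (is.null(channel)) {
      if (length(volume$channels) > 1) {
        abort("volume has several channels; name one.")
      }
      return(volume$channels[[1]])
    }
    if (!channel %in% names(volume$channels)) {
      abort(paste0("no channel '", channel, "'."))
    }
    return(volume$channels[[channel]])
  }
  if (is.array(volume)) return(volume)
  abort("expected a voxel_volume or a 3D array.")
}

# physical voxel-centre coordinates along one axis
axis_coords <- function(n, sp) (seq_len(n) - 1) * sp

#' Subtract the autofluorescence channel from a reporter channel
#'
#' Age pigments emit across the whole collection spectrum, so an
#' independently imaged autofluorescence channel can be scaled and subtracted
#' from each reporter channel; negative results are clipped at zero.
#'
#' @param reporter,autofluor 3D arrays of equal shape.
#' @param scale Scale factor applied to `autofluor`.
#' @return The cleaned reporter array.
#' @export
subtract_autofluorescence <- function(reporter, autofluor, scale = 1.0) {
  if (!identical(dim(reporter), dim(autofluor))) {
    abort("reporter and autofluorescence channels differ in shape.")
  }
  pmax(reporter - scale * autofluor, 0)
}
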