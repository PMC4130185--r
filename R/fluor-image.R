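#' Multichannel fluorescence image container
#'
#' A `fluor_image` holds named unit-interval rasters (conventionally
#' `nuclear`, `marker` and optionally `auxiliary`) that share one shape,
#' together with the bit depth of the source acquisition. Pixels are indexed
#' `(row, col)`, 0-based coordinates are never used at the R level; all
#' exported geometry is 1-based matrix indexing.
#'
#' @param channels Named list of numeric matrices with values in \[0, 1\].
#' @param bit_depth Integer bit depth of the source acquisition (default 12,
#'   the usual confocal setting).
#' @return An object of class `fluor_image`.
#' @export
fluor_image <- function(channels, bit_depth = 12L) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("`channels` must be a named list of matrices")
  for (nm in names(channels)) {
    stop_if_not_matrix(channels[[nm]], nm)
    v <- channels[[nm]]
    if (any(!is.finite(v))) stop(sprintf("channel '%s' has non-finite pixels", nm))
    if (min(v) < 0 || max(v) > 1)
      stop(sprintf("channel '%s' has pixels outside [0, 1]", nm))
  }
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1L) stop("all channels must share the same shape")
  structure(
    list(channels = channels, bit_depth = as.integer(bit_depth),
         shape = dims[[1L]]),
    class = "fluor_image"
  )
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf("<fluor_image> %d x %d px, %d-bit, channels: %s\n",
              x$shape[1], x$shape[2], x$bit_depth,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Normalize an integer raster to the unit interval
#'
#' Linearly maps raw detector counts to \[0, 1\] by dividing by the maximum
#' representable value `2^bit_depth - 1`. The map is strictly order
#' preserving; a 12-bit raw value of 4095 maps to exactly 1.
#'
#' @param raw Numeric matrix of raw counts in `[0, 2^bit_depth - 1]`.
#' @param bit_depth Integer acquisition bit depth.
#' @return Numeric matrix with values in \[0, 1\].
#' @export
normalize_image <- function(raw, bit_depth = 12L) {
  stop_if_not_matrix(raw, "raw")
  if (any(!is.finite(raw))) stop("`raw` contains non-finite values")
  top <- 2^as.integer(bit_depth) - 1
  if (min(raw) < 0)
    stop(sprintf("raw value %g below 0 is outside the %d-bit range",
                 min(raw), bit_depth))
  if (max(raw) > top)
    stop(sprintf("raw value %g exceeds the %d-bit maximum %d",
                 max(raw), bit_depth, top))
  raw / top
}
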