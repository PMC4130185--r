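#' Write and read multichannel images as multipage TIFF with a JSON sidecar
#'
#' Channels are written one per page, in the order `nuclear`, `marker`, then
#' any further channels, as 32-bit float samples. The sidecar records the
#' channel order, bit depth and (optionally) the generator ground truth, so a
#' written image round-trips with its provenance.
#'
#' @param image A [fluor_image].
#' @param path Output TIFF path.
#' @param truth Optional truth list from [gen_image()].
#' @param sidecar Sidecar JSON path; default `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fluor_image <- function(image, path, truth = NULL,
                              sidecar = paste0(path, ".json")) {
  stopifnot(inherits(image, "fluor_image"))
  ord <- intersect(c("nuclear", "marker"), names(image$channels))
  ord <- c(ord, setdiff(names(image$channels), ord))
  tiff::writeTIFF(image$channels[ord], path, bits.per.sample = 32L,
                  compression = "none")
  meta <- list(channel_order = ord, bit_depth = image$bit_depth,
               shape = image$shape)
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_fluor_image
#' @return `read_fluor_image()`: a list with `image` and `truth` (NULL when
#'   the sidecar has none).
#' @export
read_fluor_image <- function(path, sidecar = paste0(path, ".json")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!file.exists(sidecar)) stop(sprintf("sidecar not found: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (length(pages) != length(meta$channel_order))
    stop("page count does not match sidecar channel order")
  ch <- setNames(lapply(pages, function(p) {
    m <- if (length(dim(p)) == 3) p[, , 1] else p
    pmin(pmax(m, 0), 1)
  }), meta$channel_order)
  truth <- meta$truth
  if (!is.null(truth) && !is.null(truth$cells))
    truth$cells <- as.data.frame(truth$cells)
  list(image = fluor_image(ch, meta$bit_depth), truth = truth)
}

#' Write a label map as 16-bit TIFF
#'
#' Labels are stored as `label / 65535` (16-bit range), so up to 65535
#' objects round-trip exactly.
#'
#' @param labels A `label_map` or integer matrix.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  m <- if (inherits(labels, "label_map")) labels$labels else labels
  if (max(m) > 65535) stop("more than 65535 labels cannot be stored in 16 bits")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_map
#' @return `read_label_map()`: an integer matrix.
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write and read calcium traces as wide CSV with a protocol sidecar
#'
#' One row per cell (`cell_id`, then one column per frame), raw fluorescence
#' units; the acquisition protocol goes to a JSON sidecar.
#'
#' @param traces List of [calcium_trace()] sharing one protocol.
#' @param path Output CSV path.
#' @param sidecar Protocol JSON path; default `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path, sidecar = paste0(path, ".json")) {
  stopifnot(length(traces) > 0)
  p <- traces[[1]]$protocol
  m <- t(vapply(traces, function(tr) tr$values, numeric(p$n_frames)))
  df <- data.frame(cell_id = vapply(traces, function(tr) tr$cell_id, numeric(1)),
                   m)
  names(df) <- c("cell_id", paste0("frame_", seq_len(p$n_frames)))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(unclass(p), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces_csv
#' @return `read_traces_csv()`: a list of [calcium_trace()].
#' @export
read_traces_csv <- function(path, sidecar = paste0(path, ".json")) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  proto <- calcium_protocol(meta$frame_rate, meta$baseline_duration,
                            meta$stimulus_onset, meta$stimulus_offset,
                            meta$total_duration)
  lapply(seq_len(nrow(df)), function(i)
    calcium_trace(as.numeric(df[i, -1]), proto, cell_id = df$cell_id[i]))
}

#' Write and read an fEPSP series as CSV with JSON metadata
#'
#' @param series A [fepsp_series()].
#' @param path Output CSV path (`timestamp_min`, `amplitude`).
#' @param sidecar Metadata JSON path; default `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fepsp_csv <- function(series, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(series, "fepsp_series"))
  write.csv(data.frame(timestamp_min = series$time_min,
                       amplitude = series$amplitude),
            path, row.names = FALSE)
  jsonlite::write_json(list(condition = series$condition,
                            baseline_window = series$baseline_window),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fepsp_csv
#' @return `read_fepsp_csv()`: a [fepsp_series()].
#' @export
read_fepsp_csv <- function(path, sidecar = paste0(path, ".json")) {
  df <- read.csv(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  fepsp_series(df$timestamp_min, df$amplitude,
               baseline_window = meta$baseline_window,
               condition = meta$condition)
}
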