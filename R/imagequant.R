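#' Threshold the nuclear channel into a size-filtered mask
#'
#' Pixels at or above `intensity_threshold` become foreground; connected
#' components (8-connectivity) smaller than `min_area_px` are then removed,
#' mirroring the usual size-plus-intensity gating used to keep only
#' Hoechst-labelled nuclei. When `intensity_threshold` is `NULL` an Otsu
#' threshold computed from the channel histogram is used and recorded in the
#' result.
#'
#' @param nuclear Unit-interval numeric matrix (nuclear channel).
#' @param intensity_threshold Threshold in (0, 1), or `NULL` for Otsu.
#' @param min_area_px Minimum component area in px^2 (default 30).
#' @return A list of class `nuclear_mask`: `mask` (logical matrix),
#'   `intensity_threshold`, `min_area_px`.
#' @export
threshold_nuclei <- function(nuclear, intensity_threshold = NULL,
                             min_area_px = 30) {
  stop_if_not_matrix(nuclear, "nuclear")
  if (any(!is.finite(nuclear))) stop("`nuclear` contains non-finite pixels")
  if (min_area_px < 1) stop("`min_area_px` must be >= 1")
  if (is.null(intensity_threshold))
    intensity_threshold <- otsu_threshold(nuclear)
  if (intensity_threshold <= 0 || intensity_threshold >= 1)
    stop("`intensity_threshold` must lie in (0, 1)")
  fg <- nuclear >= intensity_threshold
  if (any(fg)) {
    lab <- .cc_label8(fg)
    area <- tabulate(lab[lab > 0L])
    keep <- which(area >= min_area_px)
    fg <- matrix(lab %in% keep, nrow(fg), ncol(fg))
  }
  structure(list(mask = fg, intensity_threshold = intensity_threshold,
                 min_area_px = min_area_px),
            class = "nuclear_mask")
}

# Otsu threshold on a 256-bin histogram of unit-interval data, returned as the
# lower edge of the best split (between-class variance maximiser).
otsu_threshold <- function(x, n_bins = 256L) {
  h <- tabulate(pmin(n_bins, floor(x * n_bins) + 1L), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) / n_bins
}

#' Dilate a nuclear mask into a soma region
#'
#' Morphological dilation by a Euclidean disc structuring element: the output
#' contains every pixel within `radius_px` of a mask pixel, designating a soma
#' region surrounding each nucleus. Radius 0 is the identity.
#'
#' @param mask A `nuclear_mask` or logical matrix.
#' @param radius_px Disc radius in px (>= 0, default 5).
#' @return Logical matrix, a superset of the input mask.
#' @export
dilate_soma <- function(mask, radius_px = 5) {
  m <- if (inherits(mask, "nuclear_mask")) mask$mask else mask
  if (!is.matrix(m)) stop("`mask` must be a matrix or nuclear_mask")
  if (radius_px < 0) stop("`radius_px` must be >= 0")
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  if (radius_px == 0 || !any(m)) return(m)
  .dilate_disc(m, radius_px)
}

#' Euclidean distance map of a binary mask
#'
#' For every foreground pixel, the Euclidean distance to the nearest
#' background pixel; background pixels are 0. The image boundary is treated
#' as bordered by background, so a foreground pixel on the edge has distance
#' 1.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Numeric matrix of distances in px.
#' @export
distance_map <- function(mask) {
  m <- if (inherits(mask, "nuclear_mask")) mask$mask else mask
  if (!is.matrix(m)) stop("`mask` must be a matrix")
  m <- matrix(as.numeric(as.logical(m)), nrow(m), ncol(m))
  # pad with a background border so the edge convention holds, then crop
  padded <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  padded[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  d <- EBImage::distmap(padded, metric = "euclidean")
  unclass(d)[2:(nrow(m) + 1L), 2:(ncol(m) + 1L), drop = FALSE]
}

# Local maxima of a distance map (8-neighbourhood, plateaus included),
# greedily thinned so surviving seeds are >= min_distance_px apart.
# Candidates are ranked by decreasing height, ties broken by raster order
# (smallest column-major index, i.e. smallest (col, row) -> deterministic).
find_seeds <- function(dist, min_distance_px) {
  nr <- nrow(dist); nc <- ncol(dist)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- dist
  is_max <- dist > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
    is_max <- is_max & (dist >= nb)
  }
  idx <- which(is_max)
  if (!length(idx)) return(cbind(row = integer(0), col = integer(0)))
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  ord <- order(-dist[idx], rows, cols)
  rows <- rows[ord]; cols <- cols[ord]
  keep_r <- integer(0); keep_c <- integer(0)
  min2 <- min_distance_px^2
  for (i in seq_along(rows)) {
    if (!length(keep_r) ||
        all((keep_r - rows[i])^2 + (keep_c - cols[i])^2 >= min2)) {
      keep_r <- c(keep_r, rows[i]); keep_c <- c(keep_c, cols[i])
    }
  }
  cbind(row = keep_r, col = keep_c)
}

#' Separate touching objects by nuclear-seeded watershed
#'
#' Seeds are local maxima of the distance map thinned to a minimum mutual
#' distance of `min_distance_px`; the region is then flooded from the seeds in
#' order of decreasing distance-map height (priority flooding), which splits
#' clusters of touching nuclei along the valleys between their distance
#' peaks. Objects whose equivalent radius `sqrt(area / pi)` falls below
#' `min_radius_px` are discarded and the remaining labels renumbered
#' consecutively.
#'
#' @param dist Distance map of `region` (from [distance_map()]).
#' @param region Logical matrix, the foreground to partition.
#' @param min_distance_px Minimum seed separation in px (default 10).
#' @param min_radius_px Minimum equivalent object radius in px (default 3).
#' @return A list of class `label_map`: `labels` (integer matrix, 0 =
#'   background, consecutive labels from 1), `seeds` (matrix of seed
#'   coordinates, one row per surviving label), `min_distance_px`,
#'   `min_radius_px`.
#' @export
watershed_separate <- function(dist, region, min_distance_px = 10,
                               min_radius_px = 3) {
  m <- if (inherits(region, "nuclear_mask")) region$mask else region
  stop_if_not_matrix(dist, "dist")
  if (!is.matrix(m)) stop("`region` must be a matrix")
  if (!all(dim(dist) == dim(m))) stop("`dist` and `region` shapes differ")
  if (min_distance_px < 1) stop("`min_distance_px` must be >= 1")
  if (min_radius_px < 0) stop("`min_radius_px` must be >= 0")
  m <- matrix(as.logical(m), nrow(m), ncol(m))
  seeds_rc <- find_seeds(dist, min_distance_px)
  seed_map <- matrix(0L, nrow(m), ncol(m))
  if (nrow(seeds_rc))
    seed_map[cbind(seeds_rc[, "row"], seeds_rc[, "col"])] <-
      seq_len(nrow(seeds_rc))
  labels <- .watershed_flood(dist, m, seed_map)
  # radius filter + consecutive relabelling (by original seed order)
  if (nrow(seeds_rc)) {
    area <- tabulate(labels[labels > 0L], nbins = nrow(seeds_rc))
    keep <- which(sqrt(area / pi) >= min_radius_px & area > 0L)
    remap <- integer(nrow(seeds_rc))
    remap[keep] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    seeds_rc <- seeds_rc[keep, , drop = FALSE]
  }
  structure(list(labels = labels, seeds = seeds_rc,
                 min_distance_px = min_distance_px,
                 min_radius_px = min_radius_px),
            class = "label_map")
}

#' Grow nuclear labels into soma labels
#'
#' Assigns each pixel of the dilated soma region to the nuclear label that
#' reaches it first under the same priority flooding used by
#' [watershed_separate()], so every soma region contains its nucleus
#' region-for-region.
#'
#' @param nuclear_labels A `label_map` from [watershed_separate()].
#' @param soma_region Logical matrix from [dilate_soma()] (must contain the
#'   labelled nuclear pixels).
#' @return A `label_map` over the soma region with identical label ids.
#' @export
grow_soma_labels <- function(nuclear_labels, soma_region) {
  stopifnot(inherits(nuclear_labels, "label_map"))
  lab <- nuclear_labels$labels
  if (!all(dim(lab) == dim(soma_region))) stop("shape mismatch")
  if (any(lab > 0L & !soma_region))
    stop("`soma_region` must contain every labelled nuclear pixel")
  d <- distance_map(soma_region)
  out <- .watershed_flood(d, matrix(as.logical(soma_region),
                                    nrow(soma_region), ncol(soma_region)), lab)
  structure(list(labels = out, seeds = nuclear_labels$seeds,
                 min_distance_px = nuclear_labels$min_distance_px,
                 min_radius_px = nuclear_labels$min_radius_px),
            class = "label_map")
}

#' Per-cell geometry and mean marker intensity
#'
#' For every label, computes the arithmetic mean of the marker channel over
#' the combined nuclear-plus-soma region (the full soma label, which contains
#' the nucleus), the mean nuclear-channel intensity over the nucleus, and
#' geometry: centroid, nucleus and soma areas, and equivalent nucleus radius
#' `sqrt(area / pi)`. This per-cell mean marker intensity is the unit
#' summarised and compared across conditions downstream.
#'
#' @param soma_labels `label_map` over soma regions.
#' @param nuclear_labels `label_map` over nuclei (same label ids).
#' @param marker Unit-interval marker-channel matrix.
#' @param nuclear Unit-interval nuclear-channel matrix.
#' @return A data.frame with one row per cell, ordered by `cell_id`:
#'   `cell_id`, `centroid_row`, `centroid_col`, `nucleus_area`, `soma_area`,
#'   `equivalent_radius`, `mean_marker_intensity`, `mean_nuclear_intensity`.
#' @export
measure_cells <- function(soma_labels, nuclear_labels, marker, nuclear) {
  sl <- soma_labels$labels; nl <- nuclear_labels$labels
  stop_if_not_matrix(marker, "marker")
  if (!all(dim(sl) == dim(nl)) || !all(dim(sl) == dim(marker)) ||
      !all(dim(sl) == dim(nuclear)))
    stop("label maps and channels must share one shape")
  ids <- sort(unique(nl[nl > 0L]))
  if (!length(ids))
    return(data.frame(cell_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), nucleus_area = numeric(0),
                      soma_area = numeric(0), equivalent_radius = numeric(0),
                      mean_marker_intensity = numeric(0),
                      mean_nuclear_intensity = numeric(0)))
  if (!all(ids %in% sl))
    stop("nuclear label(s) absent from soma map: containment invariant broken")
  nuc_idx <- which(nl > 0L)
  soma_idx <- which(sl > 0L)
  nr <- nrow(nl)
  nuc_lab <- nl[nuc_idx]
  rows <- (nuc_idx - 1L) %% nr + 1L
  cols <- (nuc_idx - 1L) %/% nr + 1L
  nucleus_area <- as.numeric(tabulate(nuc_lab, max(ids)))
  soma_area <- as.numeric(tabulate(sl[soma_idx], max(ids)))
  cen_r <- rowsum(rows, nuc_lab)[, 1] / nucleus_area[ids]
  cen_c <- rowsum(cols, nuc_lab)[, 1] / nucleus_area[ids]
  mean_mark <- rowsum(marker[soma_idx], sl[soma_idx])[, 1] / soma_area[ids]
  mean_nuc <- rowsum(nuclear[nuc_idx], nuc_lab)[, 1] / nucleus_area[ids]
  data.frame(
    cell_id = ids,
    centroid_row = cen_r, centroid_col = cen_c,
    nucleus_area = nucleus_area[ids], soma_area = soma_area[ids],
    equivalent_radius = sqrt(nucleus_area[ids] / pi),
    mean_marker_intensity = mean_mark,
    mean_nuclear_intensity = mean_nuc,
    row.names = NULL
  )
}

#' Pearson correlation and linear regression between channel intensities
#'
#' Ordinary least squares of one per-cell intensity on another (by default
#' mean marker on mean nuclear-channel intensity), with the Pearson
#' correlation coefficient, its square, and the two-sided p value for the
#' correlation -- the per-cell scatter analysis used to relate marker
#' expression to a reference stain.
#'
#' @param records Cell table from [measure_cells()] (or any data.frame).
#' @param x,y Column names of predictor and response.
#' @return A list: `n`, `r`, `r_squared`, `slope`, `intercept`, `p_value`.
#' @export
correlate_channels <- function(records, x = "mean_nuclear_intensity",
                               y = "mean_marker_intensity") {
  if (!all(c(x, y) %in% names(records))) stop("columns not found in `records`")
  xv <- records[[x]]; yv <- records[[y]]
  if (length(xv) < 3) stop("need at least 3 records")
  if (sd(xv) == 0) stop("constant predictor: correlation undefined")
  if (sd(yv) == 0) stop("constant response: correlation undefined")
  fit <- lm(yv ~ xv)
  ct <- cor.test(xv, yv, method = "pearson")
  list(n = length(xv), r = unname(ct$estimate),
       r_squared = unname(ct$estimate)^2,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p_value = ct$p.value)
}

#' Run the full segmentation and measurement pipeline on one image
#'
#' Convenience wrapper chaining [threshold_nuclei()], [dilate_soma()],
#' [distance_map()], [watershed_separate()], [grow_soma_labels()] and
#' [measure_cells()] with the package defaults (all overridable).
#'
#' @param image A [fluor_image] with `nuclear` and `marker` channels.
#' @param intensity_threshold Nuclear threshold, `NULL` for Otsu.
#' @param min_area_px Minimum nucleus component area.
#' @param soma_radius_px Soma dilation radius.
#' @param min_distance_px Minimum watershed seed separation.
#' @param min_radius_px Minimum equivalent nucleus radius.
#' @return A list: `cells` (data.frame), `nuclear_labels`, `soma_labels`,
#'   `mask`, `params`.
#' @export
segment_image <- function(image, intensity_threshold = NULL, min_area_px = 30,
                          soma_radius_px = 5, min_distance_px = 10,
                          min_radius_px = 3) {
  stopifnot(inherits(image, "fluor_image"))
  if (!all(c("nuclear", "marker") %in% names(image$channels)))
    stop("image must have 'nuclear' and 'marker' channels")
  mask <- threshold_nuclei(image$channels$nuclear, intensity_threshold,
                           min_area_px)
  d <- distance_map(mask$mask)
  nuc <- watershed_separate(d, mask$mask, min_distance_px, min_radius_px)
  soma_region <- dilate_soma(nuc$labels > 0L, soma_radius_px)
  soma <- grow_soma_labels(nuc, soma_region)
  cells <- measure_cells(soma, nuc, image$channels$marker,
                         image$channels$nuclear)
  list(cells = cells, nuclear_labels = nuc, soma_labels = soma, mask = mask,
       params = list(intensity_threshold = mask$intensity_threshold,
                     min_area_px = min_area_px,
                     soma_radius_px = soma_radius_px,
                     min_distance_px = min_distance_px,
                     min_radius_px = min_radius_px))
}
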