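#' Specification for a synthetic two-channel micrograph
#'
#' Describes the latent scene from which [gen_image()] renders a
#' ground-truthed image: cell count, geometry and intensity ranges, per-channel
#' background and additive noise. Defaults emulate a 12-bit 1024 x 1024
#' confocal field of the hippocampal cell layers: on the order of a hundred
#' Hoechst-stained nuclei of 6-9 px radius over a dim background, with the
#' marker channel carrying per-cell somatic expression levels spread over most
#' of the dynamic range.
#'
#' Cells are discs: the nucleus is a filled disc of `nucleus_radius` in the
#' nuclear channel and the soma a concentric disc enlarged by
#' `soma_radius_extra` carrying `marker_intensity` in the marker channel.
#' `min_separation` is the smallest admissible center-to-center distance; the
#' default keeps somata disjoint so that per-cell truth recovery is exact.
#'
#' @param n_cells Number of cells to place.
#' @param image_shape Integer vector `(rows, cols)`.
#' @param nucleus_radius Range (length-2) of nucleus radii in px.
#' @param nucleus_intensity Range of nuclear-channel disc intensities.
#' @param marker_intensity Range of per-cell marker intensities.
#' @param background Named per-channel background level, unit interval.
#' @param noise_sd Additive Gaussian noise SD (unit-interval scale).
#' @param soma_radius_extra Soma radius minus nucleus radius, px.
#' @param min_separation Minimum center separation in px; `NULL` means
#'   non-touching somata (`2 * (max nucleus radius + soma_radius_extra) + 2`).
#' @param bit_depth Acquisition bit depth recorded in the output.
#' @return A list of class `image_spec`.
#' @seealso [gen_image()], [gen_touching_pair()]
#' @export
image_spec <- function(n_cells = 100L,
                       image_shape = c(1024L, 1024L),
                       nucleus_radius = c(6, 9),
                       nucleus_intensity = c(0.7, 0.95),
                       marker_intensity = c(0.15, 0.9),
                       background = c(nuclear = 0.05, marker = 0.05),
                       noise_sd = 0.02,
                       soma_radius_extra = 5,
                       min_separation = NULL,
                       bit_depth = 12L) {
  if (n_cells < 0) stop("`n_cells` must be non-negative")
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop("`image_shape` must be (rows, cols), each >= 8")
  rng <- function(x) if (length(x) == 1L) c(x, x) else sort(x[1:2])
  nucleus_radius <- rng(nucleus_radius)
  if (nucleus_radius[1] < 1) stop("nucleus_radius must be >= 1 px")
  for (nm in c("nucleus_intensity", "marker_intensity")) {
    v <- rng(get(nm))
    if (v[1] < 0 || v[2] > 1) stop(sprintf("`%s` must lie in [0, 1]", nm))
    assign(nm, v)
  }
  if (any(background < 0) || any(background > 1))
    stop("`background` must lie in [0, 1]")
  if (noise_sd < 0 || noise_sd > 1) stop("`noise_sd` must lie in [0, 1]")
  if (soma_radius_extra < 0) stop("`soma_radius_extra` must be >= 0")
  if (is.null(min_separation))
    min_separation <- 2 * (nucleus_radius[2] + soma_radius_extra) + 2
  structure(list(
    n_cells = as.integer(n_cells), image_shape = as.integer(image_shape),
    nucleus_radius = nucleus_radius, nucleus_intensity = nucleus_intensity,
    marker_intensity = marker_intensity,
    background = c(nuclear = unname(background["nuclear"] %||% background[1]),
                   marker = unname(background["marker"] %||% background[2])),
    noise_sd = noise_sd, soma_radius_extra = soma_radius_extra,
    min_separation = min_separation, bit_depth = as.integer(bit_depth)
  ), class = "image_spec")
}

# Noiseless render of a cell table: per channel, each pixel takes the maximum
# of the background and the intensities of all discs covering it.
render_cells <- function(cells, shape, background, soma_radius_extra) {
  nuclear <- matrix(background[["nuclear"]], shape[1], shape[2])
  marker <- matrix(background[["marker"]], shape[1], shape[2])
  if (nrow(cells)) {
    for (i in seq_len(nrow(cells))) {
      paint_disc(nuclear, cells$row[i], cells$col[i], cells$nucleus_radius[i],
                 cells$nucleus_intensity[i]) -> nuclear
      paint_disc(marker, cells$row[i], cells$col[i],
                 cells$nucleus_radius[i] + soma_radius_extra,
                 cells$marker_intensity[i]) -> marker
    }
  }
  list(nuclear = nuclear, marker = marker)
}

# max-composite a filled disc onto a raster (squared-distance test, exact)
paint_disc <- function(img, row, col, radius, intensity) {
  r0 <- max(1L, floor(row - radius)); r1 <- min(nrow(img), ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(ncol(img), ceiling(col + radius))
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  sub <- img[rr, cc, drop = FALSE]
  sub[d2 <= radius^2] <- pmax(sub[d2 <= radius^2], intensity)
  img[rr, cc] <- sub
  img
}

#' Generate a ground-truthed synthetic micrograph
#'
#' Renders the scene described by an [image_spec()] and returns both the image
#' and the exact latent truth used, so downstream segmentation and
#' quantification can be scored by parameter recovery. Cell centers are placed
#' by rejection sampling with the spec's minimum separation; seeded noise is
#' added last and clipped to \[0, 1\]. Identical `(spec, seed)` give
#' bitwise-identical output.
#'
#' @param spec An [image_spec()].
#' @param seed Integer seed; the only source of randomness.
#' @param max_tries Placement attempts per cell before giving up.
#' @return A list with elements `image` ([fluor_image]) and `truth` (a list
#'   with the cell table, background, noise SD, shape, bit depth and seed).
#' @export
gen_image <- function(spec = image_spec(), seed, max_tries = 2000L) {
  stopifnot(inherits(spec, "image_spec"))
  with_seed(seed, {
    shape <- spec$image_shape
    margin <- spec$nucleus_radius[2] + spec$soma_radius_extra + 1
    if (2 * margin >= min(shape) && spec$n_cells > 0)
      stop("image too small for the requested cell geometry")
    cells <- data.frame(row = numeric(0), col = numeric(0),
                        nucleus_radius = numeric(0),
                        nucleus_intensity = numeric(0),
                        marker_intensity = numeric(0))
    if (spec$n_cells > 0) {
      rows <- cols <- numeric(spec$n_cells)
      for (i in seq_len(spec$n_cells)) {
        ok <- FALSE
        for (t in seq_len(max_tries)) {
          r <- runif(1, margin, shape[1] - margin)
          c <- runif(1, margin, shape[2] - margin)
          if (i == 1L || all((rows[seq_len(i - 1)] - r)^2 +
                             (cols[seq_len(i - 1)] - c)^2 >=
                             spec$min_separation^2)) {
            rows[i] <- r; cols[i] <- c; ok <- TRUE; break
          }
        }
        if (!ok)
          stop(sprintf(paste0("could not place cell %d of %d after %d tries; ",
                              "requested packing is infeasible"),
                       i, spec$n_cells, max_tries))
      }
      cells <- data.frame(
        row = rows, col = cols,
        nucleus_radius = runif(spec$n_cells, spec$nucleus_radius[1],
                               spec$nucleus_radius[2]),
        nucleus_intensity = runif(spec$n_cells, spec$nucleus_intensity[1],
                                  spec$nucleus_intensity[2]),
        marker_intensity = runif(spec$n_cells, spec$marker_intensity[1],
                                 spec$marker_intensity[2])
      )
    }
    ch <- render_cells(cells, shape, spec$background, spec$soma_radius_extra)
    if (spec$noise_sd > 0) {
      for (nm in names(ch)) {
        ch[[nm]] <- ch[[nm]] +
          matrix(rnorm(prod(shape), 0, spec$noise_sd), shape[1], shape[2])
        ch[[nm]][ch[[nm]] < 0] <- 0
        ch[[nm]][ch[[nm]] > 1] <- 1
      }
    }
    truth <- list(cells = cells, background = spec$background,
                  noise_sd = spec$noise_sd, image_shape = shape,
                  soma_radius_extra = spec$soma_radius_extra,
                  bit_depth = spec$bit_depth, seed = as.integer(seed))
    list(image = fluor_image(ch, spec$bit_depth), truth = truth)
  })
}

#' Generate a pair of touching or nearly-touching nuclei
#'
#' Fixture generator for the cluster-splitting behaviour of the watershed
#' stage: exactly two nuclei of equal radius with a given center-to-center
#' separation, placed symmetrically about the image center along the column
#' axis.
#'
#' @param separation Center separation in px; must be positive and fit in the
#'   image.
#' @param radius Nucleus radius in px.
#' @param seed Integer seed (noise only).
#' @param image_shape Image shape, default `c(96, 96)`.
#' @param noise_sd Additive noise SD, default 0 (noiseless fixture).
#' @param spec Optional [image_spec()] supplying intensities/background.
#' @return As [gen_image()]: list with `image` and `truth`.
#' @export
gen_touching_pair <- function(separation, radius, seed = 1L,
                              image_shape = c(96L, 96L), noise_sd = 0,
                              spec = NULL) {
  if (separation <= 0) stop("`separation` must be positive")
  if (radius < 1) stop("`radius` must be >= 1 px")
  if (is.null(spec))
    spec <- image_spec(n_cells = 2L, image_shape = image_shape,
                       nucleus_radius = c(radius, radius),
                       noise_sd = noise_sd, min_separation = separation)
  mid <- (spec$image_shape + 1) / 2
  half <- separation / 2
  margin <- radius + spec$soma_radius_extra
  if (mid[2] - half - margin < 1 || mid[2] + half + margin > spec$image_shape[2])
    stop("`separation` (plus soma margin) does not fit in the image")
  with_seed(seed, {
    cells <- data.frame(
      row = c(mid[1], mid[1]), col = c(mid[2] - half, mid[2] + half),
      nucleus_radius = rep(radius, 2),
      nucleus_intensity = rep(mean(spec$nucleus_intensity), 2),
      marker_intensity = runif(2, spec$marker_intensity[1],
                               spec$marker_intensity[2])
    )
    ch <- render_cells(cells, spec$image_shape, spec$background,
                       spec$soma_radius_extra)
    if (noise_sd > 0) {
      for (nm in names(ch)) {
        ch[[nm]] <- ch[[nm]] + matrix(rnorm(prod(spec$image_shape), 0, noise_sd),
                                      spec$image_shape[1], spec$image_shape[2])
        ch[[nm]][ch[[nm]] < 0] <- 0
        ch[[nm]][ch[[nm]] > 1] <- 1
      }
    }
    truth <- list(cells = cells, background = spec$background,
                  noise_sd = noise_sd, image_shape = spec$image_shape,
                  soma_radius_extra = spec$soma_radius_extra,
                  bit_depth = spec$bit_depth, seed = as.integer(seed))
    list(image = fluor_image(ch, spec$bit_depth), truth = truth)
  })
}
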