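# Independent brute-force oracles. These deliberately re-derive results from
# first principles (explicit loops, textbook formulas) and share no code with
# the implementation they check.

# Render a cell table pixel by pixel: per channel, max of background and all
# covering discs.
bf_render <- function(cells, shape, background, soma_extra) {
  nuclear <- matrix(background[["nuclear"]], shape[1], shape[2])
  marker <- matrix(background[["marker"]], shape[1], shape[2])
  for (r in seq_len(shape[1])) for (c in seq_len(shape[2])) {
    for (i in seq_len(nrow(cells))) {
      d2 <- (r - cells$row[i])^2 + (c - cells$col[i])^2
      if (d2 <= cells$nucleus_radius[i]^2)
        nuclear[r, c] <- max(nuclear[r, c], cells$nucleus_intensity[i])
      if (d2 <= (cells$nucleus_radius[i] + soma_extra)^2)
        marker[r, c] <- max(marker[r, c], cells$marker_intensity[i])
    }
  }
  list(nuclear = nuclear, marker = marker)
}

# Exhaustive nearest-background Euclidean distance, image bordered by
# background.
bf_distance_map <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    # nearest virtual background pixel just outside the border
    d_border <- min(r, c, nr + 1 - r, nc + 1 - c)
    d2 <- d_border^2
    if (nrow(bg))
      d2 <- min(d2, min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
    out[r, c] <- sqrt(d2)
  }
  out
}

# Dilation by explicit kernel sweep over every disc offset.
bf_dilate <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  ri <- floor(radius)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    for (dr in -ri:ri) for (dc in -ri:ri) {
      if (dr^2 + dc^2 <= radius^2) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) out[rr, cc] <- TRUE
      }
    }
  }
  out
}

# U statistic by explicit pair counting (a over b, ties half).
bf_u_stat <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# Two-sided permutation p for the U statistic by full enumeration of group
# labelings.
bf_mw_exact_p <- function(a, b) {
  x <- c(a, b); na <- length(a)
  mu <- na * length(b) / 2
  obs <- abs(bf_u_stat(a, b) - mu)
  combs <- combn(length(x), na)
  hits <- 0
  for (j in seq_len(ncol(combs))) {
    u <- bf_u_stat(x[combs[, j]], x[-combs[, j]])
    if (abs(u - mu) >= obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(combs)
}

# Tie-corrected Kruskal-Wallis H from the textbook rank-sum formula, with
# mid-ranks computed by explicit sorting.
bf_kw_h <- function(groups) {
  x <- unlist(groups); grp <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  o <- order(x); r <- numeric(N); sx <- x[o]; i <- 1
  while (i <= N) {
    j <- i
    while (j < N && sx[j + 1] == sx[i]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, grp, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tt <- table(x); ts <- tt[tt > 1]
  corr <- 1 - sum(as.numeric(ts)^3 - as.numeric(ts)) / (N^3 - N)
  h / corr
}

# Match detected cells to truth rows by nearest center; returns truth index
# per detected cell.
match_cells <- function(cells, truth_cells) {
  vapply(seq_len(nrow(cells)), function(i)
    which.min((truth_cells$row - cells$centroid_row[i])^2 +
              (truth_cells$col - cells$centroid_col[i])^2), integer(1))
}

random_mask <- function(nr = 16, nc = 16, p = 0.5) {
  matrix(runif(nr * nc) < p, nr, nc)
}
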