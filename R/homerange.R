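#' Kernel utilisation distribution
#'
#' Bivariate Gaussian product-kernel density of sighting locations on a
#' regular grid padded at least three bandwidths beyond the data extent, with
#' the density normalised so that sum(density) * cell_area = 1. The default
#' bandwidth is the bivariate normal reference ("href") bandwidth
#' \eqn{h = \sigma n^{-1/6}} with \eqn{\sigma^2} the mean of the coordinate
#' variances (Worton-style), the convention of standard home-range software.
#' The 95% isopleth is the smallest set of grid cells containing at least 95%
#' of the probability mass.
#'
#' @param points Two-column matrix/data frame of projected metre coordinates.
#' @param bandwidth `"reference"` or a positive number (metres).
#' @param cell Grid cell side (metres); default `bandwidth / 4`.
#' @param grid Optional list with numeric vectors `x`, `y`: evaluate on this
#'   fixed grid instead (used to put several animals on a common lattice).
#' @param max_cells Upper bound on cells per axis (the cell size is coarsened
#'   to respect it).
#' @return An object of class `ud`: list with grid vectors `x`, `y`, density
#'   matrix `z` (rows = x), `cell_area`, `h`, and logical matrix
#'   `isopleth_95`.
#' @export
kde_ud <- function(points, bandwidth = "reference", cell = NULL, grid = NULL,
                   max_cells = 400) {
  pts <- as.matrix(points)
  if (nrow(pts) < 5)
    stop("insufficient data: kernel home range needs >= 5 points", call. = FALSE)
  if (identical(bandwidth, "reference")) {
    s2 <- (stats::var(pts[, 1]) + stats::var(pts[, 2])) / 2
    h <- sqrt(s2) * nrow(pts)^(-1 / 6)
    if (!is.finite(h) || h <= 0) h <- 1
  } else {
    h <- as.numeric(bandwidth)
    if (!is.finite(h) || h <= 0) stop("bandwidth must be positive", call. = FALSE)
  }
  if (is.null(grid)) {
    if (is.null(cell)) cell <- h / 4
    pad <- 3 * h
    rx <- range(pts[, 1]) + c(-pad, pad)
    ry <- range(pts[, 2]) + c(-pad, pad)
    nx <- min(max_cells, max(20, ceiling(diff(rx) / cell)))
    ny <- min(max_cells, max(20, ceiling(diff(ry) / cell)))
    gx <- seq(rx[1], rx[2], length.out = nx)
    gy <- seq(ry[1], ry[2], length.out = ny)
  } else {
    gx <- grid$x; gy <- grid$y
  }
  ## product kernel: z = (1/n) K_x %*% t(K_y) row-combined per point
  Kx <- outer(gx, pts[, 1], function(g, p) stats::dnorm(g - p, sd = h))
  Ky <- outer(gy, pts[, 2], function(g, p) stats::dnorm(g - p, sd = h))
  z <- (Kx %*% t(Ky)) / nrow(pts)
  cell_area <- mean(diff(gx)) * mean(diff(gy))
  tot <- sum(z) * cell_area
  if (tot <= 0) stop("degenerate density (all mass off-grid)", call. = FALSE)
  z <- z / tot
  ud <- list(x = gx, y = gy, z = z, cell_area = cell_area, h = h)
  ud$isopleth_95 <- ud_isopleth(ud, 0.95)
  class(ud) <- "ud"
  ud
}

#' Smallest cell set holding a given probability mass
#'
#' @param ud A `ud` object.
#' @param level Probability mass (default 0.95).
#' @return Logical matrix marking cells inside the isopleth.
#' @export
ud_isopleth <- function(ud, level = 0.95) {
  p <- as.vector(ud$z) * ud$cell_area
  ord <- order(p, decreasing = TRUE)
  cum <- cumsum(p[ord])
  k <- which(cum >= level)[1]
  keep <- logical(length(p))
  keep[ord[seq_len(k)]] <- TRUE
  matrix(keep, nrow = nrow(ud$z))
}

## bilinear resampling of ud_b's density onto ud_a's grid (renormalised)
.resample_ud <- function(ud, gx, gy) {
  fx <- findInterval(gx, ud$x, all.inside = TRUE)
  fy <- findInterval(gy, ud$y, all.inside = TRUE)
  tx <- (gx - ud$x[fx]) / (ud$x[fx + 1] - ud$x[fx])
  ty <- (gy - ud$y[fy]) / (ud$y[fy + 1] - ud$y[fy])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  inside_x <- gx >= min(ud$x) & gx <= max(ud$x)
  inside_y <- gy >= min(ud$y) & gy <= max(ud$y)
  z <- matrix(0, length(gx), length(gy))
  for (j in seq_along(gy)) {
    if (!inside_y[j]) next
    col <- (1 - ty[j]) * ((1 - tx) * ud$z[cbind(fx, fy[j])] +
                          tx * ud$z[cbind(fx + 1, fy[j])]) +
           ty[j] * ((1 - tx) * ud$z[cbind(fx, fy[j] + 1)] +
                    tx * ud$z[cbind(fx + 1, fy[j] + 1)])
    col[!inside_x] <- 0
    z[, j] <- col
  }
  z
}

#' Volume of intersection between two utilisation distributions
#'
#' \eqn{VI = \sum_{cells} \min(f_a, f_b) \times cell\_area \in [0, 1]}. With
#' `restrict_95 = TRUE` (the default, matching the convention of overlapping
#' *95% home ranges*) each density is first zeroed outside its own 95%
#' isopleth and renormalised; with `FALSE` the full UDs are intersected.
#'
#' @param ud_a,ud_b `ud` objects. If the grids differ, `ud_b` is resampled
#'   onto `ud_a`'s grid by bilinear interpolation (then renormalised).
#' @param restrict_95 Restrict to 95% home ranges first (default TRUE).
#' @return Overlap in `[0, 1]`.
#' @export
volume_intersection <- function(ud_a, ud_b, restrict_95 = TRUE) {
  same_grid <- length(ud_a$x) == length(ud_b$x) &&
    length(ud_a$y) == length(ud_b$y) &&
    isTRUE(all.equal(ud_a$x, ud_b$x)) && isTRUE(all.equal(ud_a$y, ud_b$y))
  za <- ud_a$z
  if (same_grid) {
    zb <- ud_b$z
    iso_b <- ud_b$isopleth_95
  } else {
    zb <- .resample_ud(ud_b, ud_a$x, ud_a$y)
    tot <- sum(zb) * ud_a$cell_area
    if (tot <= 0) stop("grid error: no overlap after resampling", call. = FALSE)
    zb <- zb / tot
    iso_b <- ud_isopleth(list(z = zb, cell_area = ud_a$cell_area), 0.95)
  }
  if (restrict_95) {
    za <- za * ud_a$isopleth_95
    za <- za / (sum(za) * ud_a$cell_area)
    zb <- zb * iso_b
    zb <- zb / (sum(zb) * ud_a$cell_area)
  }
  min(1, sum(pmin(za, zb)) * ud_a$cell_area)
}

#' Pairwise home-range overlap matrix
#'
#' Estimates each individual's utilisation distribution on one common grid
#' spanning all sightings and returns the volume-of-intersection matrix.
#' Individuals with fewer than 5 sightings get `NA` overlaps (they are masked
#' downstream) and are reported.
#'
#' @param sightings Sighting table with `individual_id`, `x`, `y`.
#' @param individuals Ids to include.
#' @param bandwidth Passed to [kde_ud()]; `"reference"` uses the median of
#'   the per-individual reference bandwidths so all animals share one kernel
#'   scale and grid.
#' @param restrict_95 Passed to [volume_intersection()].
#' @param max_cells Grid resolution bound per axis.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
overlap_matrix <- function(sightings, individuals, bandwidth = "reference",
                           restrict_95 = TRUE, max_cells = 200) {
  ids <- sort(unique(individuals))
  sub <- sightings[sightings$individual_id %in% ids, ]
  pts_of <- split(data.frame(x = sub$x, y = sub$y), sub$individual_id)
  counts <- vapply(pts_of, nrow, 0L)[ids]
  ok <- !is.na(counts) & counts >= 5
  if (any(!ok))
    message(sum(!ok), " individuals have < 5 sightings; overlaps set NA")
  if (identical(bandwidth, "reference")) {
    hs <- vapply(pts_of[ids[ok]], function(p) {
      s2 <- (stats::var(p$x) + stats::var(p$y)) / 2
      sqrt(s2) * nrow(p)^(-1 / 6)
    }, 0)
    h <- stats::median(hs, na.rm = TRUE)
    if (!is.finite(h) || h <= 0) h <- 1
  } else h <- as.numeric(bandwidth)
  pad <- 3 * h
  rx <- range(sub$x) + c(-pad, pad)
  ry <- range(sub$y) + c(-pad, pad)
  nx <- min(max_cells, max(50, ceiling(diff(rx) / (h / 4))))
  ny <- min(max_cells, max(50, ceiling(diff(ry) / (h / 4))))
  grid <- list(x = seq(rx[1], rx[2], length.out = nx),
               y = seq(ry[1], ry[2], length.out = ny))
  uds <- lapply(ids, function(id) {
    if (!ok[[id]]) return(NULL)
    kde_ud(pts_of[[id]], bandwidth = h, grid = grid)
  })
  names(uds) <- ids
  n <- length(ids)
  VI <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(VI) <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.null(uds[[i]]) || is.null(uds[[j]])) next
    v <- volume_intersection(uds[[i]], uds[[j]], restrict_95 = restrict_95)
    VI[i, j] <- VI[j, i] <- v
  }
  VI
}
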