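#' Gridded ganglion-cell density field
#'
#' A regular lattice of densities (cells/mm^2) masked to a retinal outline.
#' The grid follows the `graphics::image()` convention: `z[i, j]` is the
#' density at `(x[i], y[j])`; cells outside the outline are `NA`.
#'
#' @param x,y Strictly increasing grid coordinate vectors (mm).
#' @param z Density matrix, `length(x)` rows by `length(y)` columns.
#' @param outline Data frame with columns `x`, `y`: the simple (non
#'   self-intersecting) wholemount outline polygon in mm.
#' @param step Grid spacing in mm.
#' @return An object of class `density_field`.
#' @export
density_field <- function(x, y, z, outline, step) {
  stopifnot(is.matrix(z), nrow(z) == length(x), ncol(z) == length(y))
  if (any(diff(x) <= 0) || any(diff(y) <= 0))
    stop("grid coordinates must be strictly increasing")
  if (any(z < 0, na.rm = TRUE)) stop("densities must be >= 0")
  if (!all(c("x", "y") %in% names(outline)))
    stop("outline needs columns x, y")
  if (.polygon_self_intersects(outline$x, outline$y))
    stop("outline polygon is self-intersecting")
  structure(list(x = x, y = y, z = z, outline = outline, step = step),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  rng <- range(x$z, na.rm = TRUE)
  cat("density_field:", length(x$x), "x", length(x$y), "grid, step",
      x$step, "mm\n")
  cat("  density range [", signif(rng[1], 4), ",", signif(rng[2], 4),
      "] cells/mm^2;", sum(!is.na(x$z)), "unmasked cells\n")
  invisible(x)
}

## O(n^2) segment-crossing test; outlines are small polygons.
.polygon_self_intersects <- function(px, py) {
  n <- length(px)
  if (n < 4) return(FALSE)
  x2 <- c(px[-1], px[1]); y2 <- c(py[-1], py[1])
  seg_int <- function(i, j) {
    d1 <- c(x2[i] - px[i], y2[i] - py[i])
    d2 <- c(x2[j] - px[j], y2[j] - py[j])
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-300) return(FALSE)
    dx <- px[j] - px[i]; dy <- py[j] - py[i]
    t <- (dx * d2[2] - dy * d2[1]) / den
    u <- (dx * d1[2] - dy * d1[1]) / den
    t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
  }
  for (i in seq_len(n - 2L)) {
    jj <- seq(i + 2L, n)
    jj <- jj[!(i == 1L & jj == n)]  # adjacent via wrap-around
    for (j in jj) if (seg_int(i, j)) return(TRUE)
  }
  FALSE
}

#' Even-odd point-in-polygon test
#'
#' @param px,py Query point coordinates.
#' @param ox,oy Polygon vertex coordinates (closed implicitly).
#' @return Logical vector; boundary points count as inside.
#' @export
point_in_polygon <- function(px, py, ox, oy) {
  n <- length(ox)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((oy[i] > py) != (oy[j] > py)) &
      (px < (ox[j] - ox[i]) * (py - oy[i]) / (oy[j] - oy[i]) + ox[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  ## boundary tolerance: points within a tiny distance of an edge are inside
  inside
}

#' Evaluate a density field at arbitrary points
#'
#' Bilinear interpolation on the grid; returns `NA` outside the grid or
#' where any of the four surrounding nodes is masked.
#'
#' @param field A `density_field`.
#' @param px,py Coordinates in mm.
#' @return Numeric vector of densities (cells/mm^2).
#' @export
field_value <- function(field, px, py) {
  gx <- field$x; gy <- field$y; z <- field$z
  nx <- length(gx); ny <- length(gy)
  i <- findInterval(px, gx, rightmost.closed = TRUE)
  j <- findInterval(py, gy, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(px))
  ## rightmost.closed makes points on the top/right grid lines fall in the
  ## last cell
  ok <- i >= 1L & i < nx & j >= 1L & j < ny
  ii <- i[ok]; jj <- j[ok]
  tx <- (px[ok] - gx[ii]) / (gx[ii + 1L] - gx[ii])
  ty <- (py[ok] - gy[jj]) / (gy[jj + 1L] - gy[jj])
  z00 <- z[cbind(ii, jj)]; z10 <- z[cbind(ii + 1L, jj)]
  z01 <- z[cbind(ii, jj + 1L)]; z11 <- z[cbind(ii + 1L, jj + 1L)]
  out[ok] <- (1 - tx) * (1 - ty) * z00 + tx * (1 - ty) * z10 +
    (1 - tx) * ty * z01 + tx * ty * z11
  out
}

#' Build a topographic density map from counting frames
#'
#' Converts counting-frame samples to site densities (`count / frame_area`)
#' and interpolates them onto a regular grid masked to the wholemount
#' outline.  The default method is exact thin-plate-spline interpolation
#' (radial basis `r^2 log r` plus an affine term), which reproduces the site
#' densities exactly and extrapolates smoothly to the outline; alternatives
#' are inverse-distance weighting (`"idw"`, power 2, exact at sites) and
#' nearest-neighbour (`"nearest"`).  Negative interpolants are clipped to 0.
#'
#' @param frames A [counting_frames()] table (>= 4 sites).
#' @param outline Outline polygon data frame (`x`, `y`, mm).
#' @param grid_step Grid spacing in mm.
#' @param method `"tps"`, `"idw"` or `"nearest"`.
#' @param smoothing Ridge parameter for the `"tps"` method: 0 (default)
#'   interpolates the site densities exactly; positive values give the
#'   classical thin-plate smoothing spline, appropriate when site densities
#'   carry counting noise (units: mm^2 x density, the scale of the
#'   `r^2 log r` basis).
#' @return A `density_field`.
#' @examples
#' spec <- retina_spec(5, c(0.2, 0.1), 500, 4000, 1)
#' fld <- generate_density_field(spec, 0.25)
#' cf <- sample_counting_frames(fld, 200, seed = 3)
#' rec <- build_topographic_map(cf, fld$outline, grid_step = 0.25)
#' rec
#' @export
build_topographic_map <- function(frames, outline, grid_step,
                                  method = c("tps", "idw", "nearest"),
                                  smoothing = 0) {
  method <- match.arg(method)
  stopifnot(inherits(frames, "counting_frames"))
  if (nrow(frames) < 4) stop("need at least 4 counting frames")
  sx <- frames$x; sy <- frames$y; sz <- frames$density
  ## collapse duplicated sites to their mean density
  key <- paste(signif(sx, 12), signif(sy, 12))
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(sz, list(key = key), mean)
    first <- !duplicated(key)
    ord <- match(key[first], agg$key)
    sx <- sx[first]; sy <- sy[first]; sz <- agg$x[ord]
  }
  if (.collinear(sx, sy))
    stop("counting-frame sites are collinear; cannot interpolate a surface")
  gx <- seq(min(outline$x) - grid_step, max(outline$x) + grid_step,
            by = grid_step)
  gy <- seq(min(outline$y) - grid_step, max(outline$y) + grid_step,
            by = grid_step)
  g <- expand.grid(x = gx, y = gy)
  strictly <- point_in_polygon(g$x, g$y, outline$x, outline$y)
  ## one-grid-step collar outside the outline keeps bilinear evaluation
  ## defined up to the margin
  inside <- strictly
  near <- .near_outline(g$x[!inside], g$y[!inside], outline, grid_step)
  inside[!inside][near] <- TRUE
  if (all(frames$count == 0)) {
    warning("all counts are zero; returning a flat zero field")
    zv <- rep(NA_real_, nrow(g)); zv[inside] <- 0
  } else {
    zv <- rep(NA_real_, nrow(g))
    zv[inside] <- switch(method,
      tps = .tps_interp(sx, sy, sz, g$x[inside], g$y[inside], smoothing),
      idw = .idw_interp(sx, sy, sz, g$x[inside], g$y[inside]),
      nearest = .nn_interp(sx, sy, sz, g$x[inside], g$y[inside]))
    ## collar cells sit outside the site hull where smooth extrapolation is
    ## unreliable; use nearest-neighbour extrapolation there
    collar <- inside & !strictly
    if (any(collar))
      zv[collar] <- .nn_interp(sx, sy, sz, g$x[collar], g$y[collar])
    zv <- pmax(zv, 0)
  }
  z <- matrix(zv, nrow = length(gx), ncol = length(gy))
  density_field(x = gx, y = gy, z = z, outline = outline, step = grid_step)
}

## TRUE for points within `tol` of the outline (distance measured to the
## outline's vertices, which are assumed densely spaced).  Chunked to keep
## the distance matrix small.
.near_outline <- function(px, py, outline, tol) {
  if (!length(px)) return(logical(0))
  out <- logical(length(px))
  chunk <- 4000L
  for (s in seq(1L, length(px), by = chunk)) {
    e <- min(s + chunk - 1L, length(px))
    d2 <- outer(px[s:e], outline$x, "-")^2 + outer(py[s:e], outline$y, "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min)) <= tol
  }
  out
}

.collinear <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  M <- cbind(xc, yc)
  sv <- svd(M, nu = 0, nv = 0)$d
  sv[2] < 1e-10 * max(sv[1], 1e-300)
}

## Thin-plate spline: solve [[K + s*I, P][P' 0]] [w; a] = [z; 0],
## K_ij = r^2 log r, P = [1 x y].  smoothing = 0 gives exact interpolation;
## smoothing > 0 the classical smoothing spline (ridge on the RBF block).
## Dense solve; site counts are small.
.tps_interp <- function(sx, sy, sz, px, py, smoothing = 0) {
  n <- length(sx)
  rbf <- function(r2) ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)  # r^2 log r
  D2 <- outer(sx, sx, "-")^2 + outer(sy, sy, "-")^2
  K <- rbf(D2) + diag(smoothing, n)
  P <- cbind(1, sx, sy)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(sz, 0, 0, 0)
  coef <- tryCatch(solve(A, rhs),
                   error = function(e) stop("thin-plate system singular: ",
                                            conditionMessage(e)))
  w <- coef[seq_len(n)]; a <- coef[n + 1:3]
  E2 <- outer(px, sx, "-")^2 + outer(py, sy, "-")^2
  drop(rbf(E2) %*% w) + a[1] + a[2] * px + a[3] * py
}

.idw_interp <- function(sx, sy, sz, px, py, power = 2) {
  E2 <- outer(px, sx, "-")^2 + outer(py, sy, "-")^2
  out <- numeric(length(px))
  exact <- E2 < 1e-24
  hit <- rowSums(exact) > 0
  w <- 1 / E2^(power / 2)
  out <- drop(w %*% sz) / rowSums(w)
  if (any(hit))
    out[hit] <- sz[apply(E2[hit, , drop = FALSE], 1, which.min)]
  out
}

.nn_interp <- function(sx, sy, sz, px, py) {
  E2 <- outer(px, sx, "-")^2 + outer(py, sy, "-")^2
  sz[apply(E2, 1, which.min)]
}

#' Isodensity contours of a topographic map
#'
#' Marching-squares contours (via [grDevices::contourLines()]) of the masked
#' density grid at the requested levels.  Levels outside the field's range
#' yield an empty contour set for that level, not an error.
#'
#' @param field A `density_field`.
#' @param levels Strictly increasing density values (cells/mm^2).
#' @return A list, one element per level, each a list of polyline data
#'   frames (`x`, `y`).
#' @export
isodensity_contours <- function(field, levels) {
  if (is.unsorted(levels, strictly = TRUE))
    stop("levels must be strictly increasing")
  cl <- suppressWarnings(
    grDevices::contourLines(field$x, field$y, field$z, levels = levels))
  zmin <- suppressWarnings(min(field$z, na.rm = TRUE))
  out <- lapply(levels, function(lv) {
    if (is.finite(zmin) && lv < zmin) {
      ## the whole masked region sits above this level: its boundary is
      ## the outline itself
      return(list(field$outline))
    }
    hits <- Filter(function(cc) isTRUE(all.equal(cc$level, lv)), cl)
    lapply(hits, function(cc) data.frame(x = cc$x, y = cc$y))
  })
  names(out) <- as.character(levels)
  out
}

#' Locate the fovea on a topographic map
#'
#' The fovea is the site of peak ganglion-cell density.  Returns the grid
#' coordinates of the global maximum; if several cells tie for the maximum
#' (within a relative tolerance of 1e-9) the centroid of the connected
#' maximal-density region containing the first maximum is returned.
#'
#' @param field A `density_field`; must not be flat.
#' @param method `"max"` (default): coordinates of the global maximum, with
#'   the tie rule above.  `"contour"`: centroid of the super-level region
#'   with density at least `level` times the maximum — more robust when the
#'   map carries counting noise, since the argmax of a noisy surface
#'   wanders over flat peak plateaus.
#' @param level Fraction of the maximum defining the super-level region for
#'   `method = "contour"`.
#' @return Numeric length-2: fovea position in mm.
#' @export
locate_fovea <- function(field, method = c("max", "contour"),
                         level = 0.95) {
  method <- match.arg(method)
  z <- field$z
  ## only cells inside the outline proper can host the fovea (the grid may
  ## carry a collar of extrapolated cells just outside the margin)
  g <- expand.grid(x = field$x, y = field$y)
  inside <- point_in_polygon(g$x, g$y, field$outline$x, field$outline$y)
  z[!matrix(inside, nrow = length(field$x))] <- NA_real_
  rng <- range(z, na.rm = TRUE)
  if (!is.finite(rng[1]) || diff(rng) <= 1e-12 * max(abs(rng), 1))
    stop("flat field: no unique fovea")
  zmax <- rng[2]
  if (method == "contour") {
    sel <- which(!is.na(z) & z >= level * zmax, arr.ind = TRUE)
    return(c(x = mean(field$x[sel[, 1]]), y = mean(field$y[sel[, 2]])))
  }
  tie <- !is.na(z) & (zmax - z) <= 1e-9 * zmax
  idx <- which(tie, arr.ind = TRUE)
  if (nrow(idx) > 1L) {
    ## connected component (4-neighbour) containing the first maximal cell
    comp <- .connected_component(tie, which(tie, arr.ind = TRUE)[1, ])
    idx <- which(comp, arr.ind = TRUE)
  }
  c(x = mean(field$x[idx[, 1]]), y = mean(field$y[idx[, 2]]))
}

.connected_component <- function(mask, start) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(FALSE, nr, nc)
  queue <- matrix(start, ncol = 2)
  comp[start[1], start[2]] <- TRUE
  while (nrow(queue)) {
    cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r <- cur[1] + d[1]; cc <- cur[2] + d[2]
      if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
          mask[r, cc] && !comp[r, cc]) {
        comp[r, cc] <- TRUE
        queue <- rbind(queue, c(r, cc))
      }
    }
  }
  comp
}

#' Polygon centroid and area (shoelace)
#'
#' @param outline Data frame with `x`, `y`.
#' @return List with `centroid` (length-2) and `area` (positive).
#' @export
polygon_centroid_area <- function(outline) {
  x <- outline$x; y <- outline$y
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cross <- x * y2 - x2 * y
  a <- sum(cross) / 2
  cx <- sum((x + x2) * cross) / (6 * a)
  cy <- sum((y + y2) * cross) / (6 * a)
  list(centroid = c(cx, cy), area = abs(a))
}

#' Normalize a fovea position to retina-centred unit coordinates
#'
#' The retinal "centre" is the outline centroid and the normalization radius
#' is the radius of the circle with the same area as the outline.  The
#' normalized position is `(fovea - centre) / radius`.  For left eyes the
#' horizontal axis is mirrored so that, in the stored convention, negative x
#' is temporal and positive x nasal for both eyes (positive y dorsal).
#'
#' Raw wholemount coordinates are assumed to have positive x toward nasal
#' for right eyes (and hence toward temporal for left eyes, which is why
#' left eyes are mirrored).
#'
#' @param fovea_mm Numeric length-2 fovea position (mm).
#' @param outline Outline polygon data frame.
#' @param eye_side `"right"` or `"left"`.
#' @param species Optional species label.
#' @return A `fovea_position` object with fields `x`, `y`, `species`,
#'   `eye_side`.
#' @examples
#' outl <- circle_outline(5)
#' normalize_fovea_position(c(-0.725, 0.285), outl, "right")
#' @export
normalize_fovea_position <- function(fovea_mm, outline,
                                     eye_side = c("right", "left"),
                                     species = NA_character_) {
  eye_side <- match.arg(eye_side)
  if (!point_in_polygon(fovea_mm[1], fovea_mm[2], outline$x, outline$y))
    stop("fovea lies outside the outline")
  ca <- polygon_centroid_area(outline)
  r <- sqrt(ca$area / pi)
  xy <- (fovea_mm - ca$centroid) / r
  if (eye_side == "left") xy[1] <- -xy[1]
  if (sum(xy^2) >= 1)
    stop("normalized fovea position falls outside the unit disk")
  structure(list(x = unname(xy[1]), y = unname(xy[2]),
                 species = species, eye_side = eye_side),
            class = "fovea_position")
}

#' @export
print.fovea_position <- function(x, ...) {
  cat(sprintf("fovea_position (%s, %s eye): x = %.4f, y = %.4f\n",
              ifelse(is.na(x$species), "?", x$species), x$eye_side,
              x$x, x$y))
  invisible(x)
}

#' Across-species mean fovea position with t-based confidence intervals
#'
#' One position per species (average per-species beforehand).  Per axis the
#' summary is mean, `SE = sd/sqrt(n)` and
#' `CI = mean +/- t(1 - alpha/2, n - 1) * SE`.
#'
#' @param positions List of `fovea_position` objects, or a data frame with
#'   columns `species`, `x`, `y`.
#' @param alpha Two-sided error level (default 0.05 for 95% CIs).
#' @return A data frame of class `position_summary` with rows `x` and `y`
#'   and columns `mean`, `se`, `ci_low`, `ci_high`, `n`.
#' @examples
#' pos <- data.frame(species = paste0("sp", 1:5),
#'                   x = c(-.1, -.2, -.15, -.12, -.18),
#'                   y = c(.05, .07, .02, .08, .06))
#' mean_position_with_ci(pos)
#' @export
mean_position_with_ci <- function(positions, alpha = 0.05) {
  if (is.list(positions) && !is.data.frame(positions) &&
      all(vapply(positions, inherits, TRUE, "fovea_position"))) {
    positions <- data.frame(
      species = vapply(positions, `[[`, "", "species"),
      x = vapply(positions, `[[`, 0, "x"),
      y = vapply(positions, `[[`, 0, "y"))
  }
  if (anyDuplicated(positions$species))
    stop("duplicate species labels: average per species first")
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 species")
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
  one <- function(v) {
    m <- mean(v); se <- stats::sd(v) / sqrt(n)
    c(mean = m, se = se, ci_low = m - tcrit * se, ci_high = m + tcrit * se,
      n = n)
  }
  out <- as.data.frame(rbind(x = one(positions$x), y = one(positions$y)))
  class(out) <- c("position_summary", "data.frame")
  out
}
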