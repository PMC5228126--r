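#' Specification of a synthetic wholemount retina
#'
#' Describes a circular retinal wholemount with a single foveal density peak.
#' Ganglion-cell density rises from `base_density` at the retinal margin to
#' `peak_density` at the fovea.  The fall-off from fovea to margin follows
#' `density(d) = base + (peak - base) * (1 - d)^s`, where `d` is the
#' fovea-to-margin normalized distance (0 at the fovea, 1 on the margin) and
#' `s` a per-quadrant steepness exponent: `s = 1` gives a smooth linear
#' profile, large `s` a steep one in which density collapses quickly away
#' from the fovea.  Quadrants are the four 90-degree angular sectors centred
#' on the nasal, temporal, dorsal and ventral rays emanating from the fovea,
#' so each transect axis runs through the interior of its own sector.
#'
#' The wholemount plane uses the convention of a right eye after side
#' normalization: positive x is nasal, negative x temporal, positive y
#' dorsal, negative y ventral.
#'
#' @param radius Retinal radius in mm (circular outline centred at the
#'   origin).
#' @param fovea_xy Numeric length-2, normalized fovea position (unit-disk
#'   coordinates, each component in (-1, 1), strictly inside the disk).
#' @param base_density Density at the margin, cells/mm^2.
#' @param peak_density Density at the fovea, cells/mm^2; must be >=
#'   `base_density`.
#' @param quadrant_steepness Named numeric length-4 with names `nasal`,
#'   `temporal`, `dorsal`, `ventral`; positive shape exponents.  A single
#'   unnamed value is recycled to all four.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   density noise applied cell-wise to the generated field (>= 0; 0 means
#'   noiseless).
#' @param seed Integer RNG seed used by [generate_density_field()] when
#'   `noise_cv > 0`.
#' @return An object of class `retina_spec`.
#' @examples
#' spec <- retina_spec(radius = 5, fovea_xy = c(-0.145, 0.057),
#'                     base_density = 500, peak_density = 4000,
#'                     quadrant_steepness = c(nasal = 1, temporal = 1.5,
#'                                            dorsal = 2, ventral = 1.2))
#' spec
#' @export
retina_spec <- function(radius, fovea_xy, base_density, peak_density,
                        quadrant_steepness = 1, noise_cv = 0, seed = 1L) {
  stopifnot(is.numeric(radius), length(radius) == 1L)
  if (radius <= 0) stop("radius must be > 0")
  fovea_xy <- as.numeric(fovea_xy)
  if (length(fovea_xy) != 2L || anyNA(fovea_xy))
    stop("fovea_xy must be two finite numbers")
  if (sum(fovea_xy^2) >= 1)
    stop("fovea must lie strictly inside the retina (unit disk): got (",
         fovea_xy[1], ", ", fovea_xy[2], ")")
  if (base_density <= 0 || peak_density < base_density)
    stop("densities must satisfy peak_density >= base_density > 0")
  axes <- c("nasal", "temporal", "dorsal", "ventral")
  if (length(quadrant_steepness) == 1L && is.null(names(quadrant_steepness)))
    quadrant_steepness <- stats::setNames(rep(quadrant_steepness, 4), axes)
  if (!all(axes %in% names(quadrant_steepness)))
    stop("quadrant_steepness needs names: ", paste(axes, collapse = ", "))
  quadrant_steepness <- quadrant_steepness[axes]
  if (any(quadrant_steepness <= 0)) stop("quadrant_steepness must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(
    list(radius = radius, fovea_xy = fovea_xy, base_density = base_density,
         peak_density = peak_density,
         quadrant_steepness = quadrant_steepness,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "retina_spec")
}

#' @export
print.retina_spec <- function(x, ...) {
  cat("retina_spec: radius", x$radius, "mm, fovea at (",
      x$fovea_xy[1], ",", x$fovea_xy[2], ") [normalized]\n")
  cat("  density", x$base_density, "->", x$peak_density, "cells/mm^2\n")
  cat("  steepness:", paste(names(x$quadrant_steepness),
                            signif(x$quadrant_steepness, 3),
                            sep = "=", collapse = " "), "\n")
  cat("  noise_cv", x$noise_cv, " seed", x$seed, "\n")
  invisible(x)
}

## Sector of each point relative to the fovea: 90-degree sectors centred on
## the +x (nasal), -x (temporal), +y (dorsal), -y (ventral) rays.
.quadrant_of <- function(dx, dy) {
  horiz <- abs(dx) >= abs(dy)
  out <- ifelse(horiz, ifelse(dx >= 0, "nasal", "temporal"),
                ifelse(dy >= 0, "dorsal", "ventral"))
  out
}

## Normalized fovea-to-margin distance for points p (matrix nx2, mm) given
## fovea f (mm) on a circular outline of radius R centred at the origin:
## the ray from f through p meets the circle at distance L; d = |p-f| / L.
.dnorm_circle <- function(px, py, fx, fy, R) {
  dx <- px - fx; dy <- py - fy
  r <- sqrt(dx^2 + dy^2)
  ux <- ifelse(r > 0, dx / r, 1); uy <- ifelse(r > 0, dy / r, 0)
  b <- fx * ux + fy * uy
  L <- -b + sqrt(b^2 + R^2 - (fx^2 + fy^2))
  pmin(r / L, 1)
}

## Noiseless density of a retina_spec at arbitrary mm coordinates.
## Vectorized over px, py.  NA beyond `collar` mm outside the outline
## (a one-grid-step collar at margin density keeps bilinear evaluation
## defined all the way to the margin).
.true_density <- function(spec, px, py, collar = 0) {
  R <- spec$radius
  f <- spec$fovea_xy * R
  d <- .dnorm_circle(px, py, f[1], f[2], R)
  q <- .quadrant_of(px - f[1], py - f[2])
  s <- spec$quadrant_steepness[q]
  dens <- unname(spec$base_density +
    (spec$peak_density - spec$base_density) * (1 - d)^s)
  dens[sqrt(px^2 + py^2) > R + collar + 1e-12] <- NA_real_
  dens
}

#' Generate a gridded ganglion-cell density field from a retina specification
#'
#' Evaluates the parametric density surface of a [retina_spec()] on a regular
#' grid masked to the circular outline.  If `spec$noise_cv > 0`,
#' multiplicative lognormal noise with unit mean and the requested
#' coefficient of variation is applied cell-wise (one RNG draw per unmasked
#' grid cell, in column-major order, seeded from `spec$seed`).
#'
#' @param spec A [retina_spec()].
#' @param grid_step Grid spacing in mm; must be smaller than `radius / 10`.
#' @return A `density_field` (see [density_field()]).
#' @examples
#' spec <- retina_spec(5, c(0, 0), 500, 4000, 1)
#' fld <- generate_density_field(spec, grid_step = 0.25)
#' range(fld$z, na.rm = TRUE)
#' @export
generate_density_field <- function(spec, grid_step) {
  stopifnot(inherits(spec, "retina_spec"))
  if (grid_step >= spec$radius / 10)
    stop("grid_step must be < radius/10")
  R <- spec$radius
  gx <- seq(-R - grid_step, R + grid_step, by = grid_step)
  gy <- seq(-R - grid_step, R + grid_step, by = grid_step)
  pts <- expand.grid(x = gx, y = gy)
  dens <- .true_density(spec, pts$x, pts$y, collar = grid_step)
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    ok <- !is.na(dens)
    old <- .Random.seed_save()
    set.seed(spec$seed)
    dens[ok] <- dens[ok] * stats::rlnorm(sum(ok), -sdlog^2 / 2, sdlog)
    .Random.seed_restore(old)
  }
  z <- matrix(dens, nrow = length(gx), ncol = length(gy))
  outline <- circle_outline(R, n = 256L)
  density_field(x = gx, y = gy, z = z, outline = outline, step = grid_step)
}

## save/restore the global RNG state so seeded generators do not perturb
## the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
}

#' Circular retinal outline polygon
#'
#' @param radius Radius in mm.
#' @param n Number of vertices.
#' @param center Numeric length-2 centre (mm).
#' @return A data frame with columns `x`, `y` (closed implicitly; the last
#'   vertex differs from the first).
#' @export
circle_outline <- function(radius, n = 256L, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  data.frame(x = center[1] + radius * cos(th),
             y = center[2] + radius * sin(th))
}

#' Sample stereology-style counting frames from a density field
#'
#' Draws `n_sites` sampling sites inside the field's outline (uniformly at
#' random, or on a regular lattice) and simulates the ganglion-cell count in
#' a square counting frame at each site as
#' `count ~ Poisson(density * frame_area)`, where `frame_area =
#' (frame_side/1000)^2` mm^2.  Densities are read off the field by bilinear
#' interpolation.
#'
#' Draw order with `layout = "uniform"`: candidate site coordinates are drawn
#' in rejection-sampling batches (x then y), then one Poisson draw per
#' accepted site in site order.
#'
#' @param field A `density_field`.
#' @param n_sites Number of sites (>= 4).
#' @param frame_side Counting-frame side length in micrometres (default 50).
#' @param frames_per_site Number of counting frames pooled at each site
#'   (default 1); the recorded count is the Poisson total over all frames
#'   and the site density estimate is `count / (frames_per_site * area)`.
#' @param seed Integer RNG seed.
#' @param layout `"uniform"` (random) or `"lattice"` (regular grid clipped
#'   to the outline; the realized number of sites is the largest lattice
#'   count not exceeding `n_sites`... see Details).
#' @details With `layout = "lattice"` the function chooses the finest square
#'   lattice whose in-outline site count does not exceed `n_sites`, so the
#'   realized number of sites can be slightly below `n_sites`.
#' @return A `counting_frames` data frame with columns `x`, `y` (mm),
#'   `frame_side` (um), `count`.
#' @examples
#' spec <- retina_spec(5, c(0.2, 0.1), 500, 4000, 1)
#' fld <- generate_density_field(spec, 0.25)
#' cf <- sample_counting_frames(fld, n_sites = 100, seed = 42)
#' head(cf)
#' @export
sample_counting_frames <- function(field, n_sites, frame_side = 50,
                                   frames_per_site = 1L, seed = 1L,
                                   layout = c("uniform", "lattice")) {
  stopifnot(inherits(field, "density_field"))
  layout <- match.arg(layout)
  if (n_sites < 4) stop("n_sites must be >= 4")
  if (frame_side <= 0) stop("frame_side must be > 0")
  ox <- field$outline$x; oy <- field$outline$y
  span <- min(diff(range(ox)), diff(range(oy)))
  if (frame_side / 1000 > span)
    stop("counting frame (", frame_side, " um) larger than the retina")
  old <- .Random.seed_save()
  set.seed(seed)
  if (layout == "uniform") {
    xs <- ys <- numeric(0)
    bb <- c(range(ox), range(oy))
    while (length(xs) < n_sites) {
      m <- 2L * (n_sites - length(xs)) + 8L
      cx <- stats::runif(m, bb[1], bb[2])
      cy <- stats::runif(m, bb[3], bb[4])
      keep <- point_in_polygon(cx, cy, ox, oy) &
        !is.na(field_value(field, cx, cy))
      xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
    }
    xs <- xs[seq_len(n_sites)]; ys <- ys[seq_len(n_sites)]
  } else {
    ## finest k x k lattice whose in-outline count does not exceed n_sites
    lattice_sites <- function(k) {
      gx <- seq(min(ox), max(ox), length.out = k)
      gy <- seq(min(oy), max(oy), length.out = k)
      g <- expand.grid(x = gx, y = gy)
      keep <- point_in_polygon(g$x, g$y, ox, oy) &
        !is.na(field_value(field, g$x, g$y))
      g[keep, , drop = FALSE]
    }
    k <- max(2L, as.integer(floor(sqrt(n_sites / 2))))
    g <- lattice_sites(k)
    while (TRUE) {
      g2 <- lattice_sites(k + 1L)
      if (nrow(g2) > n_sites) break
      k <- k + 1L; g <- g2
    }
    xs <- g$x; ys <- g$y
    if (length(xs) < 4) stop("lattice produced fewer than 4 in-outline sites")
  }
  dens <- field_value(field, xs, ys)
  area <- (frame_side / 1000)^2
  counts <- stats::rpois(length(xs), dens * area * frames_per_site)
  .Random.seed_restore(old)
  counting_frames(x = xs, y = ys, frame_side = frame_side, count = counts,
                  n_frames = frames_per_site)
}

#' Construct a counting-frame table
#'
#' @param x,y Site coordinates in mm.
#' @param frame_side Frame side length(s) in micrometres.
#' @param count Non-negative integer cell counts (pooled over
#'   `n_frames` frames at the site).
#' @param n_frames Frames pooled per site (default 1).
#' @return A data frame of class `counting_frames` with a `density` column
#'   (cells/mm^2) computed as `count / (n_frames * (frame_side/1000)^2)`.
#' @export
counting_frames <- function(x, y, frame_side, count, n_frames = 1L) {
  if (any(count < 0)) stop("counts must be >= 0")
  if (any(frame_side <= 0)) stop("frame_side must be > 0")
  if (any(n_frames < 1)) stop("n_frames must be >= 1")
  df <- data.frame(x = x, y = y, frame_side = frame_side,
                   count = as.integer(round(count)),
                   n_frames = as.integer(n_frames))
  df$density <- df$count / (df$n_frames * (df$frame_side / 1000)^2)
  class(df) <- c("counting_frames", "data.frame")
  df
}

#' Specification of a phylogenetic trait simulation
#'
#' Traits are generated as `y = beta0 + beta1 * x + e` with `e` multivariate
#' normal, covariance `sigma2 * V(lambda)`, where `V` is the Brownian-motion
#' shared-path-length matrix of the tree and `lambda` scales its
#' off-diagonal entries (Pagel's lambda).
#'
#' @param tree A rooted `phylo` tree with branch lengths and unique tips.
#' @param beta0,beta1 Regression intercept and coefficient.
#' @param lambda_true Pagel's lambda in \[0, 1\].
#' @param sigma2 Brownian-motion rate (trait units^2 per unit branch
#'   length), >= 0.
#' @param seed Integer RNG seed.
#' @return An object of class `trait_sim_spec`.
#' @export
trait_sim_spec <- function(tree, beta0 = 0, beta1 = 1, lambda_true = 1,
                           sigma2 = 1, seed = 1L) {
  tree <- .validate_tree(tree)
  if (lambda_true < 0 || lambda_true > 1) stop("lambda_true must be in [0, 1]")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  structure(list(tree = tree, beta0 = beta0, beta1 = beta1,
                 lambda_true = lambda_true, sigma2 = sigma2,
                 seed = as.integer(seed)),
            class = "trait_sim_spec")
}

#' Simulate species traits on a phylogeny
#'
#' Generates one trait value per tip as a linear function of a per-species
#' predictor plus phylogenetically correlated error (Brownian motion scaled
#' by Pagel's lambda).  Draw order: a single block of `n` standard-normal
#' deviates in tip order, premultiplied by the Cholesky factor of
#' `sigma2 * V(lambda)`.
#'
#' @param spec A [trait_sim_spec()].
#' @param predictor Named numeric vector keyed by tip label; must cover all
#'   tips of `spec$tree`.
#' @return A data frame with columns `species`, `predictor`, `trait`, in
#'   tree tip order.
#' @examples
#' tr <- ape::rtree(8)
#' sp <- trait_sim_spec(tr, beta0 = 1, beta1 = 0.5, lambda_true = 1,
#'                      sigma2 = 0.2, seed = 7)
#' x <- stats::setNames(rnorm(8), tr$tip.label)
#' simulate_traits_on_tree(sp, x)
#' @export
simulate_traits_on_tree <- function(spec, predictor) {
  stopifnot(inherits(spec, "trait_sim_spec"))
  tips <- spec$tree$tip.label
  missing <- setdiff(tips, names(predictor))
  if (length(missing))
    stop("predictor missing species: ", paste(missing, collapse = ", "))
  x <- predictor[tips]
  n <- length(tips)
  mu <- spec$beta0 + spec$beta1 * x
  if (spec$sigma2 == 0) {
    y <- mu
  } else {
    V <- lambda_transform(bm_vcv(spec$tree), spec$lambda_true)
    L <- chol(spec$sigma2 * V)  # upper triangular: V = t(L) %*% L
    old <- .Random.seed_save()
    set.seed(spec$seed)
    z <- stats::rnorm(n)
    .Random.seed_restore(old)
    y <- mu + drop(t(L) %*% z)
  }
  data.frame(species = tips, predictor = unname(x), trait = unname(y))
}

.validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}
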