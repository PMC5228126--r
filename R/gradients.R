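#' Lay periphery-to-fovea transects along the four retinal axes
#'
#' One transect per retinal axis (nasal, temporal, dorsal, ventral), each
#' running from the point where the axis ray from the fovea meets the
#' outline (the margin end) to the fovea.  Horizontal rays give the nasal
#' (+x) and temporal (-x) transects, vertical rays the dorsal (+y) and
#' ventral (-y) transects.
#'
#' @param field A `density_field`.
#' @param fovea Fovea position in mm (numeric length-2), strictly inside the
#'   outline.
#' @return A named list of four transects, each a list with `axis`,
#'   `margin` (mm), `fovea` (mm) and `length` (mm).
#' @export
lay_transects <- function(field, fovea) {
  ox <- field$outline$x; oy <- field$outline$y
  if (!point_in_polygon(fovea[1], fovea[2], ox, oy))
    stop("fovea must lie strictly inside the outline")
  dirs <- list(nasal = c(1, 0), temporal = c(-1, 0),
               dorsal = c(0, 1), ventral = c(0, -1))
  out <- lapply(names(dirs), function(ax) {
    u <- dirs[[ax]]
    t_hit <- .ray_polygon_distance(fovea, u, ox, oy)
    if (!is.finite(t_hit) || t_hit <= field$step / 2)
      stop("fovea is on (or too close to) the outline along the ", ax,
           " axis")
    margin <- fovea + t_hit * u
    list(axis = ax, margin = margin, fovea = fovea, length = t_hit)
  })
  names(out) <- names(dirs)
  out
}

## Distance from point p along unit direction u to the nearest crossing of
## the polygon boundary.
.ray_polygon_distance <- function(p, u, ox, oy) {
  n <- length(ox)
  x2 <- c(ox[-1], ox[1]); y2 <- c(oy[-1], oy[1])
  ex <- x2 - ox; ey <- y2 - oy
  den <- u[1] * ey - u[2] * ex
  dx <- ox - p[1]; dy <- oy - p[2]
  t <- (dx * ey - dy * ex) / den
  s <- (u[2] * dx - u[1] * dy) / den
  ok <- is.finite(t) & is.finite(s) & t > 0 & s >= -1e-12 & s <= 1 + 1e-12
  if (!any(ok)) return(NA_real_)
  min(t[ok])
}

#' Sample densities along a transect
#'
#' Places `n_points` equally spaced sampling positions from the margin end
#' (normalized distance 0) to the fovea (distance 1) and records at each
#' the field density averaged over a small disk of radius one grid step
#' (the disk average uses the centre plus eight points on the disk rim,
#' evaluated by bilinear interpolation; rim points falling in the masked
#' region are ignored).  Positions whose centre falls in the masked region
#' are dropped with a warning.
#'
#' @param field A `density_field`.
#' @param transect One element of [lay_transects()] output.
#' @param n_points Number of sampling positions (>= 3).
#' @return A `transect_profile` data frame with columns `distance`
#'   (normalized, 0 = margin, 1 = fovea) and `density` (10^3 cells/mm^2),
#'   with attribute `axis`.
#' @export
sample_transect <- function(field, transect, n_points = 10) {
  if (n_points < 3) stop("n_points must be >= 3")
  tt <- seq(0, 1, length.out = n_points)
  px <- transect$margin[1] + tt * (transect$fovea[1] - transect$margin[1])
  py <- transect$margin[2] + tt * (transect$fovea[2] - transect$margin[2])
  r <- field$step
  ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
  centre <- field_value(field, px, py)
  ring <- sapply(ang, function(a)
    field_value(field, px + r * cos(a), py + r * sin(a)))
  if (n_points == 1L) ring <- matrix(ring, nrow = 1L)
  vals <- rowMeans(cbind(centre, ring), na.rm = TRUE)
  vals[is.na(centre)] <- NA_real_
  keep <- !is.na(vals)
  if (any(!keep))
    warning(sum(!keep), " transect point(s) fell in the masked region and ",
            "were dropped (", transect$axis, ")")
  if (sum(keep) < 3)
    stop("fewer than 3 transect points survive masking (", transect$axis,
         ")")
  out <- data.frame(distance = tt[keep], density = vals[keep] / 1000)
  attr(out, "axis") <- transect$axis
  class(out) <- c("transect_profile", "data.frame")
  out
}

#' Fit the linear density-gradient slope of a transect profile
#'
#' Ordinary least squares of density (10^3 cells/mm^2) on normalized
#' distance.  The slope is the retinal-configuration proxy: the rate of
#' ganglion-cell density change from the retinal periphery (distance 0) to
#' the fovea (distance 1).
#'
#' @param profile A `transect_profile`.
#' @param species Optional species label carried into the estimate.
#' @return A `slope_estimate` list with `axis`, `slope`, `intercept`, `r2`,
#'   `species`, and `flat` (TRUE when the profile had zero density variance,
#'   in which case r2 is reported as 0).
#' @examples
#' prof <- structure(data.frame(distance = seq(0, 1, length.out = 10),
#'                              density = seq(0.5, 4.0, length.out = 10)),
#'                   class = c("transect_profile", "data.frame"))
#' attr(prof, "axis") <- "nasal"
#' fit_gradient_slope(prof)$slope  # 3.5
#' @export
fit_gradient_slope <- function(profile, species = NA_character_) {
  stopifnot(inherits(profile, "transect_profile"))
  d <- profile$distance; y <- profile$density
  if (stats::var(d) <= 0) stop("zero variance in transect distances")
  fit <- stats::lm(y ~ d)
  flat <- stats::var(y) <= 1e-24
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (flat) 0 else 1 - rss / tss
  structure(list(axis = attr(profile, "axis"),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, species = species, flat = flat),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("slope_estimate [%s%s]: slope = %.4f, intercept = %.4f, r2 = %.3f%s\n",
              x$axis,
              ifelse(is.na(x$species), "", paste0(", ", x$species)),
              x$slope, x$intercept, x$r2,
              ifelse(isTRUE(x$flat), " (flat profile)", "")))
  invisible(x)
}

#' Overall gradient slope across the four retinal axes
#'
#' Arithmetic mean of the nasal, temporal, dorsal and ventral slopes.
#'
#' @param estimates List of four `slope_estimate` objects, exactly one per
#'   axis.
#' @return A `slope_estimate` with `axis = "overall"` (intercept and r2 are
#'   the means of the per-axis values).
#' @export
overall_slope <- function(estimates) {
  axes <- vapply(estimates, `[[`, "", "axis")
  need <- c("nasal", "temporal", "dorsal", "ventral")
  missing <- setdiff(need, axes)
  if (length(missing))
    stop("missing axis estimate(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(axes)) stop("duplicate axis estimates")
  sp <- unique(stats::na.omit(vapply(estimates, `[[`, "", "species")))
  structure(list(axis = "overall",
                 slope = mean(vapply(estimates, `[[`, 0, "slope")),
                 intercept = mean(vapply(estimates, `[[`, 0, "intercept")),
                 r2 = mean(vapply(estimates, `[[`, 0, "r2")),
                 species = if (length(sp) == 1L) sp else NA_character_,
                 flat = all(vapply(estimates, `[[`, TRUE, "flat"))),
            class = "slope_estimate")
}

#' Per-axis and overall gradient slopes of one retina
#'
#' Convenience wrapper: locates (or accepts) the fovea, lays the four
#' transects, samples them and fits the four axis slopes plus the overall
#' mean slope.
#'
#' @param field A `density_field`.
#' @param fovea Optional fovea position (mm); located with [locate_fovea()]
#'   when omitted.
#' @param n_points Sampling positions per transect.
#' @param species Optional species label.
#' @return A named list of five `slope_estimate`s
#'   (`nasal`, `temporal`, `dorsal`, `ventral`, `overall`).
#' @export
transect_slopes <- function(field, fovea = NULL, n_points = 10,
                            species = NA_character_) {
  if (is.null(fovea)) fovea <- locate_fovea(field)
  tr <- lay_transects(field, fovea)
  ests <- lapply(tr, function(t1)
    fit_gradient_slope(sample_transect(field, t1, n_points), species))
  ests$overall <- overall_slope(ests)
  ests
}

#' Tabulate per-species slopes
#'
#' @param slopes_list Named list (by species) of [transect_slopes()]
#'   results.
#' @return Data frame with columns `species`, `nasal`, `temporal`,
#'   `dorsal`, `ventral`, `overall` (slope units: 10^3 cells/mm^2 per unit
#'   normalized distance).
#' @export
slope_table <- function(slopes_list) {
  rows <- lapply(names(slopes_list), function(sp) {
    e <- slopes_list[[sp]]
    data.frame(species = sp,
               nasal = e$nasal$slope, temporal = e$temporal$slope,
               dorsal = e$dorsal$slope, ventral = e$ventral$slope,
               overall = e$overall$slope)
  })
  do.call(rbind, rows)
}
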