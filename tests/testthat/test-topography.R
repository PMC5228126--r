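test_that("uniform site densities interpolate to a constant field", {
  set.seed(2)
  outl <- circle_outline(5)
  th <- runif(30, 0, 2 * pi); r <- sqrt(runif(30)) * 4.5
  cf <- counting_frames(r * cos(th), r * sin(th), 50,
                        rep(10, 30))
  for (m in c("tps", "idw", "nearest")) {
    fld <- build_topographic_map(cf, outl, 0.5, method = m)
    expect_lt(max(abs(fld$z - 4000), na.rm = TRUE), 1e-6)
  }
})

test_that("site density is count over frame area", {
  cf <- counting_frames(x = 0, y = 0, frame_side = 50, count = 10)
  expect_equal(cf$density, 4000)
})

test_that("the default method reproduces site densities exactly", {
  set.seed(9)
  th <- runif(40, 0, 2 * pi); r <- sqrt(runif(40)) * 4
  sx <- r * cos(th); sy <- r * sin(th)
  sz <- 500 + 3500 * runif(40)
  cf <- counting_frames(sx, sy, 50, round(sz * 0.0025))
  fld <- build_topographic_map(cf, circle_outline(5), 0.25)
  at_sites <- field_value(fld, sx, sy)
  ## bilinear read-back from the grid is itself approximate; evaluate the
  ## interpolant directly instead
  direct <- retgrad:::.tps_interp(sx, sy, cf$density, sx, sy)
  expect_equal(direct, cf$density, tolerance = 1e-8)
  expect_false(any(is.na(at_sites)))
})

test_that("a noiseless synthetic retina is reconstructed within 5%", {
  spec <- retina_spec(5, c(-0.145, 0.057), 500, 4000,
                      c(nasal = 0.7, temporal = 1.1, dorsal = 1.3,
                        ventral = 0.9))
  fld <- generate_density_field(spec, 0.2)
  cf <- sample_counting_frames(fld, 400, seed = 3, layout = "lattice")
  cf$density <- field_value(fld, cf$x, cf$y)  # noiseless site densities
  rec <- build_topographic_map(cf, fld$outline, 0.2)
  g <- expand.grid(x = rec$x, y = rec$y)
  tv <- field_value(fld, g$x, g$y)
  rv <- as.vector(rec$z)
  away <- sqrt(g$x^2 + g$y^2) < 4 & !is.na(tv) & !is.na(rv)
  mare <- mean(abs(rv[away] - tv[away]) / tv[away])
  expect_lt(mare, 0.05)
  ## and the planted fovea comes back within one grid step
  fov <- locate_fovea(rec)
  expect_lt(sqrt(sum((fov - spec$fovea_xy * 5)^2)), 2 * 0.2)
})

test_that("all-zero counts yield a flat zero field with a warning", {
  cf <- counting_frames(c(-2, 2, 0, 0), c(0, 0, -2, 2), 50, rep(0, 4))
  expect_warning(fld <- build_topographic_map(cf, circle_outline(5), 0.5),
                 "zero")
  expect_true(all(fld$z[!is.na(fld$z)] == 0))
})

test_that("collinear sites are rejected", {
  cf <- counting_frames(x = c(-2, -1, 0, 1, 2), y = rep(0, 5), 50,
                        rep(5, 5))
  expect_error(build_topographic_map(cf, circle_outline(5), 0.5),
               "collinear")
})

test_that("isodensity contours nest and handle out-of-range levels", {
  spec <- retina_spec(5, c(0, 0), 500, 4000, 1)
  fld <- generate_density_field(spec, 0.1)
  cl <- isodensity_contours(fld, c(1000, 2000, 3000))
  area <- function(piece) {
    x <- piece$x; y <- piece$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  a <- vapply(cl, function(p) sum(vapply(p, area, 0)), 0)
  expect_true(all(diff(a) < 0))  # higher level encloses less area
  ## symmetric field: contour centroid sits at the fovea
  cen <- colMeans(cl[["2000"]][[1]])
  expect_lt(max(abs(cen)), 0.1)
  ## outside the range: below the minimum -> whole outline; above -> empty
  out <- isodensity_contours(fld, c(100, 5000))
  expect_equal(out[["100"]][[1]], fld$outline)
  expect_length(out[["5000"]], 0)
  expect_error(isodensity_contours(fld, c(2000, 1000)), "increasing")
})

test_that("contours of a flat field degenerate correctly", {
  fld <- density_field(x = seq(-5, 5, 0.5), y = seq(-5, 5, 0.5),
                       z = matrix(1000, 21, 21),
                       outline = circle_outline(5), step = 0.5)
  cl <- isodensity_contours(fld, c(500, 1500))
  expect_equal(cl[["500"]][[1]], fld$outline)
  expect_length(cl[["1500"]], 0)
})

test_that("fovea on an exact grid node is recovered exactly", {
  ## fovea planted at (-0.6, 0.2) mm, a node of the 0.2 grid
  spec <- retina_spec(5, c(-0.12, 0.04), 500, 4000, 1)
  fld <- generate_density_field(spec, 0.2)
  expect_equal(unname(locate_fovea(fld)), c(-0.6, 0.2))
})

test_that("tied maxima return the plateau midpoint; flat fields fail", {
  z <- matrix(1, 21, 21)
  z[10, 11] <- z[11, 11] <- 2  # two adjacent maximal cells
  fld <- density_field(x = seq(-5, 5, 0.5), y = seq(-5, 5, 0.5), z = z,
                       outline = circle_outline(5.5), step = 0.5)
  fov <- locate_fovea(fld)
  expect_equal(unname(fov), c(mean(fld$x[10:11]), fld$y[11]))
  flat <- density_field(x = seq(-5, 5, 0.5), y = seq(-5, 5, 0.5),
                        z = matrix(1, 21, 21),
                        outline = circle_outline(5.5), step = 0.5)
  expect_error(locate_fovea(flat), "flat")
})

test_that("normalized fovea positions use centroid and equal-area radius", {
  outl <- circle_outline(5, n = 2048)
  pos <- normalize_fovea_position(c(-0.725, 0.285), outl, "right")
  expect_equal(pos$x, -0.145, tolerance = 1e-3)
  expect_equal(pos$y, 0.057, tolerance = 1e-3)
  ## at the centroid -> origin
  p0 <- normalize_fovea_position(c(0, 0), outl, "right")
  expect_equal(c(p0$x, p0$y), c(0, 0))
  ## outside -> rejection
  expect_error(normalize_fovea_position(c(10, 0), outl, "right"),
               "outside")
})

test_that("left and right eyes with mirrored anatomy normalize identically", {
  outl <- circle_outline(5)
  right <- normalize_fovea_position(c(-0.7, 0.3), outl, "right")
  left <- normalize_fovea_position(c(0.7, 0.3), outl, "left")
  expect_equal(right$x, left$x)
  expect_equal(right$y, left$y)
})

test_that("normalization is invariant to uniform rescaling", {
  set.seed(4)
  base <- circle_outline(5, n = 128)
  ## a mildly irregular outline
  rr <- 1 + 0.1 * sin(3 * atan2(base$y, base$x))
  outl <- data.frame(x = base$x * rr, y = base$y * rr)
  f <- c(-0.8, 0.4)
  p1 <- normalize_fovea_position(f, outl, "right")
  for (k in c(0.25, 3, 17)) {
    pk <- normalize_fovea_position(f * k,
                                   data.frame(x = outl$x * k,
                                              y = outl$y * k), "right")
    expect_equal(pk$x, p1$x, tolerance = 1e-12)
    expect_equal(pk$y, p1$y, tolerance = 1e-12)
  }
})

test_that("position summaries collapse correctly with zero variance", {
  pos <- data.frame(species = paste0("s", 1:5),
                    x = rep(-0.2, 5), y = rep(0.1, 5))
  s <- mean_position_with_ci(pos)
  expect_equal(s["x", "se"], 0)
  expect_equal(s["x", "ci_low"], -0.2)
  expect_equal(s["x", "ci_high"], -0.2)
  expect_error(mean_position_with_ci(rbind(pos, pos[1, ])), "duplicate")
  expect_error(mean_position_with_ci(pos[1, , drop = FALSE]), "at least 2")
})

test_that("95% confidence intervals achieve nominal coverage", {
  set.seed(123)
  hits <- 0L; nrep <- 1000L
  for (i in seq_len(nrep)) {
    pos <- data.frame(species = paste0("s", 1:29),
                      x = rnorm(29, -0.145, 0.07),
                      y = rnorm(29, 0.057, 0.09))
    s <- mean_position_with_ci(pos)
    hits <- hits + (s["x", "ci_low"] <= -0.145 &&
                      -0.145 <= s["x", "ci_high"])
  }
  expect_gt(hits / nrep, 0.93)
  expect_lt(hits / nrep, 0.97)
})
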