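test_that("degenerate flat retina gives a uniform field at base density", {
  spec <- retina_spec(5, c(0.2, -0.1), 800, 800, c(nasal = 1, temporal = 3,
                                                   dorsal = 0.5, ventral = 2))
  fld <- generate_density_field(spec, 0.25)
  expect_true(all(abs(fld$z[!is.na(fld$z)] - 800) < 1e-9))
})

test_that("linear profile interpolates exactly between base and peak", {
  ## closed form: density at the midpoint of the fovea-margin path is the
  ## arithmetic mean of peak and base when the steepness exponent is 1
  spec <- linear_spec(fovea = c(0.1, -0.2))
  f_mm <- spec$fovea_xy * spec$radius
  ## margin point along +x from the fovea, then its midpoint
  L <- retgrad:::.ray_polygon_distance(f_mm, c(1, 0),
                                       circle_outline(5, 720)$x,
                                       circle_outline(5, 720)$y)
  mid <- f_mm + c(L / 2, 0)
  expect_equal(retgrad:::.true_density(spec, mid[1], mid[2]),
               2250, tolerance = 1e-3)
})

test_that("equal steepness with centred fovea is radially symmetric", {
  spec <- retina_spec(5, c(0, 0), 500, 4000, 1.7)
  fld <- generate_density_field(spec, 0.25)
  z <- fld$z
  ## mirrored grid points: flip in x and in y
  expect_lt(max(abs(z - z[rev(seq_along(fld$x)), ]), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(z - z[, rev(seq_along(fld$y))]), na.rm = TRUE), 1e-9)
})

test_that("density values lie within [base, peak] before noise", {
  set.seed(7)
  for (i in 1:5) {
    spec <- retina_spec(runif(1, 3, 6), c(runif(1, -0.4, 0.4),
                                          runif(1, -0.4, 0.4)),
                        500, runif(1, 3000, 6000),
                        stats::setNames(runif(4, 0.3, 3),
                                        c("nasal", "temporal", "dorsal",
                                          "ventral")))
    fld <- generate_density_field(spec, spec$radius / 15)
    rng <- range(fld$z, na.rm = TRUE)
    expect_gte(rng[1], spec$base_density - 1e-9)
    expect_lte(rng[2], spec$peak_density + 1e-9)
  }
})

test_that("counting-frame counts are Poisson with mean density x area", {
  ## flat field at 4000 cells/mm^2; a 50 um frame has area 0.0025 mm^2,
  ## so the Poisson mean is 10; 10,000 frames pin the mean to +/- 3 SE
  spec <- retina_spec(5, c(0, 0), 4000, 4000, 1)
  fld <- generate_density_field(spec, 0.25)
  cf <- sample_counting_frames(fld, 10000, frame_side = 50, seed = 99)
  se <- sqrt(10 / 10000)
  expect_lt(abs(mean(cf$count) - 10), 3 * se)
  expect_equal(cf$density, cf$count / 0.0025)
})

test_that("zero density fields give zero counts", {
  fld <- density_field(x = 0:10, y = 0:10,
                       z = matrix(0, 11, 11),
                       outline = circle_outline(5, center = c(5, 5)),
                       step = 1)
  cf <- sample_counting_frames(fld, 50, frame_side = 50, seed = 1)
  expect_true(all(cf$count == 0))
})

test_that("frame sampling is reproducible for a fixed seed", {
  spec <- linear_spec()
  fld <- generate_density_field(spec, 0.25)
  a <- sample_counting_frames(fld, 100, seed = 42)
  b <- sample_counting_frames(fld, 100, seed = 42)
  expect_identical(a, b)
  c2 <- sample_counting_frames(fld, 100, seed = 43)
  expect_false(identical(a$count, c2$count))
})

test_that("pooled frames scale the Poisson mean and the density estimate", {
  spec <- retina_spec(5, c(0, 0), 4000, 4000, 1)
  fld <- generate_density_field(spec, 0.25)
  cf <- sample_counting_frames(fld, 4000, frame_side = 50,
                               frames_per_site = 4, seed = 5)
  expect_lt(abs(mean(cf$count) - 40), 3 * sqrt(40 / 4000))
  expect_equal(cf$density, cf$count / (4 * 0.0025))
})

test_that("empirical count/area densities are unbiased for the field", {
  spec <- linear_spec(fovea = c(0.15, -0.05))
  fld <- generate_density_field(spec, 0.2)
  cf <- sample_counting_frames(fld, 4000, frame_side = 100, seed = 17)
  tv <- field_value(fld, cf$x, cf$y)
  ## pooled z-score of (count - mu) over all frames
  mu <- tv * 0.01
  z <- sum(cf$count - mu) / sqrt(sum(mu))
  expect_lt(abs(z), 3)
})

test_that("spec invariants are enforced", {
  expect_error(retina_spec(-1, c(0, 0), 500, 4000), "radius")
  expect_error(retina_spec(5, c(0.9, 0.6), 500, 4000), "inside")
  expect_error(retina_spec(5, c(0, 0), 0, 4000), "densities")
  expect_error(retina_spec(5, c(0, 0), 5000, 4000), "densities")
  expect_error(retina_spec(5, c(0, 0), 500, 4000, -1), "steepness")
  expect_error(retina_spec(5, c(0, 0), 500, 4000, 1, noise_cv = -0.1),
               "noise_cv")
  expect_error(generate_density_field(linear_spec(), 1), "grid_step")
  fld <- generate_density_field(linear_spec(), 0.25)
  expect_error(sample_counting_frames(fld, 3), "n_sites")
  expect_error(sample_counting_frames(fld, 10, frame_side = 2e4),
               "larger than the retina")
})

test_that("noiseless trait simulation returns the exact linear predictor", {
  tr <- hand_tree()
  x <- c(A = 1, B = 2, C = 3)
  sim <- simulate_traits_on_tree(
    trait_sim_spec(tr, beta0 = 0.5, beta1 = 2, sigma2 = 0, seed = 1), x)
  expect_equal(sim$trait, 0.5 + 2 * c(1, 2, 3))
})

test_that("star-tree errors are uncorrelated between tips", {
  tr <- star_tree(2, depth = 1.5)
  x <- stats::setNames(c(0, 0), tr$tip.label)
  e <- replicate(5000, {
    s <- trait_sim_spec(tr, 0, 0, lambda_true = 0.7, sigma2 = 1,
                        seed = sample.int(2^30, 1))
    simulate_traits_on_tree(s, x)$trait
  })
  r <- cor(e[1, ], e[2, ])
  expect_lt(abs(r), 3 / sqrt(5000))
})

test_that("shared-path covariance of sister tips matches Brownian expectation", {
  ## A and B share a root path of length 2
  tr <- parse_newick("((A:1,B:1):2,O:3);")
  V <- bm_vcv(tr)
  expect_equal(V["A", "B"], 2)
  sig2 <- 0.8
  x <- stats::setNames(rep(0, 3), tr$tip.label)
  set.seed(71)
  e <- replicate(5000, {
    s <- trait_sim_spec(tr, 0, 0, lambda_true = 1, sigma2 = sig2,
                        seed = sample.int(2^30, 1))
    tt <- simulate_traits_on_tree(s, x)
    tt$trait[match(c("A", "B"), tt$species)]
  })
  emp_cov <- stats::cov(e[1, ], e[2, ])
  ## sampling SD of the covariance of bivariate normals
  se <- sqrt((prod(diag(sig2 * V[c("A", "B"), c("A", "B")])) +
                (sig2 * 2)^2) / 5000)
  expect_lt(abs(emp_cov - sig2 * 2), 3 * se)
})

test_that("lambda 0 simulation standardizes to i.i.d. normal errors", {
  tr <- ape::rtree(40)
  V <- bm_vcv(tr)
  x <- stats::setNames(rep(0, 40), tr$tip.label)
  set.seed(31)
  draws <- replicate(100, {
    s <- trait_sim_spec(tr, 0, 0, lambda_true = 0, sigma2 = 1,
                        seed = sample.int(2^30, 1))
    simulate_traits_on_tree(s, x)$trait / sqrt(diag(V))
  })
  ks <- stats::ks.test(as.vector(draws), "pnorm")
  expect_gt(ks$p.value, 0.01)
})

test_that("trait simulation rejects incomplete predictors", {
  tr <- hand_tree()
  expect_error(
    simulate_traits_on_tree(trait_sim_spec(tr, seed = 1), c(A = 1, B = 2)),
    "missing species: C")
})
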