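test_that("newick parsing handles small trees and bad input", {
  tr <- parse_newick("(A:1,B:1):0;")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  depths <- diag(bm_vcv(tr))
  expect_equal(unname(depths), c(1, 1))

  tr3 <- hand_tree()
  V <- bm_vcv(tr3)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(V["A", "A"], 2)

  expect_error(parse_newick("((A:1,B:1):1;"), "unmatched")
  expect_error(parse_newick("(A:1,B:1)):1;"), "unmatched")
  expect_error(parse_newick("(A:1,A:2);"), "duplicate")
  expect_error(parse_newick("(A,B);"), "branch length")
})

test_that("write/parse round trips preserve topology and lengths", {
  set.seed(11)
  for (i in 1:5) {
    tr <- ape::rtree(sample(4:40, 1))
    tr2 <- parse_newick(write_newick(tr))
    expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
    V1 <- bm_vcv(tr); tips <- sort(tr$tip.label)
    V2 <- bm_vcv(tr2)
    expect_lt(max(abs(V1[tips, tips] - V2[tips, tips])), 1e-12)
  }
})

test_that("Brownian covariance matches the independent ape oracle", {
  set.seed(12)
  for (i in 1:5) {
    tr <- ape::rtree(sample(5:64, 1))
    V <- bm_vcv(tr)
    Vo <- ape::vcv(tr)[tr$tip.label, tr$tip.label]
    expect_lt(max(abs(V - Vo)), 1e-12)
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)  # PSD
  }
  ## star tree: no shared history
  st <- star_tree(6, depth = 2.5)
  expect_equal(unname(bm_vcv(st)), diag(2.5, 6))
  ## ultrametric: constant diagonal
  expect_lt(diff(range(diag(bm_vcv(ape::rcoal(20))))), 1e-12)
  expect_error(bm_vcv(hand_tree(), tips = c("A", "Z")), "unknown")
})

test_that("the lambda transform scales only the off-diagonal", {
  V <- bm_vcv(ape::rcoal(10))
  W0 <- lambda_transform(V, 0)
  expect_equal(W0, diag(diag(V), nrow(V)), ignore_attr = TRUE)
  expect_equal(lambda_transform(V, 1), V)
  W5 <- lambda_transform(V, 0.5)
  off <- row(V) != col(V)
  expect_equal(W5[off], V[off] / 2)
  expect_equal(diag(W5), diag(V))
  expect_error(lambda_transform(V, 1.2), "lambda")
})

test_that("PGLS at lambda 0 on ultrametric trees equals OLS", {
  set.seed(13)
  tr <- ape::rcoal(15)
  x <- stats::setNames(rnorm(15), tr$tip.label)
  y <- stats::setNames(2 + 0.7 * x + rnorm(15, 0, 0.4), tr$tip.label)
  fit <- pgls_fit(y, x, tr, lambda = 0)
  ols <- stats::coef(stats::lm(y[tr$tip.label] ~ x[tr$tip.label]))
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-10)
  ## and the F test is the OLS F test
  sm <- summary(stats::lm(y[tr$tip.label] ~ x[tr$tip.label]))
  expect_equal(fit$F, unname(sm$fstatistic[1]), tolerance = 1e-8)
  expect_equal(fit$df, c(1, 13))
  expect_equal(fit$df_label, "F_2,13")
})

test_that("two-tip GLS matches the closed-form 2x2 solution", {
  ## intercept-only model on a genuine two-tip tree: the GLS mean is the
  ## precision-weighted tip average, computable by hand from the 2x2 V
  tr2 <- parse_newick("(A:1,B:3);")
  V2 <- bm_vcv(tr2)
  y2 <- c(A = 1.0, B = 2.0)
  w <- solve(V2) %*% rep(1, 2)
  mu_hand <- sum(w * y2[rownames(V2)]) / sum(w)
  f0 <- pgls_fit(y2, matrix(1, 2, 1, dimnames = list(c("A", "B"), "int")),
                 tr2, lambda = 1)
  expect_equal(unname(f0$coefficients), mu_hand, tolerance = 1e-10)

  tr <- parse_newick("((A:1,B:1):2,C:3);")
  y <- c(A = 1.2, B = 0.7, C = 2.0)
  x <- c(A = 0.5, B = -0.3, C = 1.1)
  V <- bm_vcv(tr)
  X <- cbind(1, x[rownames(V)])
  beta_hand <- gls_oracle(y[rownames(V)], X, V)
  fit <- pgls_fit(y, x, tr, lambda = 1)
  expect_equal(unname(fit$coefficients), drop(beta_hand),
               tolerance = 1e-10)
})

test_that("profile likelihood is smooth and honours boundaries", {
  set.seed(14)
  tr <- ape::rcoal(24)
  V <- bm_vcv(tr)
  x <- rnorm(24)
  X <- cbind(1, x)
  y <- drop(t(chol(V)) %*% rnorm(24))
  prof <- profile_lambda(y, X, tr)
  expect_true(prof$lambda_hat >= 0 && prof$lambda_hat <= 1)
  ## continuity: adjacent grid log-likelihoods change gradually
  expect_lt(max(abs(diff(prof$curve))), 5)
  ## iid data on a deep balanced tree pushes lambda to the 0 boundary
  deep <- ape::compute.brlen(ape::stree(64, "balanced"), 1)
  y0 <- rnorm(64)
  p0 <- profile_lambda(y0, cbind(1, rnorm(64)), deep)
  expect_lt(p0$lambda_hat, 0.2)
})

test_that("lambda estimates are scale-free while sigma2 scales", {
  set.seed(15)
  tr <- ape::rcoal(20)
  x <- stats::setNames(rnorm(20), tr$tip.label)
  V <- bm_vcv(tr)
  y <- stats::setNames(1 + 0.5 * x[tr$tip.label] +
                         drop(t(chol(0.5 * lambda_transform(V, 0.6))) %*%
                                rnorm(20)), tr$tip.label)
  f1 <- pgls_fit(y, x, tr)
  k <- 7.3
  trk <- tr; trk$edge.length <- tr$edge.length * k
  f2 <- pgls_fit(y, x, trk)
  expect_lt(abs(f1$lambda_hat - f2$lambda_hat), 1e-5)
  expect_equal(f2$sigma2_hat, f1$sigma2_hat / k, tolerance = 1e-6)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("REML lambda and coefficients match the nlme/ape oracle", {
  skip_if_not_installed("nlme")
  set.seed(16)
  tr <- ape::rcoal(20)
  x <- stats::setNames(rnorm(20), tr$tip.label)
  V <- bm_vcv(tr)
  y <- stats::setNames(1 + 0.4 * x[tr$tip.label] +
                         drop(t(chol(0.3 * lambda_transform(V, 0.7))) %*%
                                rnorm(20)), tr$tip.label)
  d <- data.frame(y = y[tr$tip.label], x = x[tr$tip.label],
                  sp = tr$tip.label)
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corPagel(0.5, tr, form = ~sp),
                 method = "REML")
  fit <- pgls_fit(y, x, tr, lambda = "ml", method = "REML")
  lam_o <- stats::coef(g$modelStruct$corStruct, unconstrained = FALSE)
  if (lam_o >= 0 && lam_o <= 1) {
    expect_equal(fit$lambda_hat, unname(lam_o), tolerance = 1e-3)
    expect_equal(unname(fit$coefficients), unname(stats::coef(g)),
                 tolerance = 1e-4)
    expect_equal(fit$loglik, as.numeric(stats::logLik(g)),
                 tolerance = 1e-4)
  }
})

test_that("degenerate designs and bad inputs are rejected", {
  tr <- ape::rcoal(10)
  y <- stats::setNames(rnorm(10), tr$tip.label)
  xc <- stats::setNames(rep(1, 10), tr$tip.label)
  X <- cbind(`(Intercept)` = 1, bad = xc)
  expect_error(pgls_fit(y, X, tr), "singular")
  expect_error(pgls_fit(y, stats::setNames(rnorm(10), tr$tip.label), tr,
                        lambda = 2), "lambda")
  yy <- c(y, zz = 1)
  expect_error(pgls_fit(yy, stats::setNames(rnorm(11), names(yy)), tr),
               "not in tree")
})

test_that("log transform of movement rates is the natural log", {
  expect_equal(log_transform_rate(1), 0)
  expect_equal(log_transform_rate(exp(1)), 1)
  r <- sort(runif(10, 0.1, 50))
  expect_true(all(diff(log_transform_rate(r)) > 0))
  expect_error(log_transform_rate(0), "positive")
  expect_error(log_transform_rate(-2), "positive")
})
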