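#' Parse a newick tree with validation
#'
#' Thin validating wrapper around [ape::read.tree()].  Requires branch
#' lengths on every edge and unique tip labels; unmatched parentheses are
#' reported with their character position.
#'
#' @param text Newick string, or `NULL` when `file` is given.
#' @param file Path to a newick file.
#' @return A rooted `phylo` tree.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply text or file")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  depth <- cumsum(ifelse(strsplit(text, "")[[1]] == "(", 1L,
                         ifelse(strsplit(text, "")[[1]] == ")", -1L, 0L)))
  if (any(depth < 0))
    stop("unmatched ')' at character ", which(depth < 0)[1])
  if (utils::tail(depth, 1) != 0)
    stop("unmatched '(': ", utils::tail(depth, 1),
         " parenthesis(es) left open at end of string")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse failure: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("newick parse failure: no tree found")
  if (is.null(tree$edge.length))
    stop("newick tree has no branch lengths")
  if (length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("branch length missing on ",
         sum(is.na(tree$edge.length)), " edge(s)")
  .validate_tree(tree)
}

#' Write a tree as newick
#'
#' @param tree A `phylo` tree.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @param digits Significant digits for branch lengths (default preserves
#'   double precision so that parse-write round trips are exact).
#' @return The newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 17) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Brownian-motion variance-covariance matrix of a tree
#'
#' `V[i, j]` is the shared root-to-MRCA path length of tips i and j (their
#' expected trait covariance per unit rate under Brownian motion);
#' `V[i, i]` is the root-to-tip depth.  Built by accumulating each edge's
#' length over the tip pairs descending from it.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param tips Optional tip ordering (subset of the tree's tips).
#' @return Symmetric positive semidefinite matrix with tip-label dimnames.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' bm_vcv(tr)
#' @export
bm_vcv <- function(tree, tips = NULL) {
  tree <- .validate_tree(tree)
  lab <- tree$tip.label
  n <- length(lab)
  if (is.null(tips)) tips <- lab
  unknown <- setdiff(tips, lab)
  if (length(unknown))
    stop("unknown tip(s): ", paste(unknown, collapse = ", "))
  edge <- tree$edge; el <- tree$edge.length
  nnode <- n + tree$Nnode
  ## postorder over edges: repeatedly process edges whose child's subtree
  ## indicator is complete
  ind <- matrix(FALSE, nnode, n)
  ind[cbind(seq_len(n), seq_len(n))] <- TRUE
  remaining <- rep(TRUE, nrow(edge))
  done <- c(rep(TRUE, n), rep(FALSE, tree$Nnode))
  V <- matrix(0, n, n, dimnames = list(lab, lab))
  while (any(remaining)) {
    ready <- remaining & done[edge[, 2]]
    if (!any(ready)) stop("malformed tree edge matrix")
    for (k in which(ready)) {
      child <- edge[k, 2]; parent <- edge[k, 1]
      tipsk <- ind[child, ]
      V[tipsk, tipsk] <- V[tipsk, tipsk] + el[k]
      ind[parent, ] <- ind[parent, ] | tipsk
      remaining[k] <- FALSE
    }
    ## a node is done once all edges below it are processed
    kids_left <- tabulate(edge[remaining, 1], nbins = nnode)
    done <- done | (tabulate(edge[, 1], nbins = nnode) > 0 & kids_left == 0)
  }
  V[tips, tips, drop = FALSE]
}

#' Pagel's lambda transform of a Brownian-motion covariance matrix
#'
#' Multiplies all off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged.  `lambda = 0` gives the diagonal (ordinary least squares)
#' structure, `lambda = 1` the untransformed Brownian matrix.
#'
#' @param V Covariance matrix from [bm_vcv()].
#' @param lambda Value in \[0, 1\].
#' @return Transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  W <- V * lambda
  diag(W) <- diag(V)
  W
}

## GLS machinery shared by pgls_fit and profile_lambda.  Returns the
## whitened regression pieces for a fixed covariance W.
.gls_solve <- function(y, X, W) {
  tU <- tryCatch(t(chol(W)),
                 error = function(e)
                   stop("transformed covariance is not positive definite: ",
                        conditionMessage(e)))
  ys <- forwardsolve(tU, y)
  Xs <- forwardsolve(tU, X)
  qrX <- qr(Xs)
  if (qrX$rank < ncol(X)) stop("singular design matrix")
  beta <- qr.coef(qrX, ys)
  res <- ys - Xs %*% beta
  rss <- sum(res^2)
  list(beta = beta, rss = rss, logdet = 2 * sum(log(diag(tU))),
       Xs = Xs, ys = ys, tU = tU)
}

## Log-likelihood of the GLS model at fixed lambda (profiled over beta and
## sigma2).  method "ML" or "REML".
.gls_loglik <- function(y, X, V, lambda, method = "ML") {
  n <- length(y); p <- ncol(X)
  W <- lambda_transform(V, lambda)
  g <- .gls_solve(y, X, W)
  if (method == "ML") {
    s2 <- g$rss / n
    -0.5 * (n * log(2 * pi) + n * log(s2) + g$logdet + n)
  } else {
    s2 <- g$rss / (n - p)
    xtx <- crossprod(g$Xs)
    -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(s2) + g$logdet +
              as.numeric(determinant(xtx, logarithm = TRUE)$modulus) +
              (n - p))
  }
}

#' Profile likelihood of Pagel's lambda
#'
#' Evaluates the (profiled) log-likelihood on a uniform grid over \[0, 1\]
#' and refines the maximum with bounded golden-section search
#' ([stats::optimize()], tolerance 1e-6).  Optima at the boundary are
#' returned exactly as 0 or 1.
#'
#' @param y Response vector (tree tip order).
#' @param X Design matrix including the intercept column.
#' @param tree A `phylo` tree, or a precomputed [bm_vcv()] matrix.
#' @param ngrid Number of grid points (default 101).
#' @param method `"ML"` or `"REML"`.
#' @return List with `lambda_hat`, `loglik` (at the optimum), `grid` and
#'   `curve` (log-likelihood at each grid point).
#' @export
profile_lambda <- function(y, X, tree, ngrid = 101L,
                           method = c("ML", "REML")) {
  method <- match.arg(method)
  V <- if (is.matrix(tree)) tree else bm_vcv(tree)
  grid <- seq(0, 1, length.out = ngrid)
  curve <- vapply(grid, function(l) .gls_loglik(y, X, V, l, method), 0)
  if (any(!is.finite(curve)))
    stop("non-finite log-likelihood at lambda = ",
         grid[which(!is.finite(curve))[1]])
  i <- which.max(curve)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(ngrid, i + 1L)]
  opt <- stats::optimize(function(l) .gls_loglik(y, X, V, l, method),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-6)
  cand_l <- c(grid[i], opt$maximum)
  cand_v <- c(curve[i], opt$objective)
  best <- which.max(cand_v)
  lam <- cand_l[best]
  ## snap to the boundary when the optimum is within optimizer tolerance
  if (lam < 1e-5 && .gls_loglik(y, X, V, 0, method) >= cand_v[best] - 1e-8)
    lam <- 0
  if (lam > 1 - 1e-5 && .gls_loglik(y, X, V, 1, method) >= cand_v[best] - 1e-8)
    lam <- 1
  list(lambda_hat = lam,
       loglik = .gls_loglik(y, X, V, lam, method),
       grid = grid, curve = curve, method = method)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * V(lambda))`, where `V` is the
#' Brownian-motion covariance of the tree and `V(lambda)` scales its
#' off-diagonals by Pagel's lambda.  `lambda` may be fixed or estimated by
#' maximum likelihood (`"ml"`, profile over a grid plus golden-section
#' refinement; boundary optima 0 and 1 are returned exactly).  The model
#' F-test compares the fit against the intercept-only model under the same
#' lambda, with conventional degrees of freedom `(p - 1, n - p)` for a
#' design with `p` columns; `df_label` additionally echoes the
#' `F_{p, n-p}` format some comparative analyses print for one-predictor
#' models.
#'
#' @param y Named response vector (names = species), or unnamed in tree tip
#'   order.
#' @param X Design matrix with an intercept column (a vector is taken as a
#'   single predictor and an intercept is prepended).
#' @param tree A `phylo` tree covering all species in `y`.
#' @param lambda `"ml"` or a fixed value in \[0, 1\].
#' @param method `"ML"` or `"REML"` likelihood for lambda estimation.
#' @return A `pgls_fit` object: `coefficients`, `lambda_hat`, `sigma2_hat`
#'   (GLS residual variance, RSS/(n-p)), `F`, `df`, `df_label`, `p_value`,
#'   `r2`, `r2_adj`, `loglik`, `n`, `method`, `residuals` (raw scale) and
#'   `std_residuals` (whitened, unit variance).
#' @examples
#' tr <- ape::rtree(12)
#' x <- stats::setNames(rnorm(12), tr$tip.label)
#' sim <- simulate_traits_on_tree(
#'   trait_sim_spec(tr, beta0 = 1, beta1 = 0.5, sigma2 = 0.2, seed = 2),
#'   x)
#' fit <- pgls_fit(stats::setNames(sim$trait, sim$species), x, tr)
#' fit
#' @export
pgls_fit <- function(y, X, tree, lambda = "ml",
                     method = c("ML", "REML")) {
  method <- match.arg(method)
  tree <- .validate_tree(tree)
  tips <- tree$tip.label
  if (!is.null(names(y))) {
    missing <- setdiff(tips, names(y))
    extra <- setdiff(names(y), tips)
    if (length(extra))
      stop("species not in tree: ", paste(extra, collapse = ", "))
    if (length(missing))
      tree <- ape::drop.tip(tree, missing)
    tips <- tree$tip.label
    yv <- y[tips]
  } else {
    if (length(y) != length(tips))
      stop("unnamed y must have one value per tree tip")
    yv <- y
  }
  if (is.null(dim(X))) {
    Xn <- names(X)
    X <- matrix(X, ncol = 1,
                dimnames = list(Xn, deparse(substitute(X))[1]))
  }
  if (!is.null(rownames(X))) X <- X[tips, , drop = FALSE]
  if (!any(apply(X, 2, function(cc) all(cc == cc[1]))))
    X <- cbind(`(Intercept)` = 1, X)
  if (nrow(X) != length(yv)) stop("nrow(X) must match length(y)")
  if (anyNA(yv) || anyNA(X)) stop("complete cases required")
  n <- length(yv); p <- ncol(X)
  if (n <= p) stop("need n > number of design columns")
  V <- bm_vcv(tree)
  if (identical(lambda, "ml")) {
    prof <- profile_lambda(yv, X, V, method = method)
    lam <- prof$lambda_hat
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be 'ml' or a number in [0, 1]")
    lam <- lambda
    prof <- NULL
  }
  W <- lambda_transform(V, lam)
  g <- .gls_solve(yv, X, W)
  sigma2 <- g$rss / (n - p)
  ## intercept-only reference model under the same lambda
  g0 <- .gls_solve(yv, matrix(1, n, 1), W)
  q <- p - 1L
  if (q > 0) {
    Fstat <- ((g0$rss - g$rss) / q) / (g$rss / (n - p))
    pval <- stats::pf(Fstat, q, n - p, lower.tail = FALSE)
    r2 <- 1 - g$rss / g0$rss
  } else {
    Fstat <- NA_real_; pval <- NA_real_; r2 <- NA_real_
  }
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p)
  resid_raw <- drop(yv - X %*% g$beta)
  std_resid <- drop(forwardsolve(g$tU, resid_raw)) / sqrt(sigma2)
  structure(list(
    coefficients = stats::setNames(drop(g$beta), colnames(X)),
    lambda_hat = lam, sigma2_hat = sigma2,
    F = Fstat, df = c(q, n - p),
    df_label = sprintf("F_%d,%d", p, n - p),
    p_value = pval, r2 = r2, r2_adj = r2_adj,
    loglik = .gls_loglik(yv, X, V, lam, method),
    n = n, method = method,
    residuals = stats::setNames(resid_raw, tips),
    std_residuals = stats::setNames(std_resid, tips),
    profile = prof), class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS (Pagel's lambda), n =", x$n, "\n")
  cat("  lambda =", format(x$lambda_hat, digits = 4),
      " sigma2 =", format(x$sigma2_hat, digits = 4),
      " logLik =", format(x$loglik, digits = 6), paste0("(", x$method, ")\n"))
  print(round(x$coefficients, 5))
  if (!is.na(x$F))
    cat(sprintf("  F(%d,%d) = %.3f [%s], P = %.4g, R2 = %.3f, adj R2 = %.3f\n",
                x$df[1], x$df[2], x$F, x$df_label, x$p_value, x$r2,
                x$r2_adj))
  invisible(x)
}

#' Natural-log transform of a movement rate
#'
#' Head movement rates (movements/min) are log transformed before entering
#' the comparative regressions; non-positive rates are rejected.
#'
#' @param rate Positive numeric vector.
#' @return `log(rate)`.
#' @export
log_transform_rate <- function(rate) {
  if (any(!is.finite(rate)) || any(rate <= 0))
    stop("rates must be positive and finite")
  log(rate)
}
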