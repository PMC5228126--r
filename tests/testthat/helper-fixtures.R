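## shared fixtures built in code

# small hand-checkable tree: ((A:1,B:1):1,C:2);
hand_tree <- function() parse_newick("((A:1,B:1):1,C:2);")

star_tree <- function(n, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, nrow(tr$edge))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# linear-profile retina used throughout: density rises 500 -> 4000
linear_spec <- function(fovea = c(-0.145, 0.057), radius = 5, s = 1,
                        peak = 4000) {
  retina_spec(radius, fovea, 500, peak, quadrant_steepness = s)
}

# transect profile holding an exact line in 10^3 cells/mm^2
line_profile <- function(from = 0.5, to = 4, n = 10, axis = "nasal") {
  out <- data.frame(distance = seq(0, 1, length.out = n),
                    density = seq(from, to, length.out = n))
  attr(out, "axis") <- axis
  class(out) <- c("transect_profile", "data.frame")
  out
}

# dense-linear-algebra GLS oracle: explicit inverse + normal equations
gls_oracle <- function(y, X, W) {
  Wi <- solve(W)
  solve(t(X) %*% Wi %*% X, t(X) %*% Wi %*% y)
}
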