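# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Brute-force DBSCAN by reachability-graph components: core points are
# vertices, edges join core points within eps, components are clusters;
# non-core points adopt the cluster of any core neighbor, else stay -1.
# Valid comparison for fixtures where border assignment is unambiguous.
oracle_dbscan <- function(X, eps, min_samples) {
  d <- as.matrix(dist(X))
  n <- nrow(X)
  nbr <- d <= eps
  core <- which(rowSums(nbr) >= min_samples)
  labels <- rep(-1L, n)
  if (length(core)) {
    sub <- nbr[core, core, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    labels[core] <- as.integer(comp)
    for (i in setdiff(seq_len(n), core)) {
      hits <- core[nbr[i, core]]
      if (length(hits)) labels[i] <- labels[hits[1]]
    }
  }
  labels
}

# Numeric mean curvature of an axis-aligned ellipsoid at surface point p0,
# from finite-difference first/second fundamental forms of the standard
# spherical parameterization.
oracle_mean_curvature <- function(axes, p0, h = 1e-5) {
  a <- axes[1]; b <- axes[2]; c <- axes[3]
  th0 <- acos(max(-1, min(1, p0[3] / c)))
  ph0 <- atan2(p0[2] / b, p0[1] / a)
  r <- function(th, ph) c(a * sin(th) * cos(ph), b * sin(th) * sin(ph),
                          c * cos(th))
  # guard poles: nudge theta off 0/pi so the chart is regular
  if (th0 < 1e-4) th0 <- 1e-4
  if (th0 > pi - 1e-4) th0 <- pi - 1e-4
  ru <- (r(th0 + h, ph0) - r(th0 - h, ph0)) / (2 * h)
  rv <- (r(th0, ph0 + h) - r(th0, ph0 - h)) / (2 * h)
  ruu <- (r(th0 + h, ph0) - 2 * r(th0, ph0) + r(th0 - h, ph0)) / h^2
  rvv <- (r(th0, ph0 + h) - 2 * r(th0, ph0) + r(th0, ph0 - h)) / h^2
  ruv <- (r(th0 + h, ph0 + h) - r(th0 + h, ph0 - h) -
          r(th0 - h, ph0 + h) + r(th0 - h, ph0 - h)) / (4 * h^2)
  nrm <- c(ru[2] * rv[3] - ru[3] * rv[2],
           ru[3] * rv[1] - ru[1] * rv[3],
           ru[1] * rv[2] - ru[2] * rv[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  # orient outward (away from the center)
  if (sum(nrm * r(th0, ph0)) < 0) nrm <- -nrm
  E <- sum(ru * ru); FF <- sum(ru * rv); G <- sum(rv * rv)
  L <- sum(ruu * nrm); M <- sum(ruv * nrm); N <- sum(rvv * nrm)
  # sign: with outward normal the ellipsoid curves away, giving negative
  # second fundamental form; report the convex-positive convention
  -(E * N - 2 * FF * M + G * L) / (2 * (E * G - FF^2))
}

# uniform sample inside an axis-aligned ellipsoid (volume-uniform)
runif_ellipsoid <- function(n, axes) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  rad <- runif(n)^(1 / 3)
  sweep(v * rad, 2, axes, "*")
}

# random rotation matrix (QR of a Gaussian matrix, made proper)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# minimal water-only frame for transport tests: n beads uniform in a sphere
water_ball <- function(n, radius, seed) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(3 * n), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    xyz <- v * radius * runif(n)^(1 / 3)
    particle_frame(xyz, rep(18.015, n), seq_len(n), rep("water", n),
                   component = rep("SOL", n))
  })
}
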