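#' Construct an ellipsoid model
#'
#' An `ellipsoid_model` is a center, sorted semi-axes a >= b >= c and an
#' orthonormal rotation whose columns are the axis directions. It defines
#' the ellipsoidal coordinate
#' \deqn{u(p) = | \mathrm{diag}(1/a, 1/b, 1/c)\, R^T (p - center) |,}
#' which is 0 at the center and 1 on the surface.
#'
#' @param center length-3 numeric, Angstrom.
#' @param semi_axes length-3 positive numeric; sorted descending internally.
#' @param rotation 3 x 3 orthonormal matrix, columns matching `semi_axes`.
#' @return object of class `ellipsoid_model`.
#' @export
ellipsoid_model <- function(center, semi_axes, rotation = diag(3)) {
  stopifnot(length(center) == 3, length(semi_axes) == 3,
            all(is.finite(semi_axes)), all(semi_axes > 0))
  ord <- order(semi_axes, decreasing = TRUE)
  semi_axes <- semi_axes[ord]
  rotation <- rotation[, ord, drop = FALSE]
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be orthonormal")
  }
  if (det(rotation) < 0) rotation[, 3] <- -rotation[, 3]
  structure(list(center = as.numeric(center), semi_axes = semi_axes,
                 rotation = rotation), class = "ellipsoid_model")
}

#' @export
print.ellipsoid_model <- function(x, ...) {
  cat(sprintf("ellipsoid: a,b,c = %.2f, %.2f, %.2f A; center = (%s) A\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3],
              paste(signif(x$center, 4), collapse = ", ")))
  invisible(x)
}

#' Ellipsoidal coordinate u of points
#'
#' @param model an [ellipsoid_model()].
#' @param points N x 3 matrix or length-3 vector, Angstrom.
#' @return numeric vector: u = 0 at the center, 1 on the surface, > 1 outside.
#' @export
ellipsoid_u <- function(model, points) {
  p <- matrix(points, ncol = 3)
  local <- sweep(p, 2, model$center) %*% model$rotation
  sqrt(rowSums(sweep(local, 2, model$semi_axes, "/")^2))
}

# outward unit normals at the radial footpoints of points
ellipsoid_normal <- function(model, points) {
  p <- matrix(points, ncol = 3)
  y <- sweep(p, 2, model$center) %*% model$rotation
  u <- sqrt(rowSums(sweep(y, 2, model$semi_axes, "/")^2))
  if (any(u < 1e-12)) stop("normal undefined at the ellipsoid center")
  y <- y / u   # radial footpoint on the surface
  g <- sweep(y, 2, model$semi_axes^2, "/")
  g <- g / sqrt(rowSums(g^2))
  g %*% t(model$rotation)
}

# Khachiyan iteration for the minimum-volume enclosing ellipsoid.
# Returns list(center, A) with ellipsoid {x : (x-c)' A (x-c) <= 1}.
.khachiyan <- function(P, tolerance) {
  n <- nrow(P); d <- ncol(P)
  Q <- t(cbind(P, 1))                       # (d+1) x n
  u <- rep(1 / n, n)
  for (iter in seq_len(100000L)) {
    X <- Q %*% (t(Q) * u)                   # (d+1) x (d+1)
    M <- colSums(Q * solve(X, Q))
    j <- which.max(M)
    maxM <- M[j]
    step <- (maxM - d - 1) / ((d + 1) * (maxM - 1))
    if (maxM <= (1 + tolerance) * (d + 1)) break
    u <- u * (1 - step)
    u[j] <- u[j] + step
  }
  c0 <- drop(t(P) %*% u)
  A <- solve(crossprod(P, P * u) - tcrossprod(c0)) / d
  list(center = c0, A = (A + t(A)) / 2)
}

# indices of extreme points along k near-uniform directions (+ axes):
# plays the convex-hull vertex-reduction role for the MVEE active set
.extreme_points <- function(P, k = 146L) {
  dirs <- rbind(diag(3), -diag(3), .fibonacci_directions(k))
  proj <- P %*% t(dirs)
  unique(apply(proj, 2, which.max))
}

#' Fit the minimum-volume bounding ellipsoid of a frame
#'
#' Approximates the particle's bounding surface by the minimum-volume
#' enclosing ellipsoid (MVEE) of its bead positions, computed by Khachiyan's
#' algorithm. Only extreme points (the convex-hull vertices reachable along
#' a dense fan of directions) enter the iteration; any point left outside is
#' added to the active set and the fit repeated, and the final ellipsoid is
#' rescaled minimally so that every point satisfies u <= 1.
#'
#' @param frame a [particle_frame()] or N x 3 coordinate matrix.
#' @param tolerance Khachiyan convergence tolerance (default 1e-3).
#' @param selection optional bead indices entering the fit.
#' @param exclude_vapor logical: drop stray beads farther than
#'   `vapor_factor` times the median radius from the centroid before
#'   fitting (escaped vapor would otherwise inflate the hull).
#' @param vapor_factor radial cutoff factor for `exclude_vapor`.
#' @return an [ellipsoid_model()].
#' @export
#' @examples
#' pts <- matrix(rnorm(1500), ncol = 3)
#' pts <- 200 * pts / sqrt(rowSums(pts^2))   # sphere of radius 200
#' fit_bounding_ellipsoid(pts)$semi_axes
fit_bounding_ellipsoid <- function(frame, tolerance = 1e-3, selection = NULL,
                                   exclude_vapor = FALSE,
                                   vapor_factor = 1.8) {
  P <- if (inherits(frame, "particle_frame")) frame$coords else
    as.matrix(frame)
  if (!is.null(selection)) P <- P[selection, , drop = FALSE]
  if (nrow(P) < 4) stop("ellipsoid fit needs at least 4 points")
  if (exclude_vapor) {
    ctr <- colMeans(P)
    r <- sqrt(rowSums(sweep(P, 2, ctr)^2))
    P <- P[r <= vapor_factor * stats::median(r), , drop = FALSE]
  }
  rk <- qr(sweep(P, 2, colMeans(P)))$rank
  if (rk < 3) stop("degenerate (coplanar or collinear) input")

  act <- .extreme_points(P)
  for (round in 1:20) {
    fit <- .khachiyan(P[act, , drop = FALSE], tolerance)
    dctr <- sweep(P, 2, fit$center)
    q <- rowSums((dctr %*% fit$A) * dctr)
    viol <- which(q > 1 + 2 * tolerance)
    viol <- setdiff(viol, act)
    if (!length(viol)) break
    act <- c(act, viol[order(q[viol], decreasing = TRUE)][
      seq_len(min(50L, length(viol)))])
  }
  e <- eigen(fit$A, symmetric = TRUE)
  axes <- 1 / sqrt(e$values)
  model <- ellipsoid_model(fit$center, axes, e$vectors)
  umax <- max(ellipsoid_u(model, P))
  if (umax > 1) model$semi_axes <- model$semi_axes * umax
  model
}

#' Equal-volume concentric shell boundaries
#'
#' Scale factors s_k = (k/N)^(1/3), k = 1..N, so that concentric similar
#' ellipsoids scaled by s_k enclose equal volume increments V_total/N.
#'
#' @param n_shells number of shells (default 3: core, bulk, surface).
#' @return numeric vector of scale factors ending in 1.
#' @export
#' @examples
#' shell_boundaries(3)   # (1/3)^(1/3), (2/3)^(1/3), 1
shell_boundaries <- function(n_shells = 3) {
  if (n_shells < 1) stop("n_shells must be >= 1")
  (seq_len(n_shells) / n_shells)^(1 / 3)
}

.region_names <- function(n) {
  if (n == 3) c("core", "bulk", "surface")
  else if (n == 1) "surface"
  else c("core", paste0("shell", seq_len(n - 2) + 1), "surface")
}

#' Assign beads to concentric equal-volume shells
#'
#' A bead with ellipsoidal coordinate u belongs to shell k when
#' s_(k-1) < u <= s_k (with s_0 = 0); beads outside the fitted ellipsoid
#' (u > 1) belong to the outermost (surface) shell.
#'
#' @param frame a [particle_frame()] or N x 3 matrix.
#' @param model an [ellipsoid_model()].
#' @param boundaries shell scale factors from [shell_boundaries()].
#' @return factor of region labels, ordered core -> surface.
#' @export
assign_regions <- function(frame, model, boundaries = shell_boundaries(3)) {
  P <- if (inherits(frame, "particle_frame")) frame$coords else
    as.matrix(frame)
  u <- ellipsoid_u(model, P)
  n <- length(boundaries)
  k <- rowSums(outer(u, boundaries, ">")) + 1L
  k <- pmin(k, n)
  factor(.region_names(n)[k], levels = .region_names(n))
}

#' Per-component mass distribution over shells
#'
#' For every component class, the percentage of that class's mass found in
#' each region: 100 x (class mass in region) / (class total mass). Rows sum
#' to 100. Classes with zero total mass are reported by a warning and
#' omitted.
#'
#' @param frame a [particle_frame()].
#' @param labels region factor from [assign_regions()].
#' @param classes classes to tabulate; default all present in the frame.
#' @return data.frame: one row per class, one column per region, plus
#'   `class` and `total_mass_amu`.
#' @export
region_mass_fractions <- function(frame, labels, classes = NULL) {
  stopifnot(inherits(frame, "particle_frame"),
            length(labels) == n_beads(frame))
  if (is.null(classes)) classes <- unique(frame$component_class)
  regions <- levels(labels)
  rows <- lapply(classes, function(cl) {
    sel <- frame$component_class == cl
    total <- sum(frame$masses[sel])
    if (total <= 0) {
      warning("component class '", cl, "' has zero total mass; row omitted")
      return(NULL)
    }
    by_region <- vapply(regions, function(rg)
      sum(frame$masses[sel & labels == rg]), numeric(1))
    cbind(data.frame(class = cl, total_mass_amu = total),
          as.data.frame(as.list(100 * by_region / total)))
  })
  do.call(rbind, rows)
}

#' Ellipsoid surface area (Thomsen approximation)
#'
#' \deqn{S \approx 4\pi \left(\frac{a^p b^p + a^p c^p + b^p c^p}{3}
#'   \right)^{1/p}, \quad p = 1.6075,}
#' accurate to within about 1 % for all aspect ratios.
#'
#' @param model an [ellipsoid_model()] (or length-3 vector of semi-axes).
#' @return surface area, Angstrom^2.
#' @export
ellipsoid_surface_area <- function(model) {
  ax <- if (inherits(model, "ellipsoid_model")) model$semi_axes else model
  p <- 1.6075
  a <- ax[1]; b <- ax[2]; c <- ax[3]
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

#' Mean curvature of the ellipsoid surface at radial footpoints
#'
#' Projects each point radially (along the ray from the center) onto the
#' ellipsoid surface and evaluates the mean curvature H there from the
#' closed form for the implicit surface x^2/a^2 + y^2/b^2 + z^2/c^2 = 1,
#' with the sign convention H = 1/R > 0 on a sphere of radius R.
#'
#' @param model an [ellipsoid_model()].
#' @param points N x 3 matrix, Angstrom (must not sit at the center).
#' @return numeric vector of mean curvatures, 1/Angstrom.
#' @export
ellipsoid_mean_curvature <- function(model, points) {
  p <- matrix(points, ncol = 3)
  y <- sweep(p, 2, model$center) %*% model$rotation
  u <- sqrt(rowSums(sweep(y, 2, model$semi_axes, "/")^2))
  if (any(u < 1e-12)) stop("curvature undefined at the ellipsoid center")
  y <- y / u
  ax2 <- model$semi_axes^2
  g <- 2 * sweep(y, 2, ax2, "/")        # gradient of F
  gn2 <- rowSums(g^2)
  trH <- 2 * sum(1 / ax2)
  gHg <- rowSums(sweep(g^2, 2, ax2, "/")) * 2
  (gn2 * trH - gHg) / (2 * gn2^1.5)
}
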