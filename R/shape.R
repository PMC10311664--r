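#' Gyration tensor of a particle frame
#'
#' Computes the (optionally mass-weighted) gyration tensor
#' \deqn{S_{ab} = \sum_i w_i (r_{i,a} - \bar r_a)(r_{i,b} - \bar r_b) /
#'   \sum_i w_i}
#' about the weighted centroid. The tensor is symmetric positive
#' semidefinite and invariant under global translation; its eigenvalues
#' (in Angstrom^2) feed the asphericity and relative shape anisotropy
#' descriptors.
#'
#' @param frame a [particle_frame()], or an N x 3 coordinate matrix.
#' @param mass_weighted logical; weight beads by mass (default TRUE).
#'   Ignored when `frame` is a bare matrix unless `masses` is given.
#' @param masses optional explicit weights when `frame` is a matrix.
#' @param selection optional bead indices to include.
#' @return 3 x 3 symmetric numeric matrix, Angstrom^2.
#' @export
#' @examples
#' cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
#' gyration_tensor(cube)   # identity
gyration_tensor <- function(frame, mass_weighted = TRUE, masses = NULL,
                            selection = NULL) {
  if (inherits(frame, "particle_frame")) {
    xyz <- frame$coords
    w <- if (mass_weighted) frame$masses else rep(1, nrow(xyz))
  } else {
    xyz <- as.matrix(frame)
    w <- if (!is.null(masses)) masses else rep(1, nrow(xyz))
  }
  if (!is.null(selection)) {
    xyz <- xyz[selection, , drop = FALSE]
    w <- w[selection]
  }
  if (nrow(xyz) < 2) stop("gyration tensor needs at least 2 points")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be nonnegative, sum > 0")
  ctr <- colSums(xyz * w) / sum(w)
  d <- sweep(xyz, 2, ctr)
  S <- crossprod(d * w, d) / sum(w)
  S <- (S + t(S)) / 2
  dimnames(S) <- NULL
  S
}

#' Shape descriptors from a gyration tensor
#'
#' Sorts the gyration-tensor eigenvalues descending
#' (lambda1 >= lambda2 >= lambda3) and computes the asphericity
#' \deqn{\phi = \lambda_1 - (\lambda_2 + \lambda_3)/2}
#' (Angstrom^2; zero for a perfect sphere) and the relative shape
#' anisotropy
#' \deqn{\kappa^2 = 1 - 3\frac{\lambda_1\lambda_2 + \lambda_2\lambda_3 +
#'   \lambda_3\lambda_1}{(\lambda_1+\lambda_2+\lambda_3)^2}}
#' (dimensionless, in \[0, 1\]; 1 when all points lie on a line, 0 for
#' isotropic symmetry such as a sphere or regular tetrahedron). Both closed
#' forms of kappa^2 (the product form and
#' \eqn{\tfrac{3}{2}\sum\lambda^2/(\sum\lambda)^2 - \tfrac12}) are evaluated
#' and must agree to 1e-12.
#'
#' @param S 3 x 3 symmetric positive semidefinite matrix.
#' @param time optional timestamp (ns) carried into the result.
#' @return object of class `shape_metrics`: list with `lambda` (sorted
#'   descending), `phi`, `kappa2`, `time`.
#' @export
#' @examples
#' shape_metrics(diag(c(2, 1, 1)))   # phi = 1, kappa2 = 0.0625
shape_metrics <- function(S, time = NA_real_) {
  S <- as.matrix(S)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    stop("gyration tensor must be symmetric")
  }
  lam <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  lam[lam < 0 & lam > -1e-12 * max(abs(lam), 1)] <- 0
  if (any(lam < 0)) stop("tensor is not positive semidefinite")
  tr <- sum(lam)
  if (tr <= 0) stop("all-zero gyration tensor: shape descriptors undefined")
  phi <- lam[1] - (lam[2] + lam[3]) / 2
  k2_prod <- 1 - 3 * (lam[1] * lam[2] + lam[2] * lam[3] + lam[3] * lam[1]) /
    tr^2
  k2_sq <- 1.5 * sum(lam^2) / tr^2 - 0.5
  if (abs(k2_prod - k2_sq) > 1e-12) {
    stop("internal inconsistency between kappa^2 closed forms")
  }
  k2 <- min(max(k2_prod, 0), 1)
  structure(list(lambda = lam, phi = phi, kappa2 = k2, time = time),
            class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
  cat(sprintf("shape: phi = %.4g A^2, kappa2 = %.4g, lambda = (%s) A^2\n",
              x$phi, x$kappa2, paste(signif(x$lambda, 5), collapse = ", ")))
  invisible(x)
}

#' Shape descriptors along a trajectory
#'
#' Computes one set of shape descriptors per frame and returns them as a
#' tidy table. All beads (water included) enter by default, matching the
#' convention of analysing the whole aerosol; restrict with `classes`.
#'
#' @param traj a [trajectory()].
#' @param classes component classes to include, or NULL for all beads.
#' @param mass_weighted logical, see [gyration_tensor()].
#' @return data.frame with columns `time_ns`, `lambda1`, `lambda2`,
#'   `lambda3` (A^2), `phi_A2`, `kappa2`.
#' @export
shape_series <- function(traj, classes = NULL, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- select_beads(traj$topology, classes = classes)
  if (!length(sel)) stop("selection empty in every frame")
  rows <- lapply(seq_len(n_frames(traj)), function(i) {
    f <- get_frame(traj, i)
    m <- tryCatch(
      shape_metrics(gyration_tensor(f, mass_weighted = mass_weighted,
                                    selection = sel), time = f$time),
      error = function(e) stop("frame ", i, ": ", conditionMessage(e)))
    data.frame(time_ns = m$time, lambda1 = m$lambda[1],
               lambda2 = m$lambda[2], lambda3 = m$lambda[3],
               phi_A2 = m$phi, kappa2 = m$kappa2)
  })
  do.call(rbind, rows)
}
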