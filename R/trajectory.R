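#' Construct a trajectory
#'
#' A `trajectory` couples one static topology (a [particle_frame()] carrying
#' masses, molecule ids, classes and head/tail indices) with a list of
#' per-frame coordinate matrices and frame times. The droplet sits in vacuum:
#' the box edge is metadata only and is never used for periodic imaging.
#'
#' @param topology a `particle_frame` providing the static bead attributes.
#' @param coords list of N x 3 coordinate matrices, one per frame (Angstrom).
#' @param times frame times in ns, strictly increasing.
#' @param box_edge vacuum box edge length in Angstrom (metadata only).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, times, box_edge = NA_real_) {
  stopifnot(inherits(topology, "particle_frame"), is.list(coords))
  n <- n_beads(topology)
  if (!length(coords)) stop("trajectory needs at least one frame")
  ok <- vapply(coords, function(x) is.matrix(x) && nrow(x) == n &&
                 ncol(x) == 3, logical(1))
  if (!all(ok)) stop("every frame must be an N x 3 matrix with N = ", n,
                     " (constant atom count)")
  if (length(times) != length(coords)) stop("times/frames length mismatch")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times), box_edge = box_edge),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$coords), "frames x", n_beads(x$topology),
      "beads, t =", x$times[1], "..", x$times[length(x$times)], "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$coords)

#' Extract one frame as a particle_frame
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return a [particle_frame()] at the frame's time.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  f <- traj$topology
  f$coords <- traj$coords[[i]]
  f$time <- traj$times[i]
  f
}

#' Generate an overdamped Brownian water trajectory with shell-dependent D
#'
#' Propagates the water beads of a frame as an overdamped random walk:
#' at every step each water takes an isotropic Gaussian step with per-axis
#' variance 2 D(r) dt, where D(r) is the diffusivity of the radial shell
#' containing the bead at the start of the step (radii measured from the
#' sphere center, taken as the origin of the input frame). The outermost
#' shell edge acts as a reflecting spherical wall. Non-water beads stay
#' static. This generator is the ground-truth oracle for the
#' mean-squared-displacement analysis.
#'
#' @param frame starting [particle_frame()].
#' @param shell_D data.frame with columns `r_min`, `r_max` (Angstrom) and
#'   `D` (A^2/ns); bands must tile the occupied radii without gaps.
#' @param dt time step between frames, ns.
#' @param n_frames number of frames to generate (including the start frame).
#' @param seed integer random seed.
#' @return a [trajectory()].
#' @export
#' @examples
#' fix <- generate_raft_fixture(1, 10, n_water = 50, radius = 60, seed = 1)
#' sd <- data.frame(r_min = 0, r_max = 60, D = 1.5)
#' traj <- generate_brownian_trajectory(fix$frame, sd, dt = 0.01,
#'                                      n_frames = 50, seed = 2)
generate_brownian_trajectory <- function(frame, shell_D, dt, n_frames,
                                         seed) {
  stopifnot(inherits(frame, "particle_frame"), dt > 0, n_frames >= 1)
  shell_D <- as.data.frame(shell_D)
  stopifnot(all(c("r_min", "r_max", "D") %in% names(shell_D)))
  if (any(shell_D$D < 0)) stop("negative diffusion coefficient")
  shell_D <- shell_D[order(shell_D$r_min), ]
  edges <- c(shell_D$r_min[1], shell_D$r_max)
  if (any(abs(shell_D$r_min[-1] - utils::head(shell_D$r_max, -1)) > 1e-9)) {
    stop("shell bands must be contiguous")
  }
  wat <- select_beads(frame, classes = "water")
  if (!length(wat)) stop("frame has no water beads")
  r0 <- sqrt(rowSums(frame$coords[wat, , drop = FALSE]^2))
  if (any(r0 < edges[1] - 1e-9) || any(r0 > edges[length(edges)] + 1e-9)) {
    stop("shell bands must cover the occupied radii (",
         sprintf("%.1f..%.1f A found", min(r0), max(r0)), ")")
  }
  R_wall <- edges[length(edges)]

  local_seed(seed)
  nw <- length(wat)
  coords <- vector("list", n_frames)
  coords[[1]] <- frame$coords
  pos <- frame$coords[wat, , drop = FALSE]
  for (k in seq_len(n_frames - 1L)) {
    r <- sqrt(rowSums(pos^2))
    band <- findInterval(r, edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
    sdv <- sqrt(2 * shell_D$D[band] * dt)
    pos <- pos + matrix(stats::rnorm(3 * nw), ncol = 3) * sdv
    # reflect beads that left the wall back inside (radial fold)
    r <- sqrt(rowSums(pos^2))
    out <- which(r > R_wall)
    if (length(out)) {
      fold <- (2 * R_wall - r[out]) / r[out]
      fold[fold < 0] <- 0   # pathological long jumps land at the center side
      pos[out, ] <- pos[out, , drop = FALSE] * fold
    }
    frm <- coords[[1]]
    frm[wat, ] <- pos
    coords[[k + 1]] <- frm
  }
  trajectory(frame, coords, times = frame$time + dt * (seq_len(n_frames) - 1))
}
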