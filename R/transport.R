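#' Mean squared displacement over trajectory time slices
#'
#' Splits the tail of the trajectory into `n_slices` consecutive slices of
#' `slice_length` ns. Within each slice the MSD uses the slice start as the
#' single time origin:
#' \deqn{\mathrm{MSD}(\tau) = \langle |r(t_0 + \tau) - r(t_0)|^2 \rangle}
#' averaged over the selected beads, and curves are reported per slice and
#' averaged across slices. With `multi_origin = TRUE`, every frame of the
#' slice serves as an origin (classic multiple-time-origin averaging).
#'
#' @param traj a [trajectory()].
#' @param classes component classes to include (default water).
#' @param slice_length slice duration, ns.
#' @param n_slices number of slices (taken from the trajectory tail).
#' @param selection explicit bead indices (overrides `classes`).
#' @param multi_origin logical, see above.
#' @return object of class `msd_curves`: list with `per_slice` (data.frame
#'   `slice`, `tau_ns`, `msd_A2`), `average` (data.frame `tau_ns`,
#'   `msd_A2`), `n_beads`, `dt`.
#' @export
compute_msd <- function(traj, classes = "water", slice_length, n_slices,
                        selection = NULL, multi_origin = FALSE) {
  stopifnot(inherits(traj, "trajectory"), slice_length > 0, n_slices >= 1)
  if (is.null(selection)) {
    selection <- select_beads(traj$topology, classes = classes)
  }
  if (!length(selection)) stop("selection empty")
  dt <- stats::median(diff(traj$times))
  per_slice <- max(2L, round(slice_length / dt) + 1L)
  need <- n_slices * (per_slice - 1L) + 1L
  if (n_frames(traj) < need) {
    stop("insufficient frames: need ", need, " for ", n_slices, " x ",
         slice_length, " ns at dt = ", signif(dt, 4), " ns, have ",
         n_frames(traj))
  }
  start0 <- n_frames(traj) - n_slices * (per_slice - 1L)
  taus <- dt * (seq_len(per_slice) - 1L)
  rows <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    i0 <- start0 + (s - 1L) * (per_slice - 1L)
    idx <- i0 + seq_len(per_slice) - 1L
    X <- lapply(traj$coords[idx], function(m) m[selection, , drop = FALSE])
    if (multi_origin) {
      msd <- vapply(seq_len(per_slice), function(k) {
        if (k == 1) return(0)
        orig <- seq_len(per_slice - k + 1L)
        mean(vapply(orig, function(o)
          mean(rowSums((X[[o + k - 1L]] - X[[o]])^2)), numeric(1)))
      }, numeric(1))
    } else {
      msd <- vapply(X, function(m) mean(rowSums((m - X[[1]])^2)), numeric(1))
    }
    rows[[s]] <- data.frame(slice = s, tau_ns = taus, msd_A2 = msd)
  }
  per <- do.call(rbind, rows)
  avg <- data.frame(tau_ns = taus,
                    msd_A2 = rowMeans(matrix(per$msd_A2, ncol = n_slices)))
  structure(list(per_slice = per, average = avg,
                 n_beads = length(selection), dt = dt),
            class = "msd_curves")
}

#' Diffusion coefficient from an MSD curve (Einstein relation)
#'
#' Ordinary least-squares fit of MSD(tau) over a fit window; in three
#' dimensions MSD = 6 D tau, so D is the fitted slope divided by 6. The
#' intercept is reported, not constrained to zero. The default window spans
#' 10-80 % of the curve, skipping the short-time region.
#'
#' @param msd_curve data.frame with columns `tau_ns` and `msd_A2` (e.g. the
#'   `average` element of [compute_msd()]).
#' @param fit_window length-2 numeric (tau_min, tau_max) in ns, or NULL for
#'   the default 10-80 % window.
#' @return list with `D` (A^2/ns), `D_cm2_s`, `slope`, `intercept`,
#'   `r_squared`, `n_points`, `fit_window`.
#' @export
#' @examples
#' curve <- data.frame(tau_ns = 0:10, msd_A2 = 6 * (0:10))
#' fit_diffusion_coefficient(curve)$D   # 1
fit_diffusion_coefficient <- function(msd_curve, fit_window = NULL) {
  stopifnot(all(c("tau_ns", "msd_A2") %in% names(msd_curve)))
  tmax <- max(msd_curve$tau_ns)
  if (is.null(fit_window)) fit_window <- c(0.1, 0.8) * tmax
  keep <- msd_curve$tau_ns >= fit_window[1] &
    msd_curve$tau_ns <= fit_window[2]
  if (sum(keep) < 2) {
    stop("fit window [", fit_window[1], ", ", fit_window[2],
         "] ns contains fewer than 2 MSD points")
  }
  fit <- stats::lm(msd_A2 ~ tau_ns, data = msd_curve[keep, ])
  slope <- unname(coef(fit)[2])
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((msd_curve$msd_A2[keep] - mean(msd_curve$msd_A2[keep]))^2)
  list(D = slope / 6, D_cm2_s = slope / 6 * 1e-5, slope = slope,
       intercept = unname(coef(fit)[1]),
       r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
       n_points = sum(keep), fit_window = fit_window)
}

#' Shell-resolved water diffusion profile
#'
#' Assigns the selected beads to radial shells by their distance from the
#' particle center at the start of each slice (membership stays frozen for
#' the whole slice, so beads crossing a shell edge mid-slice keep their
#' slice-start label), accumulates a per-shell MSD curve, and fits a
#' per-shell diffusion coefficient. The particle center is the mass-weighted
#' centroid of the slice-start frame.
#'
#' @param traj a [trajectory()].
#' @param shell_edges increasing radii (Angstrom) bounding the shells; shell
#'   k spans `shell_edges[k]`..`shell_edges[k+1]`.
#' @param slice_length,n_slices slicing as in [compute_msd()].
#' @param classes component classes to include (default water).
#' @param fit_window passed to [fit_diffusion_coefficient()].
#' @return data.frame with one row per shell: `r_min`, `r_max`, `D_A2_ns`,
#'   `D_cm2_s`, `n_beads` (mean beads per slice), `slope`, `intercept`,
#'   `r_squared`. Empty shells carry NA diffusivities and a warning.
#' @export
radial_diffusion_profile <- function(traj, shell_edges, slice_length,
                                     n_slices, classes = "water",
                                     fit_window = NULL) {
  stopifnot(length(shell_edges) >= 2, all(diff(shell_edges) > 0))
  selection <- select_beads(traj$topology, classes = classes)
  if (!length(selection)) stop("selection empty")
  dt <- stats::median(diff(traj$times))
  per_slice <- max(2L, round(slice_length / dt) + 1L)
  need <- n_slices * (per_slice - 1L) + 1L
  if (n_frames(traj) < need) stop("insufficient frames for slicing")
  start0 <- n_frames(traj) - n_slices * (per_slice - 1L)
  n_shell <- length(shell_edges) - 1L
  taus <- dt * (seq_len(per_slice) - 1L)

  sums <- matrix(0, per_slice, n_shell)
  wsum <- numeric(n_shell)
  counts <- matrix(0, n_slices, n_shell)
  for (s in seq_len(n_slices)) {
    i0 <- start0 + (s - 1L) * (per_slice - 1L)
    f0 <- traj$coords[[i0]]
    ctr <- colSums(f0 * traj$topology$masses) / sum(traj$topology$masses)
    r <- sqrt(rowSums(sweep(f0[selection, , drop = FALSE], 2, ctr)^2))
    if (any(r < shell_edges[1] | r > shell_edges[n_shell + 1])) {
      nout <- sum(r < shell_edges[1] | r > shell_edges[n_shell + 1])
      stop(nout, " selected bead(s) outside the shell edges at slice ", s)
    }
    band <- findInterval(r, shell_edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
    counts[s, ] <- tabulate(band, n_shell)
    X0 <- f0[selection, , drop = FALSE]
    for (k in seq_len(per_slice)) {
      Xk <- traj$coords[[i0 + k - 1L]][selection, , drop = FALSE]
      d2 <- rowSums((Xk - X0)^2)
      for (b in seq_len(n_shell)) {
        if (counts[s, b] > 0) {
          sums[k, b] <- sums[k, b] + sum(d2[band == b])
        }
      }
    }
    wsum <- wsum + counts[s, ]
  }
  out <- lapply(seq_len(n_shell), function(b) {
    base <- data.frame(r_min = shell_edges[b], r_max = shell_edges[b + 1],
                       n_beads = mean(counts[, b]))
    if (wsum[b] == 0) {
      warning("shell ", b, " [", shell_edges[b], ", ", shell_edges[b + 1],
              "] A is empty in every slice; D reported as NA")
      return(cbind(base, D_A2_ns = NA_real_, D_cm2_s = NA_real_,
                   slope = NA_real_, intercept = NA_real_,
                   r_squared = NA_real_))
    }
    curve <- data.frame(tau_ns = taus, msd_A2 = sums[, b] / wsum[b])
    fit <- fit_diffusion_coefficient(curve, fit_window)
    cbind(base, D_A2_ns = fit$D, D_cm2_s = fit$D_cm2_s, slope = fit$slope,
          intercept = fit$intercept, r_squared = fit$r_squared)
  })
  do.call(rbind, out)
}
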