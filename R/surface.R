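#' Fatty-acid surface coverage
#'
#' Percentage of the particle surface covered by surface-raft lipids:
#' \deqn{\mathrm{coverage} = 100 \frac{N_\mathrm{surface}\, a_\mathrm{lipid}}
#'   {A_\mathrm{surface}},}
#' with the ellipsoid surface area from the Thomsen approximation
#' (p = 1.6075). The default condensed-monolayer area per lipid is 21
#' Angstrom^2.
#'
#' @param rafts a [identify_surface_rafts()] result, or directly the number
#'   of surface lipids.
#' @param model an [ellipsoid_model()].
#' @param a_lipid area per lipid, Angstrom^2.
#' @return coverage in percent.
#' @export
surface_coverage <- function(rafts, model, a_lipid = 21) {
  stopifnot(inherits(model, "ellipsoid_model"), a_lipid > 0)
  n_surf <- if (inherits(rafts, "raft_set")) {
    sum(rafts$n_lipids[rafts$is_surface_raft])
  } else as.numeric(rafts)
  100 * n_surf * a_lipid / ellipsoid_surface_area(model)
}

#' Predicted and measured surface excess
#'
#' The surface holds \eqn{N_\mathrm{sites} = A_\mathrm{surface} /
#' a_\mathrm{lipid}} lipid sites. The predicted surface excess is the
#' total fatty-acid count over the site count (how full the surface would
#' be if every available lipid adsorbed); the measured excess replaces the
#' total with the lipids actually resident in surface rafts. A value of 1
#' means exactly as many lipids as sites; > 1 a surplus, < 1 a deficit.
#'
#' @param n_total_fa total fatty-acid molecules in the particle.
#' @param n_surface_fa fatty-acid molecules in surface rafts.
#' @param model an [ellipsoid_model()].
#' @param a_lipid area per lipid, Angstrom^2.
#' @return list with `excess_predicted`, `excess_measured`, `n_sites`,
#'   `area_A2`.
#' @export
surface_excess <- function(n_total_fa, n_surface_fa, model, a_lipid = 21) {
  stopifnot(n_total_fa >= 0, n_surface_fa >= 0, a_lipid > 0)
  area <- ellipsoid_surface_area(model)
  if (area <= 0) stop("zero surface area")
  n_sites <- area / a_lipid
  list(excess_predicted = n_total_fa / n_sites,
       excess_measured = n_surface_fa / n_sites,
       n_sites = n_sites, area_A2 = area)
}

#' Raft mean surface curvature, weighted by raft size
#'
#' Projects every member lipid of each surface raft radially onto the
#' fitted ellipsoid and evaluates the analytic mean curvature H at the
#' footpoints; a raft's curvature is the mean over its members, and the
#' system value is the raft-size-weighted mean
#' \eqn{\sum_i n_i \bar H_i / \sum_i n_i}.
#'
#' @param rafts a [identify_surface_rafts()] result (only rows with
#'   `is_surface_raft` are used unless `surface_only = FALSE`).
#' @param model an [ellipsoid_model()].
#' @param surface_only restrict to surface rafts (default TRUE).
#' @return list with `per_raft` (data.frame `cluster`, `n_lipids`,
#'   `mean_curvature_invA`) and `weighted_mean_invA`.
#' @export
raft_curvature <- function(rafts, model, surface_only = TRUE) {
  stopifnot(inherits(rafts, "raft_set"), inherits(model, "ellipsoid_model"))
  keep <- if (surface_only) which(rafts$is_surface_raft)
          else seq_len(nrow(rafts))
  pos <- attr(rafts, "positions")
  per <- lapply(keep, function(i) {
    H <- ellipsoid_mean_curvature(model, pos[[i]])
    data.frame(cluster = rafts$cluster[i], n_lipids = rafts$n_lipids[i],
               mean_curvature_invA = mean(H))
  })
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(cluster = integer(), n_lipids = integer(),
               mean_curvature_invA = numeric())
  wmean <- if (nrow(per)) {
    sum(per$n_lipids * per$mean_curvature_invA) / sum(per$n_lipids)
  } else NA_real_
  list(per_raft = per, weighted_mean_invA = wmean)
}

#' Atmospheric exposure frequency per molecule
#'
#' A bead is exposed in a frame when its radial distance to the fitted
#' ellipsoid surface is at most `d_exp` (equivalently, its ellipsoidal
#' coordinate satisfies u >= 1 - d_exp / a_ray with a_ray the
#' center-to-surface distance along its ray), or when it lies outside the
#' surface. A molecule is exposed when any of its beads is; its exposure
#' frequency is the fraction of frames in which it is exposed.
#'
#' @param traj a [trajectory()].
#' @param models an [ellipsoid_model()], or a list of one model per frame.
#' @param classes component classes to score (default all non-water).
#' @param d_exp exposure distance threshold, Angstrom (default 3).
#' @return data.frame with columns `molecule_id`, `component`, `class`,
#'   `exposure_frequency` in \[0, 1\].
#' @export
residue_exposure <- function(traj, models, classes = NULL, d_exp = 3) {
  stopifnot(inherits(traj, "trajectory"), d_exp >= 0)
  topo <- traj$topology
  if (is.null(classes)) classes <- setdiff(unique(topo$component_class),
                                           "water")
  sel <- select_beads(topo, classes = classes)
  if (!length(sel)) stop("selection absent from the trajectory")
  if (inherits(models, "ellipsoid_model")) {
    models <- rep(list(models), n_frames(traj))
  }
  stopifnot(length(models) == n_frames(traj))
  mols <- topo$molecule_id[sel]
  uniq <- sort(unique(mols))
  exposed_frames <- numeric(length(uniq))
  for (i in seq_len(n_frames(traj))) {
    m <- models[[i]]
    P <- traj$coords[[i]][sel, , drop = FALSE]
    y <- sweep(P, 2, m$center) %*% m$rotation
    u <- sqrt(rowSums(sweep(y, 2, m$semi_axes, "/")^2))
    r <- sqrt(rowSums(y^2))
    # center-to-surface distance along each bead's ray; r/u is finite for
    # any bead off the exact center
    a_ray <- ifelse(u > 1e-12, r / u, Inf)
    exposed <- u >= 1 | (a_ray - r) <= d_exp
    hit <- tapply(exposed, factor(mols, levels = uniq), any)
    exposed_frames <- exposed_frames + as.numeric(hit)
  }
  first <- match(uniq, topo$molecule_id)
  data.frame(molecule_id = uniq,
             component = topo$component[first],
             class = topo$component_class[first],
             exposure_frequency = exposed_frames / n_frames(traj))
}

#' Assemble the interfacial surface report
#'
#' Bundles coverage, surface excess and raft curvature into one report and
#' asserts the internal identity coverage = 100 x measured excess (both use
#' the same raft set and area per lipid).
#'
#' @param rafts a [identify_surface_rafts()] result.
#' @param model an [ellipsoid_model()].
#' @param n_total_fa total fatty-acid molecule count.
#' @param a_lipid area per lipid, Angstrom^2.
#' @return list of class `surface_report` with `area_A2`, `a_lipid`,
#'   `n_sites`, `coverage_percent`, `excess_predicted`, `excess_measured`,
#'   `raft_curvature` (per raft) and `weighted_mean_curvature_invA`.
#' @export
surface_report <- function(rafts, model, n_total_fa, a_lipid = 21) {
  n_surf <- sum(rafts$n_lipids[rafts$is_surface_raft])
  cov <- surface_coverage(rafts, model, a_lipid)
  exc <- surface_excess(n_total_fa, n_surf, model, a_lipid)
  stopifnot(abs(cov - 100 * exc$excess_measured) < 1e-9 * max(1, cov))
  curv <- raft_curvature(rafts, model)
  structure(list(area_A2 = exc$area_A2, a_lipid = a_lipid,
                 n_sites = exc$n_sites, n_surface_fa = n_surf,
                 n_total_fa = n_total_fa, coverage_percent = cov,
                 excess_predicted = exc$excess_predicted,
                 excess_measured = exc$excess_measured,
                 raft_curvature = curv$per_raft,
                 weighted_mean_curvature_invA = curv$weighted_mean_invA),
            class = "surface_report")
}

#' @export
print.surface_report <- function(x, ...) {
  cat(sprintf(paste0("surface: %.0f A^2, %.0f sites, coverage %.1f %%, ",
                     "excess %.2f predicted / %.2f measured\n"),
              x$area_A2, x$n_sites, x$coverage_percent,
              x$excess_predicted, x$excess_measured))
  invisible(x)
}
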