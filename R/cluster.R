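#' Position + orientation features for surfactant molecules
#'
#' For every surfactant molecule, the molecular centroid (mass-weighted over
#' its beads), the unit head -> tail orientation vector, and the 6-D feature
#' vector \[x, y, z, w vx, w vy, w vz\] in which the orientation is scaled
#' by the weight w (Angstrom). Two lipids at the same position with opposite
#' orientation are then 2w apart in feature space, so a suitable w separates
#' oppositely tilted rafts under Euclidean clustering.
#'
#' @param frame a [particle_frame()] with surfactant head/tail indices.
#' @param w orientation weight, Angstrom (default 10). `w = 0` reduces the
#'   features to pure positions.
#' @return object of class `lipid_features`: data.frame with columns
#'   `molecule_id`, `x`, `y`, `z` (centroid), `vx`, `vy`, `vz` (unit
#'   orientation), plus attribute `w`; feature matrix via
#'   [feature_matrix()].
#' @export
lipid_features <- function(frame, w = 10) {
  stopifnot(inherits(frame, "particle_frame"), w >= 0)
  sf <- frame$surfactants
  if (!nrow(sf)) stop("frame has no surfactant molecules")
  head_xyz <- frame$coords[sf$head_index, , drop = FALSE]
  tail_xyz <- frame$coords[sf$tail_index, , drop = FALSE]
  v <- tail_xyz - head_xyz
  len <- sqrt(rowSums(v^2))
  if (any(len < 1e-9)) {
    stop("coincident head/tail beads for molecule(s) ",
         paste(sf$molecule_id[len < 1e-9], collapse = ", "))
  }
  v <- v / len
  ctr <- t(vapply(seq_len(nrow(sf)), function(i) {
    b <- which(frame$molecule_id == sf$molecule_id[i])
    colSums(frame$coords[b, , drop = FALSE] * frame$masses[b]) /
      sum(frame$masses[b])
  }, numeric(3)))
  out <- data.frame(molecule_id = sf$molecule_id,
                    x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                    vx = v[, 1], vy = v[, 2], vz = v[, 3])
  attr(out, "w") <- w
  class(out) <- c("lipid_features", "data.frame")
  out
}

#' 6-D feature matrix of lipid features
#' @param features a `lipid_features` object.
#' @return numeric matrix \[x, y, z, w vx, w vy, w vz\].
#' @export
feature_matrix <- function(features) {
  w <- attr(features, "w")
  cbind(features$x, features$y, features$z,
        w * features$vx, w * features$vy, w * features$vz)
}

# Deterministic Euclidean DBSCAN. Neighborhoods include the point itself
# (min_samples counts the point, as in scikit-learn); cluster expansion
# proceeds in ascending index order so labels are reproducible.
.dbscan <- function(X, eps, min_samples) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  nbrs <- apply(d2 <= eps^2, 1, which, simplify = FALSE)
  core <- lengths(nbrs) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      for (k in nbrs[[j]]) {
        if (labels[k] == -1L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels
}

#' Cluster surfactants by position and orientation (DBSCAN)
#'
#' Runs density-based clustering (DBSCAN) on the 6-D position + scaled
#' orientation features. Points in no dense neighborhood keep the
#' "unclustered" label -1; clusters are numbered 1, 2, ... in order of
#' first appearance by molecule index, making the output deterministic for
#' a given input order.
#'
#' @param features a [lipid_features()] object (or bare feature matrix).
#' @param eps reachability radius in feature space, Angstrom (default 12).
#' @param min_samples minimum neighborhood size (self included) for a core
#'   point (default 5).
#' @param time optional timestamp carried into the result.
#' @return object of class `cluster_assignment`: list with `labels`
#'   (per-lipid integer, -1 = unclustered), `molecule_id`, `n_clusters`,
#'   `fraction_clustered`, `time`, `eps`, `min_samples`.
#' @export
cluster_lipids <- function(features, eps = 12, min_samples = 5,
                           time = NA_real_) {
  stopifnot(eps > 0, min_samples >= 1)
  if (inherits(features, "lipid_features")) {
    X <- feature_matrix(features)
    ids <- features$molecule_id
  } else {
    X <- as.matrix(features)
    ids <- seq_len(nrow(X))
  }
  if (!nrow(X)) stop("empty feature set")
  labels <- .dbscan(X, eps, min_samples)
  structure(list(labels = labels, molecule_id = ids,
                 n_clusters = length(unique(labels[labels > 0])),
                 fraction_clustered = mean(labels > 0),
                 time = time, eps = eps, min_samples = min_samples),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("clusters: %d (%.1f %% of %d lipids clustered)\n",
              x$n_clusters, 100 * x$fraction_clustered, length(x$labels)))
  invisible(x)
}

# greedy max-overlap matching of labels in `cur` onto reference labels `ref`
.match_labels <- function(ref, cur) {
  ref_ids <- sort(unique(ref[ref > 0]))
  cur_ids <- sort(unique(cur[cur > 0]))
  if (!length(cur_ids)) return(cur)
  ov <- outer(cur_ids, ref_ids,
              Vectorize(function(a, b) sum(cur == a & ref == b)))
  mapped <- rep(NA_integer_, length(cur_ids))
  used <- integer(0)
  for (k in order(apply(ov, 1, max), decreasing = TRUE)) {
    cand <- order(ov[k, ], decreasing = TRUE)
    cand <- cand[!ref_ids[cand] %in% used & ov[k, cand] > 0]
    if (length(cand)) {
      mapped[k] <- ref_ids[cand[1]]
      used <- c(used, mapped[k])
    }
  }
  nxt <- max(c(ref_ids, 0L))
  for (k in which(is.na(mapped))) {
    nxt <- nxt + 1L
    mapped[k] <- nxt
  }
  out <- cur
  for (k in seq_along(cur_ids)) out[cur == cur_ids[k]] <- mapped[k]
  out
}

#' Clustering kinetics along a trajectory
#'
#' Clusters the surfactants of every frame and summarizes the fraction of
#' clustered lipids and the number of clusters over time. With
#' `match = TRUE`, cluster identities are carried across frames by greedy
#' maximal shared-molecule overlap with the previous frame, so a persistent
#' raft keeps its label.
#'
#' @param traj a [trajectory()].
#' @param eps,min_samples,w clustering parameters, see [cluster_lipids()]
#'   and [lipid_features()].
#' @param match logical: match cluster identities across frames.
#' @return list with `summary` (data.frame `time_ns`, `fraction_clustered`,
#'   `n_clusters`) and `assignments` (list of `cluster_assignment`).
#' @export
clustering_kinetics <- function(traj, eps = 12, min_samples = 5, w = 10,
                                match = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  out <- vector("list", n_frames(traj))
  for (i in seq_len(n_frames(traj))) {
    f <- get_frame(traj, i)
    out[[i]] <- tryCatch(
      cluster_lipids(lipid_features(f, w = w), eps = eps,
                     min_samples = min_samples, time = f$time),
      error = function(e) stop("frame ", i, ": ", conditionMessage(e)))
    if (match && i > 1) {
      out[[i]]$labels <- .match_labels(out[[i - 1]]$labels, out[[i]]$labels)
    }
  }
  summary <- data.frame(
    time_ns = vapply(out, `[[`, numeric(1), "time"),
    fraction_clustered = vapply(out, `[[`, numeric(1), "fraction_clustered"),
    n_clusters = vapply(out, function(x) as.numeric(x$n_clusters),
                        numeric(1)))
  list(summary = summary, assignments = out)
}

#' Identify surface rafts among clusters
#'
#' A cluster is a surface raft when (i) its centroid's ellipsoidal
#' coordinate u is at least `u_min` (by default the inner boundary of the
#' outermost equal-volume shell, (2/3)^(1/3)) and (ii) the mean cosine
#' between its lipids' head -> tail orientations and the outward ellipsoid
#' normal at their positions is at least `align_min` — i.e. the patch sits
#' in the surface region and points outward like a monolayer.
#'
#' @param assignment a [cluster_lipids()] result.
#' @param features the [lipid_features()] the assignment was computed from.
#' @param model an [ellipsoid_model()] of the particle.
#' @param u_min minimal centroid ellipsoidal coordinate (default
#'   (2/3)^(1/3)).
#' @param align_min minimal mean orientation/normal cosine (default 0.5).
#' @return object of class `raft_set`: data.frame with one row per cluster
#'   (`cluster`, `n_lipids`, `centroid_u`, `mean_alignment`,
#'   `is_surface_raft`), with per-raft member ids in attribute `members`
#'   and their positions retained for curvature analysis.
#' @export
identify_surface_rafts <- function(assignment, features, model,
                                   u_min = (2 / 3)^(1 / 3),
                                   align_min = 0.5) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(features, "lipid_features"),
            inherits(model, "ellipsoid_model"))
  labels <- assignment$labels
  ids <- sort(unique(labels[labels > 0]))
  pos <- as.matrix(features[, c("x", "y", "z")])
  ori <- as.matrix(features[, c("vx", "vy", "vz")])
  rows <- lapply(ids, function(cl) {
    m <- labels == cl
    centroid <- colMeans(pos[m, , drop = FALSE])
    cu <- drop(ellipsoid_u(model, centroid))
    if (cu < 1e-9) stop("cluster ", cl, " centroid at ellipsoid center: ",
                        "normal undefined")
    nrm <- ellipsoid_normal(model, pos[m, , drop = FALSE])
    algn <- mean(rowSums(ori[m, , drop = FALSE] * nrm))
    data.frame(cluster = cl, n_lipids = sum(m), centroid_u = cu,
               mean_alignment = algn,
               is_surface_raft = cu >= u_min && algn >= align_min)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster = integer(), n_lipids = integer(),
                      centroid_u = numeric(), mean_alignment = numeric(),
                      is_surface_raft = logical())
  }
  attr(out, "members") <- lapply(ids, function(cl)
    assignment$molecule_id[labels == cl])
  attr(out, "positions") <- lapply(ids, function(cl)
    pos[labels == cl, , drop = FALSE])
  class(out) <- c("raft_set", "data.frame")
  out
}
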