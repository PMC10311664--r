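#' Construct a single-snapshot particle frame
#'
#' A `particle_frame` is one snapshot of a coarse-grained particle: bead
#' coordinates in Angstrom, bead masses in amu, molecule ids, component-class
#' labels, and for surfactant molecules the bead indices defining the
#' head -> tail vector.
#'
#' @param coords N x 3 numeric matrix, Angstrom.
#' @param masses length-N positive numeric, amu.
#' @param molecule_id length-N integer molecule ids.
#' @param component_class length-N character, each one of fatty_acid,
#'   protein, lps, saccharide, water, ion.
#' @param component length-N character component names (e.g. "PA", "SOL");
#'   optional, defaults to the class label.
#' @param surfactants data.frame with columns `molecule_id`, `head_index`,
#'   `tail_index` (bead row indices), one row per surfactant molecule.
#' @param time frame time in ns.
#' @return object of class `particle_frame`.
#' @export
particle_frame <- function(coords, masses, molecule_id, component_class,
                           component = component_class,
                           surfactants = NULL, time = 0) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (ncol(coords) != 3) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0)) {
    stop("masses must be length ", n, ", finite and > 0")
  }
  if (length(molecule_id) != n) stop("molecule_id length mismatch")
  if (length(component_class) != n) stop("component_class length mismatch")
  bad <- setdiff(unique(component_class), .COMPONENT_CLASSES)
  if (length(bad)) stop("unknown component class(es): ",
                        paste(bad, collapse = ", "))
  if (is.null(surfactants)) {
    surfactants <- data.frame(molecule_id = integer(), head_index = integer(),
                              tail_index = integer())
  }
  surfactants$molecule_id <- as.integer(surfactants$molecule_id)
  surfactants$head_index <- as.integer(surfactants$head_index)
  surfactants$tail_index <- as.integer(surfactants$tail_index)
  rownames(surfactants) <- NULL
  if (nrow(surfactants)) {
    idx <- c(surfactants$head_index, surfactants$tail_index)
    if (any(idx < 1 | idx > n)) stop("surfactant head/tail index out of range")
    if (any(surfactants$head_index == surfactants$tail_index)) {
      stop("surfactant head and tail indices must differ")
    }
  }
  surf_classes <- c("fatty_acid")
  surf_mols <- unique(molecule_id[component_class %in% surf_classes])
  if (!all(surf_mols %in% surfactants$molecule_id)) {
    stop("every surfactant molecule needs head/tail indices")
  }
  structure(list(coords = coords, masses = as.numeric(masses),
                 molecule_id = as.integer(molecule_id),
                 component_class = as.character(component_class),
                 component = as.character(component),
                 surfactants = surfactants, time = as.numeric(time)),
            class = "particle_frame")
}

#' @export
print.particle_frame <- function(x, ...) {
  cat("particle_frame:", nrow(x$coords), "beads,",
      length(unique(x$molecule_id)), "molecules, t =", x$time, "ns\n")
  print(table(x$component_class))
  invisible(x)
}

#' Number of beads in a frame
#' @param frame a `particle_frame`.
#' @return integer bead count.
#' @export
n_beads <- function(frame) nrow(frame$coords)

#' Select bead indices by component class or molecule id
#'
#' @param frame a `particle_frame`.
#' @param classes character vector of component classes, or NULL for all.
#' @param molecules molecule ids to keep, or NULL for all.
#' @return integer vector of bead row indices.
#' @export
select_beads <- function(frame, classes = NULL, molecules = NULL) {
  keep <- rep(TRUE, n_beads(frame))
  if (!is.null(classes)) keep <- keep & frame$component_class %in% classes
  if (!is.null(molecules)) keep <- keep & frame$molecule_id %in% molecules
  which(keep)
}

# uniform points in a sphere of radius r by rejection from the bounding cube
.runif_sphere <- function(n, r, max_tries = 50L) {
  out <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries) stop("packing failure: rejection sampling stalled")
    m <- ceiling((n - nrow(out)) * 2)
    cand <- matrix(stats::runif(3 * m, -r, r), ncol = 3)
    cand <- cand[rowSums(cand^2) <= r^2, , drop = FALSE]
    out <- rbind(out, cand)
  }
  out[seq_len(n), , drop = FALSE]
}

# n random unit vectors
.runif_unit <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a randomly packed coarse-grained particle
#'
#' Places every molecule of a discretized composition inside a sphere of the
#' design diameter: molecule centers are drawn uniformly (rejection sampling
#' from the bounding cube), single-bead species become one bead, fatty acids
#' become two-bead head-tail rods with random orientation, LPS/laminarin
#' become bead rods and the lipase a Gaussian bead blob. Molecule centers are
#' kept far enough from the boundary that all beads stay inside the sphere.
#' Identical seeds give bit-identical output.
#'
#' @param comp a `composition` from [build_composition()].
#' @param seed integer random seed.
#' @param bond_length intra-molecular bead spacing, Angstrom.
#' @param blob_sd Gaussian spread of protein blob beads, Angstrom.
#' @return a [particle_frame()].
#' @export
#' @examples
#' comp <- build_composition("A", diameter = 120)
#' p <- generate_particle(comp, seed = 7)
generate_particle <- function(comp, seed, bond_length = 4, blob_sd = 6) {
  stopifnot(inherits(comp, "composition"))
  local_seed(seed)
  reg <- comp$spec$registry
  R <- comp$spec$diameter / 2
  counts <- comp$counts
  # fixed component order for determinism
  counts <- counts[order(match(names(counts), reg$name))]

  coords <- list(); masses <- list(); mol <- list(); cls <- list()
  nm <- list(); surf <- list()
  mol_id <- 0L; bead_at <- 0L
  for (name in names(counts)) {
    k <- counts[[name]]
    row <- reg[reg$name == name, ]
    b <- row$beads_per_molecule
    extent <- (b - 1) * bond_length / 2
    margin <- if (row$geometry == "blob") 3 * blob_sd else extent
    r_ctr <- max(R - margin, 0.5 * R)
    centers <- .runif_sphere(k, r_ctr)
    if (b == 1L) {
      xyz <- centers
    } else if (row$geometry == "blob") {
      xyz <- centers[rep(seq_len(k), each = b), , drop = FALSE] +
        matrix(stats::rnorm(3 * k * b, sd = blob_sd), ncol = 3)
    } else { # rod: beads along a random axis, centered on the center
      axis <- .runif_unit(k)
      offs <- (seq_len(b) - (b + 1) / 2) * bond_length
      xyz <- centers[rep(seq_len(k), each = b), , drop = FALSE] +
        axis[rep(seq_len(k), each = b), , drop = FALSE] * rep(offs, times = k)
    }
    ids <- mol_id + rep(seq_len(k), each = b)
    if (row$head_tail_defined) {
      first <- bead_at + (seq_len(k) - 1L) * b + 1L
      surf[[name]] <- data.frame(molecule_id = mol_id + seq_len(k),
                                 head_index = first,
                                 tail_index = first + (b - 1L))
    }
    coords[[name]] <- xyz
    masses[[name]] <- rep(row$molar_mass / b, k * b)
    mol[[name]] <- ids
    cls[[name]] <- rep(row$component_class, k * b)
    nm[[name]] <- rep(name, k * b)
    mol_id <- mol_id + k
    bead_at <- bead_at + k * b
  }
  particle_frame(do.call(rbind, coords), unlist(masses), unlist(mol),
                 unlist(cls), component = unlist(nm),
                 surfactants = do.call(rbind, c(surf,
                   list(make.row.names = FALSE))),
                 time = 0)
}

# local orthonormal frame at a unit direction n: (east, north) tangents
.tangent_frame <- function(n) {
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Fibonacci sphere directions: near-uniform, deterministic
.fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Plant monolayer raft patches (and a core aggregate) on a sphere
#'
#' Builds a test particle with known ground truth for the raft-clustering
#' and partitioning analyses: `n_patches` monolayer patches of two-bead
#' fatty-acid lipids on the surface of a sphere, each patch with a uniform
#' tilt away from the local outward normal, plus an optional aggregate of
#' randomly oriented lipids near the particle center, plus optional filler
#' water. At tilt 0 the head bead sits on the sphere and the tail bead points
#' outward (toward the atmosphere), so the head -> tail orientation vector
#' aligns with the outward normal.
#'
#' @param n_patches number of surface patches.
#' @param lipids_per_patch lipids per patch (laid out on a local square grid).
#' @param patch_tilt tilt in degrees per patch (recycled), measured from the
#'   outward normal.
#' @param n_core_aggregate lipids in the central aggregate (0 for none).
#' @param radius sphere radius, Angstrom.
#' @param spacing in-patch lipid grid spacing, Angstrom.
#' @param n_water filler water beads drawn uniformly inside the sphere.
#' @param bond_length head-tail bead distance, Angstrom.
#' @param seed integer random seed.
#' @return list with `frame` (a [particle_frame()]), `true_labels` (per
#'   surfactant molecule: patch number 1..n_patches, or n_patches + 1 for the
#'   core aggregate), and `true_region` ("surface" or "core" per surfactant).
#' @export
generate_raft_fixture <- function(n_patches, lipids_per_patch,
                                  patch_tilt = 0, n_core_aggregate = 0,
                                  radius = 150, spacing = 5, n_water = 2000,
                                  bond_length = 4, seed = 1) {
  stopifnot(n_patches >= 1, lipids_per_patch >= 1, radius > 0, spacing > 0)
  local_seed(seed)
  patch_tilt <- rep(patch_tilt, length.out = n_patches)

  # feasibility: patch angular radius vs minimal separation of directions
  grid_n <- ceiling(sqrt(lipids_per_patch))
  patch_halfwidth <- grid_n * spacing / sqrt(2)
  dirs <- .fibonacci_directions(n_patches)
  if (n_patches > 1) {
    dmin <- min(stats::dist(dirs))
    chord_needed <- 2 * patch_halfwidth + 2 * spacing
    if (dmin * radius < chord_needed) {
      stop("infeasible patch geometry: ", n_patches, " patches of halfwidth ",
           round(patch_halfwidth, 1), " A overlap on a sphere of radius ",
           radius, " A")
    }
  }

  coords <- list(); surf_rows <- list(); labels <- integer(0)
  mol_id <- 0L; bead_at <- 0L
  grid1 <- (seq_len(grid_n) - (grid_n + 1) / 2) * spacing
  grid <- as.matrix(expand.grid(grid1, grid1))[seq_len(lipids_per_patch), ,
                                               drop = FALSE]
  for (p in seq_len(n_patches)) {
    nrm <- dirs[p, ]
    tf <- .tangent_frame(nrm)
    heads <- matrix(nrm * radius, lipids_per_patch, 3, byrow = TRUE) +
      outer(grid[, 1], tf$e1) + outer(grid[, 2], tf$e2)
    # project heads back onto the sphere so patches follow the curvature
    heads <- heads * (radius / sqrt(rowSums(heads^2)))
    th <- patch_tilt[p] * pi / 180
    axis <- cos(th) * nrm + sin(th) * tf$e1   # tilt about local north
    tails <- heads + matrix(axis * bond_length, lipids_per_patch, 3,
                            byrow = TRUE)
    k <- lipids_per_patch
    first <- bead_at + (seq_len(k) - 1L) * 2L + 1L
    xyz <- matrix(NA_real_, 2 * k, 3)
    xyz[seq(1, 2 * k, 2), ] <- heads
    xyz[seq(2, 2 * k, 2), ] <- tails
    coords[[length(coords) + 1]] <- xyz
    surf_rows[[length(surf_rows) + 1]] <- data.frame(
      molecule_id = mol_id + seq_len(k),
      head_index = first, tail_index = first + 1L)
    labels <- c(labels, rep(p, k))
    mol_id <- mol_id + k; bead_at <- bead_at + 2L * k
  }
  region <- rep("surface", mol_id)
  if (n_core_aggregate > 0) {
    k <- n_core_aggregate
    ctr <- .runif_sphere(k, 0.15 * radius)
    ax <- .runif_unit(k)
    xyz <- matrix(NA_real_, 2 * k, 3)
    xyz[seq(1, 2 * k, 2), ] <- ctr - ax * bond_length / 2
    xyz[seq(2, 2 * k, 2), ] <- ctr + ax * bond_length / 2
    first <- bead_at + (seq_len(k) - 1L) * 2L + 1L
    coords[[length(coords) + 1]] <- xyz
    surf_rows[[length(surf_rows) + 1]] <- data.frame(
      molecule_id = mol_id + seq_len(k),
      head_index = first, tail_index = first + 1L)
    labels <- c(labels, rep(n_patches + 1L, k))
    region <- c(region, rep("core", k))
    mol_id <- mol_id + k; bead_at <- bead_at + 2L * k
  }
  n_lip_beads <- bead_at
  fa_mass <- 256.42 / 2   # palmitic-acid beads
  masses <- rep(fa_mass, n_lip_beads)
  mol <- rep(seq_len(mol_id), each = 2)
  cls <- rep("fatty_acid", n_lip_beads)
  nms <- rep("PA", n_lip_beads)
  if (n_water > 0) {
    coords[[length(coords) + 1]] <- .runif_sphere(n_water, radius)
    masses <- c(masses, rep(18.015, n_water))
    mol <- c(mol, mol_id + seq_len(n_water))
    cls <- c(cls, rep("water", n_water))
    nms <- c(nms, rep("SOL", n_water))
  }
  frame <- particle_frame(do.call(rbind, coords), masses, mol, cls,
                          component = nms,
                          surfactants = do.call(rbind, surf_rows))
  list(frame = frame, true_labels = labels, true_region = region)
}
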