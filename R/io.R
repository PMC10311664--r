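# Atom naming convention on write: residue name = component name (LA, MA,
# PA, SA, BCL, LPS, GLC, LAM, SOL, NA, CL, MG, CA, K); surfactant head and
# tail beads are atoms "HD" and "TL", every other bead is "BD".

#' Default component map
#'
#' Maps residue names to component classes and declares the head/tail atom
#' names of surfactant residues, so that both files written by this package
#' and third-party atomistic data can be bound into [particle_frame()]
#' objects. Extend or override via a YAML file, see [read_component_map()].
#'
#' @param registry component registry, see [component_registry()].
#' @return list of class `component_map` with `classes` (residue ->
#'   class), `head_atom`/`tail_atom` (per surfactant residue), `masses`
#'   (residue -> molecular mass override).
#' @export
default_component_map <- function(registry = component_registry()) {
  cm <- list(
    classes = as.list(stats::setNames(registry$component_class,
                                      registry$name)),
    head_atom = as.list(stats::setNames(
      rep("HD", sum(registry$head_tail_defined)),
      registry$name[registry$head_tail_defined])),
    tail_atom = as.list(stats::setNames(
      rep("TL", sum(registry$head_tail_defined)),
      registry$name[registry$head_tail_defined])),
    masses = as.list(stats::setNames(registry$molar_mass, registry$name))
  )
  class(cm) <- "component_map"
  cm
}

#' Read a component map from YAML
#'
#' The YAML file holds `classes:` (residue name -> component class),
#' optional `head_atom:`/`tail_atom:` maps for surfactant residues and an
#' optional `masses:` map of molecular masses (amu). Entries extend or
#' override the built-in defaults.
#'
#' @param path YAML file path.
#' @param base map to extend (default [default_component_map()]).
#' @return a `component_map`.
#' @export
read_component_map <- function(path, base = default_component_map()) {
  y <- yaml::read_yaml(path)
  for (fld in c("classes", "head_atom", "tail_atom", "masses")) {
    if (!is.null(y[[fld]])) base[[fld]] <- utils::modifyList(base[[fld]],
                                                             y[[fld]])
  }
  bad <- setdiff(unlist(base$classes), .COMPONENT_CLASSES)
  if (length(bad)) stop("component map declares unknown class(es): ",
                        paste(bad, collapse = ", "))
  base
}

#' Write a component map to YAML
#' @param map a `component_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_component_map <- function(map, path) {
  yaml::write_yaml(map[c("classes", "head_atom", "tail_atom", "masses")],
                   path)
  invisible(path)
}

# per-bead atom records for writers
.atom_table <- function(frame) {
  n <- n_beads(frame)
  atom <- rep("BD", n)
  atom[frame$surfactants$head_index] <- "HD"
  atom[frame$surfactants$tail_index] <- "TL"
  data.frame(atom = atom, resname = frame$component,
             resid = frame$molecule_id, stringsAsFactors = FALSE)
}

# frame assembly shared by all readers
.bind_frame <- function(xyz, resname, resid, atom, map, time = 0) {
  unmapped <- setdiff(unique(resname), names(map$classes))
  if (length(unmapped)) {
    stop("unmapped residue name(s): ", paste(unmapped, collapse = ", "))
  }
  cls <- unlist(map$classes[resname], use.names = FALSE)
  mol_mass <- unlist(map$masses[resname], use.names = FALSE)
  # split molecular mass evenly over the molecule's beads
  key <- as.integer(factor(resid, levels = unique(resid)))
  beads_per <- tabulate(key)
  masses <- mol_mass / beads_per[key]
  surf <- NULL
  surf_res <- intersect(unique(resname), names(map$head_atom))
  if (length(surf_res)) {
    rows <- which(resname %in% surf_res)
    per_mol <- split(rows, key[rows])
    surf <- do.call(rbind, lapply(per_mol, function(ix) {
      rn <- resname[ix[1]]
      h <- ix[atom[ix] == map$head_atom[[rn]]]
      t <- ix[atom[ix] == map$tail_atom[[rn]]]
      if (length(h) != 1 || length(t) != 1) {
        stop("surfactant residue ", rn, " (molecule ", resid[ix[1]],
             "): head/tail atom names do not resolve")
      }
      data.frame(molecule_id = key[ix[1]], head_index = h, tail_index = t)
    }))
    rownames(surf) <- NULL
  }
  particle_frame(xyz, masses, key, cls, component = resname,
                 surfactants = surf, time = time)
}

#' Write a particle frame as a GRO file
#'
#' Fixed-format Gromos87 coordinates; positions are converted from the
#' package's Angstrom convention to nm (GRO native). The component name is
#' stored as the residue name.
#'
#' @param frame a [particle_frame()].
#' @param path output path.
#' @param box_edge cubic box edge, Angstrom (metadata only; default fits
#'   the particle).
#' @return `path`, invisibly.
#' @export
write_gro <- function(frame, path, box_edge = NULL) {
  at <- .atom_table(frame)
  n <- n_beads(frame)
  if (is.null(box_edge)) box_edge <- 2 * max(abs(frame$coords)) + 20
  nm <- frame$coords / 10
  lines <- c(
    sprintf("aeromorph particle, t= %.4f ns", frame$time),
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            at$resid %% 100000L, substr(at$resname, 1, 5),
            substr(at$atom, 1, 5), seq_len(n) %% 100000L,
            nm[, 1], nm[, 2], nm[, 3]),
    sprintf("%10.5f%10.5f%10.5f", box_edge / 10, box_edge / 10,
            box_edge / 10))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GRO file into a particle frame
#'
#' @param path GRO file path.
#' @param map a `component_map` resolving residue names.
#' @return a [particle_frame()] (coordinates in Angstrom).
#' @export
read_gro <- function(path, map = default_component_map()) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  rec <- lines[3:(2 + n)]
  resid <- as.integer(substr(rec, 1, 5))
  resname <- trimws(substr(rec, 6, 10))
  atom <- trimws(substr(rec, 11, 15))
  x <- as.numeric(substr(rec, 21, 28))
  y <- as.numeric(substr(rec, 29, 36))
  z <- as.numeric(substr(rec, 37, 44))
  time <- 0
  tm <- regmatches(lines[1], regexec("t= *([0-9.eE+-]+)", lines[1]))[[1]]
  if (length(tm) == 2) time <- as.numeric(tm[2])
  # resid wraps at 100000: rebuild molecule ids from (resid, resname) runs
  runs <- cumsum(c(1L, as.integer(diff(resid) != 0)))
  .bind_frame(cbind(x, y, z) * 10, resname, runs, atom, map, time = time)
}

#' Write a particle frame or trajectory as (multi-frame) XYZ
#'
#' Plain-text XYZ: per frame an atom count line, a comment line carrying
#' the time in ns, then `name x y z` records in Angstrom. The atom name is
#' `residue:atom` so the file round-trips losslessly.
#'
#' @param x a [particle_frame()] or [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path) {
  frames <- if (inherits(x, "trajectory")) {
    lapply(seq_len(n_frames(x)), get_frame, traj = x)
  } else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    at <- .atom_table(f)
    writeLines(c(
      sprintf("%d", n_beads(f)),
      sprintf("t= %.6f ns", f$time),
      sprintf("%s:%s:%d %.6f %.6f %.6f", at$resname, at$atom, at$resid,
              f$coords[, 1], f$coords[, 2], f$coords[, 3])), con)
  }
  invisible(path)
}

#' Read a (multi-frame) XYZ file
#'
#' @param path XYZ file path written by [write_xyz()] (atom names
#'   `residue:atom`) or plain XYZ (names taken as residue names).
#' @param map a `component_map`.
#' @return a [particle_frame()] for single-frame files, a [trajectory()]
#'   otherwise.
#' @export
read_xyz <- function(path, map = default_component_map()) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i]))
    tm <- regmatches(lines[i + 1], regexec("t= *([0-9.eE+-]+)",
                                           lines[i + 1]))[[1]]
    time <- if (length(tm) == 2) as.numeric(tm[2]) else 0
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[ \t]+")
    rec <- do.call(rbind, rec)
    parts <- strsplit(rec[, 1], ":", fixed = TRUE)
    nf <- lengths(parts)
    resname <- vapply(parts, `[[`, character(1), 1)
    atom <- ifelse(nf >= 2, vapply(parts, function(p)
      if (length(p) >= 2) p[2] else "BD", character(1)), "BD")
    resid <- ifelse(nf >= 3, vapply(parts, function(p)
      if (length(p) >= 3) suppressWarnings(as.integer(p[3])) else
        NA_integer_, integer(1)), NA_integer_)
    xyz <- matrix(as.numeric(rec[, 2:4]), ncol = 3)
    frames[[length(frames) + 1]] <- list(xyz = xyz, resname = resname,
                                         atom = atom, resid = resid,
                                         time = time)
    i <- i + n + 2L
  }
  build <- function(fr, resid) {
    .bind_frame(fr$xyz, fr$resname, resid, fr$atom, map, time = fr$time)
  }
  # molecule ids come from the name's third field when present; otherwise a
  # new molecule starts at every head atom, residue-name change, or for
  # every bead of a residue without head/tail atoms
  mk_resid <- function(fr) {
    if (!anyNA(fr$resid)) return(fr$resid)
    single <- !fr$resname %in% names(map$head_atom)
    newmol <- fr$atom == "HD" | single |
      c(TRUE, fr$resname[-1] != fr$resname[-length(fr$resname)])
    cumsum(as.integer(newmol))
  }
  if (length(frames) == 1) return(build(frames[[1]], mk_resid(frames[[1]])))
  topo <- build(frames[[1]], mk_resid(frames[[1]]))
  trajectory(topo, lapply(frames, `[[`, "xyz"),
             times = vapply(frames, `[[`, numeric(1), "time"))
}

#' Write a particle frame as PDB
#'
#' Uses bio3d; the component name becomes the residue name and the exposure
#' or any per-bead score can be written into the B-factor column.
#'
#' @param frame a [particle_frame()].
#' @param path output path.
#' @param bfactor optional per-bead numeric vector (e.g. exposure
#'   frequency) stored in the B-factor column.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(frame, path, bfactor = NULL) {
  at <- .atom_table(frame)
  if (is.null(bfactor)) bfactor <- rep(0, n_beads(frame))
  bio3d::write.pdb(file = path, xyz = as.vector(t(frame$coords)),
                   resno = at$resid %% 10000L, resid = at$resname,
                   elety = at$atom, b = bfactor)
  invisible(path)
}

#' Read a PDB file into a particle frame
#'
#' @param path PDB file path.
#' @param map a `component_map`.
#' @return a [particle_frame()].
#' @export
read_pdb <- function(path, map = default_component_map()) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  runs <- cumsum(c(1L, as.integer(diff(a$resno) != 0)))
  .bind_frame(cbind(a$x, a$y, a$z), a$resid, runs, a$elety, map)
}

#' Read a topology + trajectory pair
#'
#' Binds a coordinate file (PDB or GRO) and an optional trajectory (DCD via
#' bio3d, or multi-frame XYZ) into a [trajectory()]. Frame times are
#' `frame_index x dt`.
#'
#' @param topology_path PDB or GRO file.
#' @param trajectory_path optional DCD or multi-frame XYZ file.
#' @param map a `component_map`.
#' @param dt frame spacing in ns for formats that do not store time.
#' @return a [trajectory()] (a single-frame trajectory when no trajectory
#'   file is given).
#' @export
read_system <- function(topology_path, trajectory_path = NULL,
                        map = default_component_map(), dt = 1) {
  ext <- tolower(tools::file_ext(topology_path))
  topo <- switch(ext,
    gro = read_gro(topology_path, map),
    pdb = read_pdb(topology_path, map),
    xyz = read_xyz(topology_path, map),
    stop("unsupported topology format: .", ext))
  if (inherits(topo, "trajectory")) topo <- get_frame(topo, 1)
  if (is.null(trajectory_path)) {
    return(trajectory(topo, list(topo$coords), times = topo$time))
  }
  text <- tolower(tools::file_ext(trajectory_path))
  if (text == "dcd") {
    xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
    nf <- nrow(xyz)
    natom <- ncol(xyz) / 3
    if (natom != n_beads(topo)) {
      stop("atom-count mismatch: topology has ", n_beads(topo),
           " atoms, trajectory has ", natom)
    }
    coords <- lapply(seq_len(nf), function(i)
      matrix(xyz[i, ], ncol = 3, byrow = TRUE))
    trajectory(topo, coords, times = dt * (seq_len(nf) - 1))
  } else if (text == "xyz") {
    tr <- read_xyz(trajectory_path, map)
    if (inherits(tr, "particle_frame")) {
      tr <- trajectory(tr, list(tr$coords), times = tr$time)
    }
    if (n_beads(tr$topology) != n_beads(topo)) {
      stop("atom-count mismatch: topology has ", n_beads(topo),
           " atoms, trajectory has ", n_beads(tr$topology))
    }
    trajectory(topo, tr$coords, times = tr$times)
  } else {
    stop("unsupported trajectory format: .", text)
  }
}

#' Write a morphology report to disk
#'
#' Deterministic CSV/JSON layout: `report.json` holds the full report
#' (schema-versioned), and each tabular section is also written as CSV.
#' Identical reports produce byte-identical files; empty optional sections
#' are omitted.
#'
#' @param report a list as produced by [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return invisible character vector of the files written.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("unwritable output path: ", out_dir)
  }
  report$schema <- "aeromorph-report/1"
  files <- file.path(out_dir, "report.json")
  jsonlite::write_json(.jsonable(report), files, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  for (sec in c("shape", "clustering", "partition_table",
                "diffusion_profile", "exposure")) {
    tab <- report[[sec]]
    if (is.data.frame(tab) && nrow(tab)) {
      f <- file.path(out_dir, paste0(sec, ".csv"))
      utils::write.csv(tab, f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  invisible(files)
}

# strip classes/attributes so jsonlite serializes deterministically
.jsonable <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(lapply(x, unclass),
                                             check.names = FALSE))
  if (is.list(x)) {
    x <- lapply(x, .jsonable)
    attributes(x) <- list(names = names(x))
    return(x)
  }
  if (is.matrix(x)) return(unclass(x))
  unclass(x)
}

#' Read a morphology report written by [write_report()]
#' @param out_dir directory holding `report.json`.
#' @return the report list.
#' @export
read_report <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "report.json"),
                      simplifyVector = TRUE)
}
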