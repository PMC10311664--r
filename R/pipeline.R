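#' Build a pipeline configuration
#'
#' Collects the per-stage parameters of the full analysis. Either a
#' generator spec (`system_id`, `diameter`, ...) or input files
#' (`topology_path`, `trajectory_path`) define the input; one global seed is
#' fanned out to per-stage child seeds by a fixed derivation
#' (seed * 1000 + stage index, modulo 2^31 - 1).
#'
#' @param system_id "A", "B" or "C" for the generator input (ignored when
#'   `topology_path` is given).
#' @param diameter generated particle diameter, Angstrom.
#' @param topology_path,trajectory_path optional input files, see
#'   [read_system()].
#' @param stages subset of c("generate", "shape", "cluster", "partition",
#'   "diffuse", "surface") to run.
#' @param seed global integer seed.
#' @param n_frames,dt generated-trajectory length and spacing (frames, ns).
#' @param shell_D generator shell diffusivities (data.frame `r_min`,
#'   `r_max`, `D`), or NULL for a default two-band profile.
#' @param eps,min_samples,w clustering parameters ([cluster_lipids()],
#'   [lipid_features()]).
#' @param n_shells equal-volume shell count ([shell_boundaries()]).
#' @param slice_length,n_slices MSD slicing ([compute_msd()]).
#' @param shell_edges radii for the diffusion profile, or NULL for
#'   quartiles of the particle radius.
#' @param a_lipid,d_exp surface-module parameters ([surface_report()],
#'   [residue_exposure()]).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(system_id = "A", diameter = 200,
                            topology_path = NULL, trajectory_path = NULL,
                            stages = c("generate", "shape", "cluster",
                                       "partition", "diffuse", "surface"),
                            seed = 1, n_frames = 51, dt = 0.1,
                            shell_D = NULL, eps = 12, min_samples = 5,
                            w = 10, n_shells = 3, slice_length = 1,
                            n_slices = 5, shell_edges = NULL, a_lipid = 21,
                            d_exp = 3) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(eps > 0, min_samples >= 1, w >= 0, n_shells >= 1,
            slice_length > 0, n_slices >= 1, a_lipid > 0, d_exp >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

.child_seed <- function(seed, k) {
  (as.numeric(seed) * 1000 + k) %% (2^31 - 1)
}

#' Run the whole-aerosol morphology pipeline
#'
#' Executes the requested stages in dependency order — generate (or read) ->
#' shape -> cluster -> partition -> diffuse -> surface — and returns one
#' morphology report. A stage failure aborts its downstream dependents but
#' the report still lists every completed stage. Identical config + seed
#' give identical reports.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress with timings to stderr.
#' @return list of class `morphology_report` with the config echo, the seed,
#'   per-stage sections (`composition`, `shape`, `clustering`,
#'   `ellipsoid`, `partition_table`, `diffusion_profile`, `surface`,
#'   `exposure`) and a `stages` status table.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  status <- list()
  report <- list(config = config[setdiff(names(config), "")],
                 seed = config$seed)
  run_stage <- function(name, deps, fun) {
    if (!name %in% c(config$stages, "input")) return(invisible(NULL))
    failed_dep <- deps[!vapply(deps, function(d)
      identical(status[[d]], "ok"), logical(1))]
    if (length(failed_dep)) {
      status[[name]] <<- paste("skipped: needs", failed_dep[1])
      return(invisible(NULL))
    }
    t0 <- proc.time()[3]
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE,
                                             msg = conditionMessage(e)))
    el <- proc.time()[3] - t0
    if (res$ok) {
      status[[name]] <<- "ok"
      say("stage %-9s ok   (%.2f s)", name, el)
      return(res$value)
    }
    status[[name]] <<- paste("error:", res$msg)
    say("stage %-9s FAIL (%.2f s): %s", name, el, res$msg)
    invisible(NULL)
  }

  env <- new.env()
  input <- run_stage("input", character(0), function() {
    if (!is.null(config$topology_path)) {
      read_system(config$topology_path, config$trajectory_path)
    } else {
      comp <- build_composition(config$system_id, config$diameter)
      frame <- generate_particle(comp, seed = .child_seed(config$seed, 1))
      R <- config$diameter / 2
      shell_D <- config$shell_D
      if (is.null(shell_D)) {
        shell_D <- data.frame(r_min = c(0, 0.7 * R),
                              r_max = c(0.7 * R, R), D = c(0.5, 2.0))
      }
      traj <- generate_brownian_trajectory(frame, shell_D, dt = config$dt,
                                           n_frames = config$n_frames,
                                           seed = .child_seed(config$seed,
                                                              2))
      report$composition <<- list(
        system_id = comp$spec$system_id,
        counts = as.list(comp$counts),
        achieved_mass_fractions = as.list(comp$achieved$mass_fractions),
        fa_share_of_organic_pct = comp$achieved$fa_share_of_organic_pct)
      traj
    }
  })
  status[["input"]] <- if (is.null(input)) status[["input"]] else "ok"

  run_or <- function(name, fun) run_stage(name, "input", fun)

  report$shape <- run_or("shape", function() shape_series(input))

  kin <- NULL; feats <- NULL; assign_last <- NULL
  if ("cluster" %in% config$stages) {
    kin <- run_stage("cluster", "input", function()
      clustering_kinetics(input, eps = config$eps,
                          min_samples = config$min_samples, w = config$w))
    if (!is.null(kin)) {
      report$clustering <- kin$summary
      assign_last <- kin$assignments[[length(kin$assignments)]]
    }
  }

  model <- NULL
  if (any(c("partition", "surface") %in% config$stages)) {
    last <- get_frame(input, n_frames(input))
    model <- run_stage("partition", "input", function()
      fit_bounding_ellipsoid(last))
    if (!is.null(model)) {
      report$ellipsoid <- list(center = model$center,
                               semi_axes = model$semi_axes)
      bounds <- shell_boundaries(config$n_shells)
      labels <- assign_regions(last, model, bounds)
      report$partition_table <- region_mass_fractions(last, labels)
    }
  }

  if ("diffuse" %in% config$stages) {
    report$diffusion_profile <- run_stage("diffuse", "input", function() {
      edges <- config$shell_edges
      if (is.null(edges)) {
        last <- get_frame(input, n_frames(input))
        ctr <- colSums(last$coords * last$masses) / sum(last$masses)
        rmax <- max(sqrt(rowSums(sweep(last$coords, 2, ctr)^2)))
        edges <- rmax * c(0, 0.5, 0.8, 1.05)
      }
      radial_diffusion_profile(input, edges, config$slice_length,
                               config$n_slices)
    })
  }

  if ("surface" %in% config$stages) {
    surface_deps <- c("input", "cluster", "partition")
    surf <- run_stage("surface", surface_deps, function() {
      last <- get_frame(input, n_frames(input))
      feats <- lipid_features(last, w = config$w)
      rafts <- identify_surface_rafts(assign_last, feats, model)
      n_total <- nrow(last$surfactants)
      rep <- surface_report(rafts, model, n_total, a_lipid = config$a_lipid)
      expo <- residue_exposure(input, model, d_exp = config$d_exp)
      list(report = rep, exposure = expo, rafts = rafts)
    })
    if (!is.null(surf)) {
      report$surface <- surf$report[setdiff(names(surf$report),
                                            "raft_curvature")]
      report$surface$raft_curvature <- surf$report$raft_curvature
      report$exposure <- surf$exposure
    }
  }

  report$stages <- data.frame(stage = names(status),
                              status = unlist(status, use.names = FALSE))
  class(report) <- c("morphology_report", "list")
  report
}

#' @export
print.morphology_report <- function(x, ...) {
  cat("morphology report (seed", x$seed, ")\n")
  print(x$stages)
  invisible(x)
}
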