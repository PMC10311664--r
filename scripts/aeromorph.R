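#!/usr/bin/env Rscript
# Thin command-line wrapper over the aeromorph package.
#
#   Rscript scripts/aeromorph.R generate --system A --diameter 400 \
#       --seed 7 --out particle.gro
#   Rscript scripts/aeromorph.R run --system A --diameter 200 --seed 1 \
#       --out report_dir
#   Rscript scripts/aeromorph.R shape --topology top.gro --trajectory tr.xyz \
#       --out shape.csv

suppressPackageStartupMessages({
  library(optparse)
  library(aeromorph)
})

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  message("usage: aeromorph.R <generate|run|shape> [options]")
  quit(status = 2)
}
cmd <- args[1]

parser <- OptionParser(option_list = list(
  make_option("--system", default = "A"),
  make_option("--diameter", type = "double", default = 400),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", default = "out"),
  make_option("--topology", default = NULL),
  make_option("--trajectory", default = NULL),
  make_option("--frames", type = "integer", default = 51L),
  make_option("--dt", type = "double", default = 0.1)
))
o <- tryCatch(parse_args(parser, args[-1]),
              error = function(e) { message(conditionMessage(e))
                                    quit(status = 2) })

status <- tryCatch({
  if (cmd == "generate") {
    comp <- build_composition(o$system, diameter = o$diameter)
    frame <- generate_particle(comp, seed = o$seed)
    write_gro(frame, o$out)
    message("wrote ", o$out, " (", n_beads(frame), " beads)")
    0
  } else if (cmd == "shape") {
    traj <- read_system(o$topology, o$trajectory)
    write.csv(shape_series(traj), o$out, row.names = FALSE)
    message("wrote ", o$out)
    0
  } else if (cmd == "run") {
    cfg <- pipeline_config(system_id = o$system, diameter = o$diameter,
                           topology_path = o$topology,
                           trajectory_path = o$trajectory,
                           seed = o$seed, n_frames = o$frames, dt = o$dt)
    report <- run_pipeline(cfg, verbose = TRUE)
    write_report(report, o$out)
    message("wrote report to ", o$out)
    if (all(report$stages$status == "ok")) 0 else 3
  } else {
    message("unknown subcommand: ", cmd)
    2
  }
}, error = function(e) { message("error: ", conditionMessage(e)); 3 })

quit(status = status)
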