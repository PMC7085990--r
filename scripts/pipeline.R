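#!/usr/bin/env Rscript
# Thin command-line wrapper over the petkin pipeline functions.
#
#   Rscript scripts/pipeline.R demo     --out DIR [--seed N] [--noise S]
#   Rscript scripts/pipeline.R simulate --out DIR [--seed N] [--noise S]
#   Rscript scripts/pipeline.R study    --out DIR [--seed N] [--noise S]
#                                       [--tstar T] [--vb-correction]
#
# demo:     reduced phantom, full pipeline (fast)
# simulate: build the default phantom and write its tables/manifest only
# study:    full pipeline on the default-size phantom

suppressMessages(library(petkin))
suppressMessages(library(optparse))

parser <- OptionParser(
  usage = "%prog {demo|simulate|study} [options]",
  option_list = list(
    make_option("--out", type = "character", default = "petkin_out",
                help = "output directory [default %default]"),
    make_option("--seed", type = "integer", default = 1L,
                help = "RNG seed [default %default]"),
    make_option("--noise", type = "double", default = 1.5,
                help = "phantom noise scale [default %default]"),
    make_option("--tstar", type = "double", default = 15,
                help = "Patlak t* in minutes [default %default]"),
    make_option("--vb-correction", action = "store_true", default = FALSE,
                dest = "vb_correction",
                help = "apply the (1 - Vb) tissue-coefficient correction")))
parsed <- parse_args(parser, positional_arguments = 1L)
cmd <- parsed$args
o <- parsed$options

if (cmd == "demo") {
  res <- run_demo(outdir = o$out, seed = o$seed,
                  noise_scale = min(o$noise, 0.5))
  print(res)
} else if (cmd == "simulate") {
  spec <- phantom_spec(noise_scale = o$noise, seed = o$seed)
  ph <- make_phantom(spec)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  write.csv(ph$truth$params, file.path(o$out, "truth_params.csv"),
            row.names = FALSE)
  saveRDS(ph, file.path(o$out, "phantom.rds"))
  jsonlite::write_json(
    list(seed = o$seed, dim = spec$dim, voxel_mm = spec$voxel_mm,
         noise_scale = spec$noise_scale, n_lesions = nrow(spec$lesions)),
    file.path(o$out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  print(ph)
} else if (cmd == "study") {
  cfg <- run_config(outdir = o$out,
                    spec = phantom_spec(noise_scale = o$noise, seed = o$seed),
                    t_star = o$tstar, vb_correction = o$vb_correction,
                    seed = o$seed)
  res <- run_study(cfg)
  print(res)
} else {
  stop("unknown command: ", cmd, " (expected demo, simulate, or study)")
}
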