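#!/usr/bin/env Rscript
# Long-running gait optimization (not part of the test suite).
#
# Stage 1 ("self-selected gait"): optimize all 43 parameters + v_init with
# the unconstrained walking cost. Stage 2 ("targeted gait"): optimize the 8
# control parameters + v_init for a target step length and cadence with the
# staged cost, starting from the stage-1 result. The best parameter set is
# written as YAML; point inst/extdata/optimized_gait.yaml at it to refresh
# the shipped gait.
#
# Usage:
#   Rscript scripts/optimize_gait.R --stage 1 --budget 20000 --seed 1 --out DIR
#   Rscript scripts/optimize_gait.R --stage 2 --cadence 110 --step-length 0.7 \
#       --params DIR/best_params.yaml --budget 2000 --seed 1 --out DIR2

suppressPackageStartupMessages({
  library(optparse)
  library(gaitplanr)
})

opt <- parse_args(OptionParser(option_list = list(
  make_option("--stage", type = "integer", default = 1L),
  make_option("--cadence", type = "double", default = 110),
  make_option("--step-length", type = "double", default = 0.7, dest = "sl"),
  make_option("--params", type = "character", default = NULL),
  make_option("--budget", type = "integer", default = 20000L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "opt_out")
)))

dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
model <- load_model()
params <- default_params(opt$params)

cb <- function(gen, best_x, best_f) {
  if (gen %% 5 == 0) {
    cat(sprintf("[gen %d] best %.4f\n", gen, best_f))
    saveRDS(list(gen = gen, best_x = best_x, best_f = best_f),
            file.path(opt$out, "checkpoint.rds"))
  }
}

res <- if (opt$stage == 1) {
  optimize_gait(params, "all", model = model, budget = opt$budget,
                seed = opt$seed, callback = cb)
} else {
  optimize_gait(params, "control", cadence_target = opt$cadence,
                step_length_target = opt$sl, model = model,
                budget = opt$budget, seed = opt$seed, callback = cb)
}

yaml::write_yaml(unclass(res$params), file.path(opt$out, "best_params.yaml"))
utils::write.csv(tidy(res), file.path(opt$out, "trace.csv"),
                 row.names = FALSE)
print(res)
sim <- run_simulation(res$params, model, duration = 20, log_muscles = FALSE)
print(sim)
print(gait_metrics(sim))
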