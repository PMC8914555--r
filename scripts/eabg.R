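#!/usr/bin/env Rscript
# Command-line front end for the blood-gel authentication pipeline.
#
#   Rscript scripts/eabg.R simulate --seed 7 --out profiles.csv
#       [--n-per-class 30] [--correlation 0.2] [--use-printed-chicken-fe]
#   Rscript scripts/eabg.R run-grid --profiles profiles.csv --out report/
#       [--reps 12] [--seed 7] [--config run.yaml]
#   Rscript scripts/eabg.R check-consistency
#   Rscript scripts/eabg.R report --runs report/grid_runs.csv

suppressMessages(library(eabgauth))

args <- commandArgs(trailingOnly = TRUE)
usage <- function() {
  cat("subcommands: simulate | run-grid | check-consistency | report\n")
  quit(status = 2L)
}
if (length(args) < 1L) usage()
cmd <- args[1L]
args <- args[-1L]

get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
has_flag <- function(flag) flag %in% args

write_resolved_config <- function(cfg, dir) {
  yaml::write_yaml(unclass(cfg), file.path(dir, "resolved_config.yaml"))
}

if (cmd == "simulate") {
  out <- get_arg("--out", "profiles.csv")
  cfg <- load_config(get_arg("--config"))
  cfg$seed <- as.integer(get_arg("--seed", cfg$seed))
  gen <- generator_config(
    n_per_class = as.integer(get_arg("--n-per-class",
                                     cfg$generator$n_per_class)),
    seed = cfg$seed,
    heavy_tail_threshold = cfg$generator$heavy_tail_threshold,
    use_printed_chicken_fe = has_flag("--use-printed-chicken-fe") ||
      cfg$generator$use_printed_chicken_fe,
    correlation = as.numeric(get_arg("--correlation",
                                     cfg$generator$correlation)))
  profiles <- generate_profiles(config = gen)
  write_profiles(profiles, out)
  message(sprintf("simulate: seed %d -> %d samples -> %s",
                  cfg$seed, nrow(profiles), out))
} else if (cmd == "run-grid") {
  path <- get_arg("--profiles")
  if (is.null(path)) { message("run-grid needs --profiles"); quit(status = 2L) }
  outdir <- get_arg("--out", "report")
  cfg <- load_config(get_arg("--config"))
  cfg$seed <- as.integer(get_arg("--seed", cfg$seed))
  n_reps <- as.integer(get_arg("--reps", cfg$experiment$n_reps))
  profiles <- read_profiles(path, kind = "absolute")
  t0 <- Sys.time()
  grid <- run_grid(profiles, n_reps = n_reps, master_seed = cfg$seed,
                   options = as_run_options(cfg))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(grid$summary, file.path(outdir, "accuracy_table.csv"),
                   row.names = FALSE)
  utils::write.csv(grid$runs, file.path(outdir, "grid_runs.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(grid$best, auto_unbox = TRUE, digits = NA),
             file.path(outdir, "best_model.json"))
  write_resolved_config(cfg, outdir)
  message(sprintf("run-grid: %d fits in %.1f s -> %s", grid$total_fits,
                  as.numeric(Sys.time() - t0, units = "secs"), outdir))
  print(grid)
} else if (cmd == "check-consistency") {
  tab <- consistency_table()
  tab$ratio_of_means <- signif(tab$ratio_of_means, 4)
  tab$deviation <- sprintf("%.2f%%", 100 * tab$deviation)
  print(tab, row.names = FALSE)
  message(sum(tab$flagged), " cell(s) flagged (deviation > 10%)")
} else if (cmd == "report") {
  path <- get_arg("--runs", "report/grid_runs.csv")
  runs <- utils::read.csv(path)
  agg <- stats::aggregate(test_accuracy ~ dataset_kind + selector +
                            reducer + activation, runs,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  print(do.call(data.frame, agg), row.names = FALSE)
} else {
  usage()
}
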