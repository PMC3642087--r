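#!/usr/bin/env Rscript
# Thin command-line front end over the fociseg package.
#
#   Rscript scripts/fociseg.R simulate --config run.yaml [--out table.tsv]
#   Rscript scripts/fociseg.R simulate --mode citrate --n 5000 --seed 7 \
#       --channels "ori=82-R,ref=3,028-R,rep=REPLISOME" --out table.tsv
#   Rscript scripts/fociseg.R analyze --table table.tsv --ref ref --outdir out/
#   Rscript scripts/fociseg.R report  --table table.tsv --outdir out/
#
# The acceptance runner lives in scripts/acceptance.R.

suppressPackageStartupMessages(library(fociseg))

usage <- function(status = 2L) {
  cat("usage: fociseg.R <simulate|analyze|report> [options]\n",
      "  simulate: --mode <citrate|glucose_caa|par_null> --n <cells>",
      " --seed <int> [--channels name=locus,...] [--config run.yaml]",
      " [--truth] --out <file>\n",
      "  analyze:  --table <file> [--ref <channel>] --outdir <dir>\n",
      "  report:   --table <file> --outdir <dir>\n", sep = "")
  quit(status = status)
}

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) usage()
cmd <- args[1]
args <- args[-1]
opt <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}
has_flag <- function(flag) flag %in% args

parse_channels <- function(spec) {
  # "ori=82-R,ref=3,028-R" -- commas inside locus labels are digit,digit
  protected <- gsub("(\\d),(\\d)", "\\1<comma>\\2", spec)
  parts <- strsplit(protected, ",")[[1]]
  parts <- gsub("<comma>", ",", parts, fixed = TRUE)
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2),
                  vapply(kv, `[`, character(1), 1))
}

log_msg <- function(...) message("[fociseg] ", ...)

if (cmd == "simulate") {
  cfg_file <- opt("--config")
  if (!is.null(cfg_file)) {
    rc <- read_run_config(cfg_file)
    channels <- unlist(rc$channels)
    cfg <- sim_config(rc$mode, rc$n_cells, seed = rc$seed,
                      channels = channels,
                      params = if (is.null(rc$params)) list() else rc$params)
    out <- opt("--out", file.path(if (is.null(rc$out_dir)) "." else rc$out_dir,
                                  "cells.tsv"))
  } else {
    mode <- opt("--mode"); n <- opt("--n"); seed <- opt("--seed")
    out <- opt("--out")
    if (is.null(mode) || is.null(n) || is.null(seed) || is.null(out)) usage()
    channels <- parse_channels(opt("--channels", "ori=82-R,dif=3,090-L"))
    cfg <- sim_config(mode, as.integer(n), seed = as.integer(seed),
                      channels = channels)
  }
  tab <- sample_population(cfg)
  write_cell_table(tab, out, truth = has_flag("--truth"))
  log_msg("mode=", cfg$mode, " n=", cfg$n_cells, " seed=", cfg$seed,
          " -> ", out, " (", nrow(tab), " rows)")
} else if (cmd == "analyze") {
  table_file <- opt("--table"); outdir <- opt("--outdir")
  if (is.null(table_file) || is.null(outdir)) usage()
  tab <- read_cell_table(table_file)
  ref <- opt("--ref")
  if (!is.null(ref) && !ref %in% tab$channel) {
    message("error: reference channel '", ref, "' not found in ", table_file)
    quit(status = 1L)
  }
  files <- analyze_all(tab, ref_channel = ref, out_dir = outdir)
  log_msg("wrote ", length(files), " summary tables to ", outdir)
} else if (cmd == "report") {
  table_file <- opt("--table"); outdir <- opt("--outdir")
  if (is.null(table_file) || is.null(outdir)) usage()
  tab <- read_cell_table(table_file)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  chans <- vapply(attr(tab, "channels"), as.character, character(1))
  locus_chans <- names(chans)[chans != "REPLISOME"]
  ref <- opt("--ref", locus_chans[length(locus_chans)])
  ot <- orient(tab, ref)
  for (ch in locus_chans) {
    png_path <- file.path(outdir, paste0("profile_", ch, ".png"))
    grDevices::png(png_path, width = 640, height = 480)
    plot_segregation_profile(segregation_profile_curve(ot, ch))
    grDevices::dev.off()
    png_path <- file.path(outdir, paste0("curve_", ch, ".png"))
    grDevices::png(png_path, width = 640, height = 480)
    plot_segregation_curve(segregation_curves(tab, ch))
    grDevices::dev.off()
  }
  log_msg("figures written to ", outdir)
} else {
  usage()
}
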