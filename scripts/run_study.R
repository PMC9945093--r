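#!/usr/bin/env Rscript
# Thin command-line wrapper over petsuvr::run_study(): simulate a
# two-genotype cohort, fit SRTM per region, validate SUVR windows against
# DVR, compare genotypes and solve the power grid, writing all tables to
# an output directory.
#
# Usage: Rscript scripts/run_study.R [--config config.yaml] [--seed <int>]
#        [--n-per-group <int>] [--out <dir>]

suppressPackageStartupMessages({
  library(optparse)
  library(petsuvr)
})

parser <- OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML run configuration"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the run seed"),
  make_option("--n-per-group", type = "integer", default = NULL,
              dest = "n_per_group", help = "animals per genotype"),
  make_option("--out", type = "character", default = "study_out",
              help = "output directory [default %default]")))
opt <- parse_args(parser)

cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else run_config()
if (!is.null(opt$seed)) cfg$seed <- opt$seed
if (!is.null(opt$n_per_group)) cfg$n_per_group <- opt$n_per_group

report <- run_study(cfg, out_dir = opt$out)
print(report)
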