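#!/usr/bin/env Rscript
# Thin command-line wrapper around the simulation pipeline: generates a
# synthetic architecture database and weather series, runs a growth-cycle
# simulation for one treatment, and writes daily/cumulative budget CSVs.
#
# Usage:
#   Rscript scripts/simulate.R --treatment 3B --days 35 --seed 42 \
#     --rays 200000 --out results/

suppressPackageStartupMessages({
  library(optparse)
  library(rosecanopy)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--treatment", default = "3B", help = "0B, 1B or 3B"),
  make_option("--days", type = "integer", default = 35L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--rays", type = "integer", default = 200000L),
  make_option("--bent-lai", type = "double", default = NA,
              dest = "bent_lai", help = "override bent-shoot LAI"),
  make_option("--out", default = "results/")
)))

db <- generate_architecture_db(opts$treatment, n_shoots = 18,
                               seed = opts$seed)
weather <- generate_weather(opts$days, seed = opts$seed + 1)
scn <- scenario(opts$treatment,
                bent_lai_override = if (is.na(opts$bent_lai)) NULL else
                  opts$bent_lai)
res <- simulate_period(scn, db, weather, days = opts$days,
                       n_rays = opts$rays, seed = opts$seed)
print(res)
write_budget_csv(res, opts$out)
cat("budgets written to", opts$out, "\n")
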