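#!/usr/bin/env Rscript
# Synthetic observer cohorts.
#
# Simulates 25-participant cohorts under each named generative model with
# response-stage (late) noise SD 1.4 on the integer 1-9 scale, writing one
# long-format CSV per cohort plus a provenance JSON.

suppressPackageStartupMessages({
  library(pleasurepairs)
  library(jsonlite)
})
dir.create("results", showWarnings = FALSE)

catalog <- select_stimuli(synthetic_rating_table(900, seed = 1))
models <- c("faithful", "compulsory_averaging", "partial_averaging",
            "compressive", "expansive")

provenance <- list()
for (model in models) {
  dat <- simulate_cohort(25, catalog, model, late_noise_sd = 1.4, seed = 1)
  path <- sprintf("results/ratings_%s.csv", model)
  write_rating_data(dat, path)
  cat(sprintf("%-22s %6d trials -> %s\n", model, nrow(dat), path))
  provenance[[model]] <- c(
    list(n_participants = 25, early_noise_sd = 0, late_noise_sd = 1.4,
         seed = 1, scheme = "linear_map", discretize = TRUE),
    generative_models()[[model]]
  )
}
write_json(provenance, "results/observer_specs.json", auto_unbox = TRUE,
           pretty = TRUE, digits = NA)
cat("observer provenance -> results/observer_specs.json\n")
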