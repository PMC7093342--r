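dataset_columns <- c("participant", "block", "block_type", "trial", "cue",
                     "left_image", "right_image", "target_side", "rating")

#' Write a rated-trial dataset as long-format CSV
#'
#' @param dataset Long-format rated-trial data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rating_data <- function(dataset, path) {
  utils::write.csv(dataset[, dataset_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a rated-trial dataset from long-format CSV
#'
#' Validates the header, preserves row order, and checks every rating
#' against the response scale; integer scales reject fractional ratings.
#'
#' @param path CSV file with the documented header.
#' @param response_scale Rating bounds (default 1-9).
#' @param discrete If `TRUE` (default) ratings must be whole numbers.
#' @return Long-format rated-trial data.frame.
#' @export
read_rating_data <- function(path, response_scale = c(1, 9),
                             discrete = TRUE) {
  dat <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_with("cannot read '%s': %s", path,
                                  conditionMessage(e))
  )
  missing_cols <- setdiff(dataset_columns, names(dat))
  if (length(missing_cols) > 0) {
    stop_with("malformed header in '%s': missing column(s) %s", path,
              paste(missing_cols, collapse = ", "))
  }
  if (nrow(dat) == 0) stop_with("empty dataset in '%s'", path)
  for (col in c("left_image", "right_image")) {
    dat[[col]] <- as.character(dat[[col]])
    dat[[col]][!is.na(dat[[col]]) & dat[[col]] == ""] <- NA_character_
  }

  bad_range <- which(!is.na(dat$rating) &
                       (dat$rating < response_scale[1] |
                          dat$rating > response_scale[2]))
  if (length(bad_range) > 0) {
    stop_with("rating out of range [%g, %g] at row %d (value %g)",
              response_scale[1], response_scale[2], bad_range[1],
              dat$rating[bad_range[1]])
  }
  if (discrete) {
    bad_int <- which(!is.na(dat$rating) &
                       abs(dat$rating - round(dat$rating)) > 1e-8)
    if (length(bad_int) > 0) {
      stop_with("non-integer rating at row %d (value %g)",
                bad_int[1], dat$rating[bad_int[1]])
    }
  }
  dat[, dataset_columns]
}

#' Configuration for the end-to-end simulation-and-analysis pipeline
#'
#' Collects the study constants and the generative-model settings, validates
#' them, and computes a provenance hash over the serialized configuration.
#'
#' @param seed Master seed.
#' @param n_participants Cohort size.
#' @param model Generative model name, see [simulate_cohort()].
#' @param early_noise_sd,late_noise_sd Noise SDs (scalar or length-2 range).
#' @param scheme Latent-pleasure scheme.
#' @param discretize Round/clip reports to the integer scale.
#' @param n_images Size of the synthetic norm table.
#' @param n_per_quintile,n_training Stimulus-selection counts.
#' @param beauty_scale,response_scale Scale bounds.
#' @return A `pipeline_config` list with a `hash` field.
#' @export
pipeline_config <- function(seed = 1, n_participants = 25,
                            model = "faithful", early_noise_sd = 0,
                            late_noise_sd = 1.4, scheme = "linear_map",
                            discretize = TRUE, n_images = 900,
                            n_per_quintile = 8, n_training = 4,
                            beauty_scale = c(1, 7),
                            response_scale = c(1, 9)) {
  cfg <- list(
    seed = as.integer(seed), n_participants = as.integer(n_participants),
    model = model, early_noise_sd = early_noise_sd,
    late_noise_sd = late_noise_sd, scheme = scheme, discretize = discretize,
    n_images = as.integer(n_images),
    n_per_quintile = as.integer(n_per_quintile),
    n_training = as.integer(n_training),
    beauty_scale = beauty_scale, response_scale = response_scale
  )
  if (cfg$n_participants < 1) stop_with("n_participants must be >= 1")
  if (!cfg$model %in% names(generative_models())) {
    stop_with("unknown generative model '%s'", cfg$model)
  }
  if (cfg$n_training > cfg$n_per_quintile) {
    stop_with("n_training must not exceed n_per_quintile")
  }
  cfg$hash <- fnv1a_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes the complete sequence: stimulus selection and design generation,
#' cohort simulation, LOOCV model comparison for both trial types, the
#' error-based reliability analyses (Cronbach's alphas, baseline ICC,
#' cross-condition correlations with attenuation ceilings) and the
#' rating-variance analyses. The returned report embeds the configuration
#' and its hash, and is byte-identical across runs with the same
#' configuration. Any stage error propagates with the stage name; stage
#' boundaries are logged via `message()`.
#'
#' @param config A `pipeline_config`.
#' @return A nested list report.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    message(sprintf("[pleasurepairs] stage: %s", name))
    tryCatch(expr, error = function(e) {
      stop_with("stage '%s': %s", name, conditionMessage(e))
    })
  }

  catalog <- stage("design", {
    ratings <- synthetic_rating_table(config$n_images, config$seed,
                                      config$beauty_scale)
    select_stimuli(ratings, config$n_per_quintile, config$n_training,
                   config$beauty_scale)
  })
  design_report <- stage("design_validation", {
    validate_design(build_design(catalog, 0, config$seed))
  })

  dataset <- stage("simulate", {
    simulate_cohort(
      config$n_participants, catalog, config$model,
      early_noise_sd = config$early_noise_sd,
      late_noise_sd = config$late_noise_sd,
      seed = config$seed, scheme = config$scheme,
      discretize = config$discretize
    )
  })

  comparison <- stage("model_comparison", compare_models(dataset))

  reliability <- stage("reliability", {
    corr <- error_correlations(dataset)
    list(
      alphas = as.list(corr$alphas),
      icc_baseline = icc_absolute_agreement(baseline_ratings(dataset)),
      correlations = corr$correlations
    )
  })

  variance <- stage("variance", {
    sds <- rating_sds(dataset)
    early <- mean(config$early_noise_sd)
    late <- mean(config$late_noise_sd)
    ratio <- if (early > 0 || late > 0) {
      as.numeric(variance_reduction_ratio(early, late, n_trials = 1e4,
                                          seed = config$seed))
    } else {
      NA_real_
    }
    list(
      participant_means = sds$participant_means,
      tests = compare_sds(sds),
      predicted_sd_ratio = ratio
    )
  })

  list(
    config = unclass(config)[setdiff(names(config), "hash")],
    config_hash = config$hash,
    seed = config$seed,
    design = list(
      n_main_images = sum(catalog$role == "main"),
      n_training_images = sum(catalog$role == "training"),
      checks_passed = design_report$pass
    ),
    model_comparison = list(
      summary = comparison$summary,
      winners = comparison$winners
    ),
    reliability = reliability,
    variance = variance
  )
}

#' Serialize a pipeline report as JSON
#'
#' @param report A report from [run_pipeline()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to `path`.
#' @export
report_json <- function(report, path = NULL) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
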