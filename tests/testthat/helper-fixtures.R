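# shared fixtures, all generated in code

# evenly spaced beauty grid; 40 rows = exactly the selection size
grid_rating_table <- function(n = 40) {
  data.frame(
    image_id = sprintf("g%02d", seq_len(n)),
    beauty = seq(1, 7, length.out = n),
    stringsAsFactors = FALSE
  )
}

# moderately sized catalog used across tests (deterministic)
test_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- select_stimuli(synthetic_rating_table(200, seed = 42))
    }
    cache
  }
})

# minimal hand-built design around explicit trial rows, for targeted
# simulation tests that need full control over what is shown
make_design <- function(trials, participant = 0L,
                        left_images = unique(stats::na.omit(trials$left_image)),
                        right_images = unique(stats::na.omit(trials$right_image))) {
  structure(
    list(
      participant_index = as.integer(participant), seed = 0L,
      side_mapping = c(left = "A", right = "B"),
      left_images = left_images, right_images = right_images,
      training_images = character(),
      main_images = c(left_images, right_images),
      n_cued_blocks_per_timing = 1,
      timing_ms = c(image = 200, cue = 1000),
      trials = trials
    ),
    class = "experiment_design"
  )
}

one_pleasure_trial <- function(n, cue = "left", left = "A1", right = "B1",
                               block_type = "precued") {
  data.frame(
    block = 1L, block_type = block_type, trial = seq_len(n), cue = cue,
    left_image = left, right_image = right,
    target_side = if (cue == "both") "both" else cue,
    stringsAsFactors = FALSE
  )
}

# small simulated cohort with the standard design
small_cohort <- function(n = 4, model = "faithful", early = 0, late = 1.4,
                         seed = 1, discretize = TRUE, scheme = "linear_map") {
  simulate_cohort(n, test_catalog(), model, early_noise_sd = early,
                  late_noise_sd = late, seed = seed, discretize = discretize,
                  scheme = scheme)
}

# synthetic trial observations with exact (noise-free) single-pleasures
synthetic_obs <- function(n, a = 0, b = 1, w = 1, noise_sd = 0, seed = 1,
                          trial_type = "one_pleasure") {
  withr_seed <- function(code) {
    set.seed(seed)
    code
  }
  withr_seed({
    P1 <- runif(n, 1, 9)
    P2 <- runif(n, 1, 9)
    y <- predict_rating(a, b, w, P1, P2) + rnorm(n, 0, noise_sd)
    out <- data.frame(P1 = P1, P2 = P2, rating = y)
    attr(out, "trial_type") <- trial_type
    out
  })
}

# independent brute-force LOOCV oracle: per-fold bounded 1-D minimization of
# the RMSE in w via stats::optimize (never touches the package's solvers)
oracle_loocv_w <- function(obs, lower = 0.5, upper = 1) {
  n <- nrow(obs)
  se <- numeric(n)
  for (i in seq_len(n)) {
    tr <- obs[-i, ]
    cost <- function(w) {
      sqrt(mean((tr$rating - (w * tr$P1 + (1 - w) * tr$P2))^2))
    }
    w <- stats::optimize(cost, c(lower, upper), tol = 1e-12)$minimum
    # compare the interior optimum against the bounds (optimize is local)
    cands <- c(w, lower, upper)
    w <- cands[which.min(vapply(cands, cost, numeric(1)))]
    se[i] <- (obs$rating[i] - (w * obs$P1[i] + (1 - w) * obs$P2[i]))^2
  }
  sqrt(mean(se))
}

# independent brute-force LOOCV oracle for (a, b) boxes via stats::optim
oracle_loocv_ab <- function(obs, lower, upper, w = 0.5) {
  n <- nrow(obs)
  se <- numeric(n)
  for (i in seq_len(n)) {
    tr <- obs[-i, ]
    m <- w * tr$P1 + (1 - w) * tr$P2
    cost <- function(p) sqrt(mean((tr$rating - p[1] - p[2] * m)^2))
    best <- NULL
    for (t in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
      res <- stats::optim(lower + t * (upper - lower), cost,
                          method = "L-BFGS-B", lower = lower, upper = upper,
                          control = list(factr = 1e1))
      if (is.null(best) || res$value < best$value) best <- res
    }
    mi <- w * obs$P1[i] + (1 - w) * obs$P2[i]
    se[i] <- (obs$rating[i] - best$par[1] - best$par[2] * mi)^2
  }
  sqrt(mean(se))
}
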