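#' Latent per-image pleasures for a synthetic observer
#'
#' Two schemes: `"linear_map"` affinely rescales catalog beauty from the norm
#' scale (1-7) onto the response scale (1-9), so beauty 1 maps to pleasure 1,
#' beauty 4 to 5, and beauty 7 to 9; `"uniform"` draws i.i.d. values from the
#' response scale, giving each observer idiosyncratic pleasures.
#'
#' @param catalog A `stimulus_catalog`.
#' @param seed Integer seed (used by the `"uniform"` scheme).
#' @param scheme `"linear_map"` or `"uniform"`.
#' @param beauty_scale Bounds of the norm scale (default 1-7).
#' @param response_scale Bounds of the response scale (default 1-9).
#' @return Named numeric vector, one latent pleasure per catalog image.
#' @export
sample_latent_pleasures <- function(catalog, seed = 1,
                                    scheme = c("linear_map", "uniform"),
                                    beauty_scale = c(1, 7),
                                    response_scale = c(1, 9)) {
  scheme <- match.arg(scheme)
  vals <- switch(scheme,
    linear_map = response_scale[1] +
      (catalog$beauty - beauty_scale[1]) *
        diff(response_scale) / diff(beauty_scale),
    uniform = with_seed(derive_seed(seed, salt = 2L),
                        stats::runif(nrow(catalog),
                                     response_scale[1], response_scale[2]))
  )
  stats::setNames(vals, catalog$image_id)
}

#' Define a synthetic observer
#'
#' An observer holds latent per-image pleasures and the parameters of its
#' generative combination rule: on every cued trial the two presented images
#' are sampled with independent early noise, combined linearly as
#' `a + b * (w * P1 + (1 - w) * P2)` (with `w` applied to target/distractor
#' on one-pleasure trials and fixed at 0.5 on combined trials), and a single
#' late noise draw is added at the response stage. Baseline trials report the
#' single image's sample plus late noise.
#'
#' @param latent_pleasures Named numeric vector of latent pleasures.
#' @param w Target weight in `[0.5, 1]`.
#' @param a Additive constant of the linear transform.
#' @param b Multiplicative constant, `> 0`.
#' @param early_noise_sd SD of the per-image sampling noise (one independent
#'   draw per presented image), `>= 0`.
#' @param late_noise_sd SD of the response-stage noise (one draw per trial),
#'   `>= 0`.
#' @param seed Integer seed for the observer's private noise stream.
#' @param discretize If `TRUE` (default) reports are rounded to the nearest
#'   integer (half away from zero) and clipped to the response scale.
#' @param response_scale Bounds of the response scale.
#' @return An `observer_spec` object.
#' @export
observer_spec <- function(latent_pleasures, w = 1, a = 0, b = 1,
                          early_noise_sd = 0, late_noise_sd = 0, seed = 1,
                          discretize = TRUE, response_scale = c(1, 9)) {
  if (is.null(names(latent_pleasures)) || !all(is.finite(latent_pleasures))) {
    stop_with("latent_pleasures must be a named, finite numeric vector")
  }
  if (w < 0.5 || w > 1) stop_with("w must lie in [0.5, 1], got %g", w)
  if (b <= 0) stop_with("b must be > 0, got %g", b)
  if (early_noise_sd < 0 || late_noise_sd < 0 ||
      !is.finite(early_noise_sd) || !is.finite(late_noise_sd)) {
    stop_with("noise SDs must be finite and >= 0")
  }
  structure(
    list(latent_pleasures = latent_pleasures, w = w, a = a, b = b,
         early_noise_sd = early_noise_sd, late_noise_sd = late_noise_sd,
         seed = as.integer(seed), discretize = discretize,
         response_scale = response_scale),
    class = "observer_spec"
  )
}

#' Parameters of the named generative observer models
#'
#' The five standard observers: faithful (w = 1, identity transform),
#' compulsory averaging (w = 0.5), partial averaging (w = 0.8, the cohort-mean
#' best-fit weight), compressive (a = 0.39, b = 0.85) and expansive
#' (a = -0.70, b = 1.05), the latter two being the cohort-mean combined-task
#' fits.
#'
#' @return Named list of parameter lists `(w, a, b)`.
#' @export
generative_models <- function() {
  list(
    faithful = list(w = 1, a = 0, b = 1),
    compulsory_averaging = list(w = 0.5, a = 0, b = 1),
    partial_averaging = list(w = 0.8, a = 0, b = 1),
    compressive = list(w = 1, a = 0.39, b = 0.85),
    expansive = list(w = 1, a = -0.70, b = 1.05)
  )
}

#' Simulate trial-level ratings for one observer
#'
#' Walks the design's trial list. On cued trials, the target and distractor
#' (or left and right) latent pleasures each receive an independent early
#' noise draw; the draws are combined linearly (target weight `w` on
#' one-pleasure trials, 0.5 on combined trials) with the observer's `(a, b)`
#' transform; one late noise draw is added. Baseline trials report the single
#' image's early-noise sample plus late noise, untransformed, since the
#' baseline block is the measurement that defines the single-pleasure
#' reference. If `discretize`, reports are rounded and clipped to the scale.
#'
#' @param design An `experiment_design`.
#' @param obs An `observer_spec`.
#' @return A data.frame: the design's trial columns preceded by
#'   `participant` and followed by `rating`.
#' @export
simulate_ratings <- function(design, obs) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(obs, "observer_spec"))
  tr <- design$trials
  shown <- unique(stats::na.omit(c(tr$left_image, tr$right_image)))
  missing <- setdiff(shown, names(obs$latent_pleasures))
  if (length(missing) > 0) {
    stop_with("no latent pleasure for image(s): %s",
              paste(missing, collapse = ", "))
  }
  lat <- obs$latent_pleasures

  with_seed(derive_seed(obs$seed, design$participant_index, salt = 3L), {
    n <- nrow(tr)
    is_base <- tr$block_type == "baseline"
    is_comb <- tr$cue == "both"
    # orient P1 = target (cued side) for one-pleasure, left for combined
    p1_img <- ifelse(tr$cue == "right", tr$right_image,
                     ifelse(is_base & is.na(tr$left_image),
                            tr$right_image, tr$left_image))
    p2_img <- ifelse(tr$cue == "right", tr$left_image, tr$right_image)

    e1 <- stats::rnorm(n, 0, obs$early_noise_sd)
    e2 <- stats::rnorm(n, 0, obs$early_noise_sd)
    late <- stats::rnorm(n, 0, obs$late_noise_sd)

    p1 <- lat[p1_img] + e1
    p2 <- ifelse(is.na(p2_img), NA_real_, lat[p2_img] + e2)

    w_trial <- ifelse(is_comb, 0.5, obs$w)
    report <- ifelse(
      is_base,
      p1 + late,
      obs$a + obs$b * (w_trial * p1 + (1 - w_trial) * p2) + late
    )
    if (obs$discretize) report <- discretize_rating(report, obs$response_scale)

    out <- cbind(
      data.frame(participant = design$participant_index),
      tr,
      data.frame(rating = as.numeric(report))
    )
    rownames(out) <- NULL
    out
  })
}

#' Simulate a cohort of observers under a named generative model
#'
#' Builds one design and one observer per participant with sub-seeds derived
#' from the master seed, simulates every trial, and concatenates the
#' long-format results. Participant indices run from 0, so set-to-side
#' counterbalancing alternates across the cohort.
#'
#' @param n_participants Number of observers (>= 1).
#' @param catalog A `stimulus_catalog`.
#' @param model One of `"faithful"`, `"compulsory_averaging"`,
#'   `"partial_averaging"`, `"compressive"`, `"expansive"`.
#' @param early_noise_sd,late_noise_sd Noise SDs; either a scalar (every
#'   participant identical, the default study condition) or a length-2 range
#'   from which each participant's SD is drawn uniformly, giving true
#'   between-participant reliability differences.
#' @param seed Master integer seed; the whole cohort is reproducible from it.
#' @param scheme Latent-pleasure scheme, see [sample_latent_pleasures()];
#'   `"uniform"` draws a fresh latent profile per participant.
#' @param discretize Round/clip reports to the integer scale (default TRUE).
#' @return A long-format data.frame of rated trials for the whole cohort.
#' @export
simulate_cohort <- function(n_participants, catalog, model = "faithful",
                            early_noise_sd = 0, late_noise_sd = 1.4,
                            seed = 1, scheme = "linear_map",
                            discretize = TRUE) {
  if (n_participants < 1) stop_with("n_participants must be >= 1")
  pars <- generative_models()[[model]]
  if (is.null(pars)) {
    stop_with("unknown generative model '%s' (known: %s)", model,
              paste(names(generative_models()), collapse = ", "))
  }
  draw_sd <- function(range, p, salt) {
    if (length(range) == 1) return(range)
    with_seed(derive_seed(seed, p, salt = salt),
              stats::runif(1, range[1], range[2]))
  }
  datasets <- lapply(seq_len(n_participants) - 1L, function(p) {
    design <- build_design(catalog, p, seed)
    obs <- observer_spec(
      latent_pleasures = sample_latent_pleasures(
        catalog, seed = derive_seed(seed, p, salt = 4L), scheme = scheme
      ),
      w = pars$w, a = pars$a, b = pars$b,
      early_noise_sd = draw_sd(early_noise_sd, p, 5L),
      late_noise_sd = draw_sd(late_noise_sd, p, 6L),
      seed = derive_seed(seed, p, salt = 7L),
      discretize = discretize
    )
    simulate_ratings(design, obs)
  })
  out <- do.call(rbind, datasets)
  rownames(out) <- NULL
  out
}
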