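#' Rating standard deviations per participant, condition and pleasure level
#'
#' Cued trials are grouped into cells by participant, trial type, cue timing
#' and target-pleasure level, where the level is the relevant single-pleasure
#' (target's for one-pleasure trials, the pair mean for combined trials)
#' rounded to the nearest integer on the response scale. The sample SD (n-1)
#' is computed within each cell with at least two ratings, and per-participant
#' mean SDs are averaged over populated cells.
#'
#' @param dataset Long-format rated-trial data.frame.
#' @return An `sd_table`: list with `cells` (per-cell SDs) and
#'   `participant_means` (per participant, trial type and timing).
#' @export
rating_sds <- function(dataset) {
  participants <- sort(unique(dataset$participant))
  cells <- list()
  for (p in participants) {
    singles <- single_pleasures(dataset, p)
    tr <- dataset[dataset$participant == p &
                    dataset$block_type %in% c("precued", "postcued"), ]
    is_comb <- tr$cue == "both"
    target <- ifelse(tr$cue == "left", tr$left_image,
                     ifelse(tr$cue == "right", tr$right_image, NA))
    ref <- ifelse(
      is_comb,
      (singles[tr$left_image] + singles[tr$right_image]) / 2,
      singles[target]
    )
    keep <- !is.na(ref) & !is.na(tr$rating)
    tr <- tr[keep, ]
    if (nrow(tr) == 0) next
    level <- discretize_rating(ref[keep])
    g <- data.frame(
      participant = p,
      trial_type = ifelse(tr$cue == "both", "combined", "one_pleasure"),
      cue_timing = tr$block_type,
      level = level,
      rating = tr$rating,
      stringsAsFactors = FALSE
    )
    key <- interaction(g$trial_type, g$cue_timing, g$level, drop = TRUE)
    cl <- do.call(rbind, lapply(split(g, key), function(gg) {
      if (nrow(gg) < 2) return(NULL)
      data.frame(
        participant = p, trial_type = gg$trial_type[1],
        cue_timing = gg$cue_timing[1], level = gg$level[1],
        n = nrow(gg), sd = stats::sd(gg$rating), stringsAsFactors = FALSE
      )
    }))
    cells[[length(cells) + 1]] <- cl
  }
  cells <- do.call(rbind, cells)
  if (is.null(cells) || nrow(cells) == 0) {
    stop_with("no cells with at least two ratings")
  }
  rownames(cells) <- NULL

  key <- interaction(cells$participant, cells$trial_type, cells$cue_timing,
                     drop = TRUE)
  pm <- do.call(rbind, lapply(split(cells, key), function(g) {
    data.frame(
      participant = g$participant[1], trial_type = g$trial_type[1],
      cue_timing = g$cue_timing[1], n_cells = nrow(g),
      mean_sd = mean(g$sd), stringsAsFactors = FALSE
    )
  }))
  rownames(pm) <- NULL
  structure(list(cells = cells, participant_means = pm), class = "sd_table")
}

#' Paired comparison of rating SDs: one-pleasure vs. combined
#'
#' Within each cue timing, a paired two-tailed t-test of per-participant mean
#' rating SDs between one-pleasure and combined trials. If averaging across
#' two independently sampled pleasures drove the reports, combined SDs should
#' be lower by a factor of sqrt(2); equal SDs indicate late
#' (post-combination) response noise.
#'
#' @param table An `sd_table` from [rating_sds()].
#' @return Data.frame per cue timing: condition means, t statistic, df,
#'   two-tailed p, and number of paired participants.
#' @export
compare_sds <- function(table) {
  pm <- table$participant_means
  out <- list()
  for (timing in sort(unique(pm$cue_timing))) {
    one <- pm[pm$cue_timing == timing & pm$trial_type == "one_pleasure", ]
    comb <- pm[pm$cue_timing == timing & pm$trial_type == "combined", ]
    shared <- intersect(one$participant, comb$participant)
    if (length(shared) < 3) {
      stop_with("paired SD comparison needs >= 3 participants with both %s",
                "conditions")
    }
    x <- one$mean_sd[match(shared, one$participant)]
    y <- comb$mean_sd[match(shared, comb$participant)]
    d <- x - y
    if (all(d == 0)) {
      t_stat <- 0; p_val <- 1; df <- length(d) - 1
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
      t_stat <- unname(tt$statistic); p_val <- tt$p.value
      df <- unname(tt$parameter)
    }
    out[[timing]] <- data.frame(
      cue_timing = timing, n = length(shared),
      mean_sd_one_pleasure = mean(x), mean_sd_combined = mean(y),
      t = t_stat, df = df, p = p_val, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predicted SD ratio of one-pleasure to combined reports
#'
#' Simulates undiscretized reports for a fixed latent pleasure: one-pleasure
#' reports receive one early draw plus one late draw; combined reports
#' average two independent early draws and add one late draw. Returns the
#' Monte-Carlo ratio `SD(one) / SD(combined)`; the closed form
#' `sqrt((se^2 + sl^2) / (se^2 / 2 + sl^2))` is attached as an attribute.
#' With early noise only the ratio is `sqrt(2)`; with late noise only it is 1.
#'
#' @param early_sd,late_sd Noise SDs (at least one positive).
#' @param n_trials Number of simulated reports per condition (>= 2).
#' @param seed Integer seed.
#' @return Numeric ratio with attributes `closed_form` and `n_trials`.
#' @export
variance_reduction_ratio <- function(early_sd, late_sd, n_trials = 1e5,
                                     seed = 1) {
  if (n_trials < 2) stop_with("n_trials must be >= 2")
  if (early_sd <= 0 && late_sd <= 0) {
    stop_with("at least one noise SD must be positive")
  }
  ratio <- with_seed(derive_seed(seed, salt = 8L), {
    one <- stats::rnorm(n_trials, 0, early_sd) +
      stats::rnorm(n_trials, 0, late_sd)
    comb <- (stats::rnorm(n_trials, 0, early_sd) +
               stats::rnorm(n_trials, 0, early_sd)) / 2 +
      stats::rnorm(n_trials, 0, late_sd)
    stats::sd(one) / stats::sd(comb)
  })
  attr(ratio, "closed_form") <-
    sqrt((early_sd^2 + late_sd^2) / (early_sd^2 / 2 + late_sd^2))
  attr(ratio, "n_trials") <- n_trials
  ratio
}
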