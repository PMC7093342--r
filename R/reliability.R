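#' Participants-by-images matrix of baseline ratings
#'
#' @param dataset Long-format rated-trial data.frame.
#' @return Numeric matrix, rows = participants, columns = main images (sorted
#'   by image id); cells are baseline (single-pleasure) ratings.
#' @export
baseline_ratings <- function(dataset) {
  participants <- sort(unique(dataset$participant))
  base <- dataset[dataset$block_type == "baseline", ]
  imgs <- sort(unique(ifelse(is.na(base$left_image),
                             base$right_image, base$left_image)))
  m <- t(vapply(participants, function(p) {
    s <- single_pleasures(dataset, p)
    unname(s[imgs])
  }, numeric(length(imgs))))
  dimnames(m) <- list(as.character(participants), imgs)
  m
}

#' Absolute-error matrix for one condition
#'
#' For every participant and main image, the mean absolute deviation of that
#' participant's ratings from the single-pleasure reference, within one
#' trial-type-by-cue-timing condition. One-pleasure trials contribute
#' `|rating - target single-pleasure|` to the target image's cell; combined
#' trials contribute `|rating - mean(two single-pleasures)|` to both images'
#' cells. Participants with a missing single-pleasure for any main image are
#' dropped with a warning (complete-case policy).
#'
#' @param dataset Long-format rated-trial data.frame.
#' @param trial_type `"one_pleasure"` or `"combined"`.
#' @param cue_timing `"precued"` or `"postcued"`.
#' @return Numeric matrix (participants x images) with condition attributes.
#' @export
error_matrix <- function(dataset,
                         trial_type = c("one_pleasure", "combined"),
                         cue_timing = c("precued", "postcued")) {
  trial_type <- match.arg(trial_type)
  cue_timing <- match.arg(cue_timing)
  participants <- sort(unique(dataset$participant))
  base <- baseline_ratings(dataset)
  imgs <- colnames(base)

  rows <- list()
  dropped <- character()
  for (p in participants) {
    singles <- base[as.character(p), ]
    if (anyNA(singles)) {
      dropped <- c(dropped, as.character(p))
      next
    }
    tr <- dataset[dataset$participant == p &
                    dataset$block_type == cue_timing, ]
    if (trial_type == "one_pleasure") {
      tr <- tr[tr$cue %in% c("left", "right"), ]
      target <- ifelse(tr$cue == "left", tr$left_image, tr$right_image)
      err <- abs(tr$rating - singles[target])
      cell <- tapply(err, factor(target, levels = imgs), mean)
    } else {
      tr <- tr[tr$cue == "both", ]
      ref <- (singles[tr$left_image] + singles[tr$right_image]) / 2
      err <- abs(tr$rating - ref)
      # the same trial error is attributed to both presented images
      cell <- tapply(c(err, err),
                     factor(c(tr$left_image, tr$right_image), levels = imgs),
                     mean)
    }
    if (anyNA(cell)) {          # some image never rated in this condition
      dropped <- c(dropped, as.character(p))
      next
    }
    rows[[as.character(p)]] <- as.numeric(cell)
  }
  if (length(dropped) > 0) {
    warning(sprintf(
      "dropped participant(s) with missing single-pleasures or empty cells: %s",
      paste(dropped, collapse = ", ")
    ), call. = FALSE)
  }
  if (length(rows) == 0) stop_with("no participants with complete baselines")
  m <- do.call(rbind, rows)
  colnames(m) <- imgs
  attr(m, "trial_type") <- trial_type
  attr(m, "cue_timing") <- cue_timing
  m
}

#' Cronbach's alpha of an items-by-cases matrix
#'
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of case totals)`,
#' with items in columns (here: images), cases in rows (participants) and
#' sample variances (n-1 denominator).
#'
#' @param m Numeric matrix, rows = cases, columns = items; no missing cells.
#' @return Alpha (numeric scalar).
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop_with("alpha needs >= 2 rows and columns")
  if (anyNA(m)) stop_with("alpha is undefined with missing cells")
  k <- ncol(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop_with("alpha undefined: zero total-score variance")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Absolute-agreement intraclass correlation (two-way, single measure)
#'
#' ICC(A,1): a two-way random-effects model in which the rated targets
#' (images) and the raters (participants) are both random, quantifying
#' absolute agreement of raw scores, not just rank consistency. Computed
#' from the mean squares of the two-way ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`, with `n` targets and
#' `k` raters.
#'
#' @param m Numeric matrix, rows = raters (participants), columns = targets
#'   (images); e.g. [baseline_ratings()].
#' @return ICC (numeric scalar in `[-1, 1]`).
#' @export
icc_absolute_agreement <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop_with("ICC needs >= 2 raters and targets")
  if (anyNA(m)) stop_with("ICC is undefined with missing cells")
  x <- t(m)                      # rows = targets, cols = raters
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  if (all(x == grand)) stop_with("ICC undefined for a constant matrix")
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((x - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Attenuation ceiling on an observable correlation
#'
#' The maximum correlation attainable between two measures given their
#' internal consistencies: `sqrt(alpha_x * alpha_y)`. Although the classical
#' inequality is printed with the reliabilities bounding the disattenuated
#' correlation from below, in practice the quantity is used as the ceiling on
#' the observable correlation between the two error profiles, and that is the
#' interpretation implemented here.
#'
#' @param alpha_x,alpha_y Cronbach's alphas, each in `(0, 1]`.
#' @return The ceiling (numeric scalar).
#' @export
attenuation_ceiling <- function(alpha_x, alpha_y) {
  if (any(c(alpha_x, alpha_y) <= 0) || any(c(alpha_x, alpha_y) > 1)) {
    stop_with("alphas must lie in (0, 1]")
  }
  sqrt(alpha_x * alpha_y)
}

#' Cross-condition error correlations with their reliability ceilings
#'
#' Builds the absolute-error matrix for each of the four conditions
#' (one-pleasure/combined x precued/postcued), reduces each to an error
#' profile (default: per-participant mean absolute error; `unit = "item"`
#' uses per-image means), and reports every pairwise Pearson correlation
#' alongside the two conditions' alphas, the attenuation ceiling
#' `sqrt(alpha_x alpha_y)`, and the observed/ceiling ratio.
#'
#' @param dataset Long-format rated-trial data.frame (>= 3 participants).
#' @param unit `"participant"` (default) or `"item"` profiles.
#' @return List with `alphas` (per condition) and `correlations`
#'   (data.frame: condition pair, r, alphas, ceiling, ratio).
#' @export
error_correlations <- function(dataset, unit = c("participant", "item")) {
  unit <- match.arg(unit)
  if (length(unique(dataset$participant)) < 3) {
    stop_with("error correlations need >= 3 participants")
  }
  conds <- expand.grid(
    trial_type = c("one_pleasure", "combined"),
    cue_timing = c("precued", "postcued"),
    stringsAsFactors = FALSE
  )
  conds$label <- paste(conds$trial_type, conds$cue_timing, sep = "_")

  mats <- lapply(seq_len(nrow(conds)), function(i) {
    error_matrix(dataset, conds$trial_type[i], conds$cue_timing[i])
  })
  names(mats) <- conds$label

  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) < 3) stop_with("fewer than 3 complete participants")
  profiles <- lapply(mats, function(m) {
    if (unit == "participant") rowMeans(m[shared, , drop = FALSE])
    else colMeans(m[shared, , drop = FALSE])
  })
  alphas <- vapply(mats, function(m) cronbach_alpha(m[shared, , drop = FALSE]),
                   numeric(1))

  pairs <- utils::combn(conds$label, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    x <- profiles[[pairs[1, j]]]
    y <- profiles[[pairs[2, j]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      stop_with("zero-variance error profile in condition %s or %s",
                pairs[1, j], pairs[2, j])
    }
    r <- stats::cor(x, y)
    ax <- alphas[[pairs[1, j]]]
    ay <- alphas[[pairs[2, j]]]
    ceiling <- if (ax > 0 && ay > 0) sqrt(ax * ay) else NA_real_
    data.frame(
      condition_x = pairs[1, j], condition_y = pairs[2, j],
      r = r, alpha_x = ax, alpha_y = ay, ceiling = ceiling,
      ratio = r / ceiling, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  list(alphas = alphas, correlations = out, unit = unit)
}
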