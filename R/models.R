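#' Predicted rating under the linear weighted-combination rule
#'
#' Computes `a + b * (w * P1 + (1 - w) * P2)` exactly, with no rounding or
#' clipping: model predictions are continuous and are compared with the
#' integer ratings through the RMSE cost.
#'
#' @param a,b,w Model parameters.
#' @param P1,P2 First and second single-pleasure (target/distractor for
#'   one-pleasure trials, left/right for combined trials).
#' @return Numeric vector of predicted ratings.
#' @export
predict_rating <- function(a, b, w, P1, P2) {
  a + b * (w * P1 + (1 - w) * P2)
}

#' Specify a member of the rating-model family
#'
#' The family partitions by trial type. One-pleasure models fix `a = 0`,
#' `b = 1` and differ in the target weight: faithful (`w = 1`), compulsory
#' averaging (`w = 0.5`), partial averaging (`w` free in `[0.5, 1]`; alias
#' `"flexible"`). Combined-pleasure models fix `w = 0.5` and differ in the
#' linear transform: faithful (`a = 0`, `b = 1`), compressive (`a > 0`,
#' `0 < b < 1`), expansive (`a < 0`, `b > 1`), flexible (`a`, `b` free).
#' Strict inequalities are realized as closed boxes with a small margin
#' `eps`, since optimization needs closed feasible sets.
#'
#' @param name Model name.
#' @param trial_type `"one_pleasure"` or `"combined"`.
#' @param eps Margin replacing strict inequalities (default `1e-6`).
#' @param a_limit,b_limit Outer box limits for the intercept and slope.
#' @return A `model_spec` object with fields `fixed`, `free`, `lower`,
#'   `upper` and `n_free`.
#' @export
model_spec <- function(name = c("faithful", "compulsory_averaging",
                                "partial_averaging", "compressive",
                                "expansive", "flexible"),
                       trial_type = c("one_pleasure", "combined"),
                       eps = 1e-6, a_limit = 8, b_limit = 4) {
  name <- match.arg(name)
  trial_type <- match.arg(trial_type)
  if (trial_type == "one_pleasure") {
    if (name == "flexible") name <- "partial_averaging"
    if (name %in% c("compressive", "expansive")) {
      stop_with("'%s' is a combined-pleasure model", name)
    }
    fixed <- list(a = 0, b = 1)
    spec <- switch(name,
      faithful = list(fixed = c(fixed, w = 1), free = character()),
      compulsory_averaging = list(fixed = c(fixed, w = 0.5),
                                  free = character()),
      partial_averaging = list(fixed = fixed, free = "w",
                               lower = c(w = 0.5), upper = c(w = 1))
    )
  } else {
    if (name %in% c("compulsory_averaging", "partial_averaging")) {
      stop_with("'%s' is a one-pleasure model", name)
    }
    fixed <- list(w = 0.5)
    spec <- switch(name,
      faithful = list(fixed = c(fixed, a = 0, b = 1), free = character()),
      compressive = list(fixed = fixed, free = c("a", "b"),
                         lower = c(a = eps, b = eps),
                         upper = c(a = a_limit, b = 1 - eps)),
      expansive = list(fixed = fixed, free = c("a", "b"),
                       lower = c(a = -a_limit, b = 1 + eps),
                       upper = c(a = -eps, b = b_limit)),
      flexible = list(fixed = fixed, free = c("a", "b"),
                      lower = c(a = -a_limit, b = eps),
                      upper = c(a = a_limit, b = b_limit))
    )
  }
  structure(
    c(list(name = name, trial_type = trial_type), spec,
      list(n_free = length(spec$free))),
    class = "model_spec"
  )
}

#' Paper-family model specifications for one trial type
#'
#' @param trial_type `"one_pleasure"` (faithful, compulsory averaging,
#'   partial averaging) or `"combined"` (faithful, compressive, expansive).
#' @return List of `model_spec` objects.
#' @export
default_model_specs <- function(trial_type = c("one_pleasure", "combined")) {
  trial_type <- match.arg(trial_type)
  names <- if (trial_type == "one_pleasure") {
    c("faithful", "compulsory_averaging", "partial_averaging")
  } else {
    c("faithful", "compressive", "expansive")
  }
  lapply(names, model_spec, trial_type = trial_type)
}

#' Extract a participant's single-pleasure ratings
#'
#' The single-pleasure of an image is that participant's own rating of it in
#' the final baseline block; group norms are never substituted.
#'
#' @param dataset Long-format rated-trial data.frame.
#' @param participant Participant index.
#' @return Named numeric vector (image -> single-pleasure); images without a
#'   usable baseline rating are `NA`.
#' @export
single_pleasures <- function(dataset, participant) {
  base <- dataset[dataset$participant == participant &
                    dataset$block_type == "baseline", ]
  img <- ifelse(is.na(base$left_image), base$right_image, base$left_image)
  stats::setNames(base$rating, img)
}

#' Assemble per-trial model observations for one participant and condition
#'
#' For one-pleasure trials `P1` is the target's single-pleasure and `P2` the
#' distractor's; for combined trials `P1`/`P2` are the left/right images'
#' single-pleasures. Trials whose single-pleasure is missing (no baseline
#' rating) are dropped and counted in the `n_dropped` attribute.
#'
#' @param dataset Long-format rated-trial data.frame.
#' @param participant Participant index.
#' @param trial_type `"one_pleasure"` or `"combined"`.
#' @param cue_timing `"precued"` or `"postcued"`.
#' @return A `trial_obs` data.frame with columns `P1`, `P2`, `rating`.
#' @export
trial_observations <- function(dataset, participant,
                               trial_type = c("one_pleasure", "combined"),
                               cue_timing = c("precued", "postcued")) {
  trial_type <- match.arg(trial_type)
  cue_timing <- match.arg(cue_timing)
  singles <- single_pleasures(dataset, participant)
  rows <- dataset[dataset$participant == participant &
                    dataset$block_type == cue_timing, ]
  rows <- if (trial_type == "one_pleasure") {
    rows[rows$cue %in% c("left", "right"), ]
  } else {
    rows[rows$cue == "both", ]
  }
  if (trial_type == "one_pleasure") {
    p1_img <- ifelse(rows$cue == "left", rows$left_image, rows$right_image)
    p2_img <- ifelse(rows$cue == "left", rows$right_image, rows$left_image)
  } else {
    p1_img <- rows$left_image
    p2_img <- rows$right_image
  }
  obs <- data.frame(
    P1 = unname(singles[p1_img]),
    P2 = unname(singles[p2_img]),
    rating = rows$rating
  )
  keep <- !is.na(obs$P1) & !is.na(obs$P2) & !is.na(obs$rating)
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "participant") <- participant
  attr(out, "trial_type") <- trial_type
  attr(out, "cue_timing") <- cue_timing
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("trial_obs", "data.frame")
  out
}

# ---- exact constrained least squares ---------------------------------------
# Every model is linear in its free parameters, so the RMSE minimum is the
# solution of a box-constrained ordinary least-squares problem: the
# unconstrained optimum if it is feasible, otherwise the best point on one of
# the box edges (exact for a convex quadratic). All solvers below work on
# sufficient statistics so leave-one-out refits reduce to rank-one downdates.

# free w, a and b fixed: minimize sum((z - w*d)^2), z = (y-a)/b - P2, d = P1-P2
solve_w_box <- function(Szd, Sdd, lo, hi) {
  w <- ifelse(Sdd > 0, Szd / Sdd, (lo + hi) / 2)
  pmin(hi, pmax(lo, w))
}

# free (a, b): minimize sum((y - a - b*m)^2) over a box; vectorized over folds
solve_ab_box <- function(n, Sm, Smm, Sy, Syy, Smy, lower, upper) {
  nf <- max(length(n), length(Sy))        # number of folds
  n <- rep_len(n, nf)
  Sm <- rep_len(Sm, nf)
  Smm <- rep_len(Smm, nf)
  Sy <- rep_len(Sy, nf)
  Syy <- rep_len(Syy, nf)
  Smy <- rep_len(Smy, nf)
  sse_ab <- function(a, b) {
    Syy - 2 * a * Sy - 2 * b * Smy + a^2 * n + 2 * a * b * Sm + b^2 * Smm
  }
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  det <- n * Smm - Sm^2
  ok <- det > 1e-12 * pmax(1, n * Smm)
  b0 <- ifelse(ok, (n * Smy - Sm * Sy) / det, NA_real_)
  a0 <- ifelse(ok, (Sy - b0 * Sm) / n, NA_real_)
  interior <- ok & !is.na(a0) &
    a0 >= lower[["a"]] & a0 <= upper[["a"]] &
    b0 >= lower[["b"]] & b0 <= upper[["b"]]

  cand_a <- list()
  cand_b <- list()
  # edges with b fixed at a bound
  for (b_edge in c(lower[["b"]], upper[["b"]])) {
    cand_a[[length(cand_a) + 1]] <-
      clamp((Sy - b_edge * Sm) / n, lower[["a"]], upper[["a"]])
    cand_b[[length(cand_b) + 1]] <- rep_len(b_edge, nf)
  }
  # edges with a fixed at a bound
  for (a_edge in c(lower[["a"]], upper[["a"]])) {
    b_hat <- ifelse(Smm > 0, (Smy - a_edge * Sm) / Smm,
                    (lower[["b"]] + upper[["b"]]) / 2)
    cand_a[[length(cand_a) + 1]] <- rep_len(a_edge, nf)
    cand_b[[length(cand_b) + 1]] <- clamp(b_hat, lower[["b"]], upper[["b"]])
  }
  cand_a[[length(cand_a) + 1]] <- ifelse(interior, a0, NA_real_)
  cand_b[[length(cand_b) + 1]] <- ifelse(interior, b0, NA_real_)

  sse <- mapply(function(a, b) {
    out <- sse_ab(a, b)
    out[is.na(a)] <- Inf
    out
  }, cand_a, cand_b)
  if (is.null(dim(sse))) sse <- matrix(sse, nrow = nf)
  pick <- max.col(-sse, ties.method = "first")
  idx <- cbind(seq_len(nf), pick)
  a_mat <- do.call(cbind, cand_a)
  b_mat <- do.call(cbind, cand_b)
  list(a = a_mat[idx], b = b_mat[idx])
}

fit_params_analytic <- function(y, P1, P2, spec) {
  pars <- c(a = NA_real_, b = NA_real_, w = NA_real_)
  pars[names(spec$fixed)] <- unlist(spec$fixed)
  if (spec$n_free == 0) return(pars)
  if (identical(spec$free, "w")) {
    d <- P1 - P2
    z <- (y - pars[["a"]]) / pars[["b"]] - P2
    pars[["w"]] <- solve_w_box(sum(z * d), sum(d * d),
                               spec$lower[["w"]], spec$upper[["w"]])
    return(pars)
  }
  if (identical(sort(spec$free), c("a", "b"))) {
    m <- pars[["w"]] * P1 + (1 - pars[["w"]]) * P2
    sol <- solve_ab_box(length(y), sum(m), sum(m^2), sum(y), sum(y^2),
                        sum(m * y), spec$lower, spec$upper)
    pars[["a"]] <- sol$a
    pars[["b"]] <- sol$b
    return(pars)
  }
  stop_with("unsupported free-parameter set: %s",
            paste(spec$free, collapse = ","))
}

fit_params_optim <- function(y, P1, P2, spec, n_starts = 5) {
  pars <- c(a = NA_real_, b = NA_real_, w = NA_real_)
  pars[names(spec$fixed)] <- unlist(spec$fixed)
  if (spec$n_free == 0) return(pars)
  lo <- spec$lower[spec$free]
  hi <- spec$upper[spec$free]
  cost <- function(theta) {
    p <- pars
    p[spec$free] <- theta
    sqrt(mean((y - predict_rating(p[["a"]], p[["b"]], p[["w"]], P1, P2))^2))
  }
  ts <- (seq_len(n_starts) - 0.5) / n_starts
  best <- NULL
  for (t in ts) {
    start <- lo + t * (hi - lo)
    res <- stats::optim(start, cost, method = "L-BFGS-B",
                        lower = lo, upper = hi,
                        control = list(factr = 1e1))
    if (is.null(best) || res$value < best$value - 1e-12) best <- res
  }
  pars[spec$free] <- best$par
  pars
}

#' Fit a rating model to one participant's trials
#'
#' Minimizes the RMSE between model predictions and observed ratings over the
#' model's free parameters within their bounds. Since the cost is least
#' squares and every model is linear in its free parameters, the default
#' `"analytic"` method computes the exact box-constrained solution in closed
#' form; `"optim"` runs bounded L-BFGS-B from `n_starts` deterministic starts
#' and exists mainly as an independent cross-check.
#'
#' @param obs A `trial_obs` (or any data.frame with columns `P1`, `P2`,
#'   `rating`).
#' @param spec A `model_spec`.
#' @param method `"analytic"` or `"optim"`.
#' @param n_starts Number of deterministic starts for `"optim"`.
#' @return A `fit_result`: list with `params` (full `(a, b, w)`), `n_free`,
#'   `n_trials` and `rmse_train`.
#' @export
fit_model <- function(obs, spec, method = c("analytic", "optim"),
                      n_starts = 5) {
  method <- match.arg(method)
  y <- obs$rating
  P1 <- obs$P1
  P2 <- obs$P2
  if (anyNA(y) || anyNA(P1) || anyNA(P2)) {
    stop_with(paste0(
      "missing single-pleasure or rating values; ",
      "participant flagged for exclusion"
    ))
  }
  if (length(y) < max(3, spec$n_free + 1)) {
    stop_with("need at least %d trials to fit '%s', got %d",
              max(3, spec$n_free + 1), spec$name, length(y))
  }
  pars <- if (method == "analytic") {
    fit_params_analytic(y, P1, P2, spec)
  } else {
    fit_params_optim(y, P1, P2, spec, n_starts)
  }
  pred <- predict_rating(pars[["a"]], pars[["b"]], pars[["w"]], P1, P2)
  structure(
    list(model = spec$name, trial_type = spec$trial_type, params = pars,
         n_free = spec$n_free, n_trials = length(y),
         rmse_train = sqrt(mean((y - pred)^2))),
    class = "fit_result"
  )
}

#' Leave-one-out cross-validation of a rating model
#'
#' For every trial `i` the model is refit on all other trials and the squared
#' prediction error on trial `i` is recorded; the LOOCV RMSE is the square
#' root of the mean held-out squared error. Models without free parameters
#' need no refitting, so their LOOCV RMSE equals the training RMSE exactly.
#' The analytic path performs each leave-one-out refit by a rank-one downdate
#' of the least-squares sufficient statistics, so the full LOOCV is exact and
#' runs in linear time; `method = "optim"` refits numerically per fold.
#'
#' @inheritParams fit_model
#' @return A `fit_result` that also carries `cv_sq_errors` (per-left-out-trial
#'   squared errors) and `rmse_loocv`.
#' @export
loocv <- function(obs, spec, method = c("analytic", "optim"), n_starts = 5) {
  method <- match.arg(method)
  fit <- fit_model(obs, spec, method = method, n_starts = n_starts)
  y <- obs$rating
  P1 <- obs$P1
  P2 <- obs$P2
  n <- length(y)
  if (n < spec$n_free + 2) {
    stop_with("need at least %d trials for LOOCV of '%s', got %d",
              spec$n_free + 2, spec$name, n)
  }

  if (spec$n_free == 0) {
    p <- fit$params
    pred <- predict_rating(p[["a"]], p[["b"]], p[["w"]], P1, P2)
    sq <- (y - pred)^2
  } else if (method == "optim") {
    sq <- vapply(seq_len(n), function(i) {
      f <- fit_model(obs[-i, , drop = FALSE], spec, method = "optim",
                     n_starts = n_starts)
      p <- f$params
      (y[i] - predict_rating(p[["a"]], p[["b"]], p[["w"]], P1[i], P2[i]))^2
    }, numeric(1))
  } else if (identical(spec$free, "w")) {
    a <- fit$params[["a"]]
    b <- fit$params[["b"]]
    d <- P1 - P2
    z <- (y - a) / b - P2
    Szd <- sum(z * d) - z * d
    Sdd <- sum(d * d) - d * d
    w_i <- solve_w_box(Szd, Sdd, spec$lower[["w"]], spec$upper[["w"]])
    pred <- predict_rating(a, b, w_i, P1, P2)
    sq <- (y - pred)^2
  } else {
    w <- fit$params[["w"]]
    m <- w * P1 + (1 - w) * P2
    sol <- solve_ab_box(
      n - 1,
      sum(m) - m, sum(m^2) - m^2, sum(y) - y, sum(y^2) - y^2,
      sum(m * y) - m * y,
      spec$lower, spec$upper
    )
    pred <- sol$a + sol$b * m
    sq <- (y - pred)^2
  }

  fit$cv_sq_errors <- sq
  fit$rmse_loocv <- sqrt(mean(sq))
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s (%s), %d free, n = %d\n",
              x$model, x$trial_type, x$n_free, x$n_trials))
  cat(sprintf("  a = %.4f, b = %.4f, w = %.4f; train RMSE = %.4f%s\n",
              x$params[["a"]], x$params[["b"]], x$params[["w"]],
              x$rmse_train,
              if (!is.null(x$rmse_loocv)) {
                sprintf(", LOOCV RMSE = %.4f", x$rmse_loocv)
              } else ""))
  invisible(x)
}

#' Compare rating models across a cohort by LOOCV
#'
#' Runs per-participant LOOCV for every model specification, separately for
#' precued and postcued trials and separately per trial-type family, then
#' summarizes mean LOOCV RMSE across participants with its standard error
#' (SD over participant means divided by the square root of the number of
#' participants). The winner of each condition is the model with the lowest
#' mean LOOCV RMSE; exact ties go to the model with fewer free parameters.
#' Participants whose trials cannot be fit (e.g. too few usable
#' single-pleasures) are excluded from that condition with a warning.
#'
#' @param dataset Long-format rated-trial data.frame.
#' @param specs List of `model_spec`s; defaults to both trial-type families'
#'   paper trios.
#' @param cue_timings Cue timings to analyze.
#' @param method Fitting method, see [fit_model()].
#' @return A `model_comparison`: list with `per_participant` (long
#'   data.frame of LOOCV RMSEs), `summary` (mean, SEM, n per condition and
#'   model) and `winners`.
#' @export
compare_models <- function(dataset, specs = NULL,
                           cue_timings = c("precued", "postcued"),
                           method = "analytic") {
  if (is.null(specs)) {
    specs <- c(default_model_specs("one_pleasure"),
               default_model_specs("combined"))
  }
  participants <- sort(unique(dataset$participant))
  if (length(participants) < 2) {
    stop_with("model comparison: insufficient participants (need >= 2, got %d)",
              length(participants))
  }

  rows <- list()
  for (spec in specs) {
    for (timing in cue_timings) {
      for (p in participants) {
        obs <- trial_observations(dataset, p, spec$trial_type, timing)
        res <- tryCatch(loocv(obs, spec, method = method),
                        error = function(e) e)
        if (inherits(res, "error")) {
          warning(sprintf(
            "participant %s excluded from %s/%s/%s: %s",
            p, spec$trial_type, timing, spec$name, conditionMessage(res)
          ), call. = FALSE)
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, trial_type = spec$trial_type,
          cue_timing = timing, model = spec$name, n_free = spec$n_free,
          n_trials = res$n_trials, n_dropped = attr(obs, "n_dropped"),
          a = res$params[["a"]], b = res$params[["b"]],
          w = res$params[["w"]],
          rmse_train = res$rmse_train, rmse_loocv = res$rmse_loocv,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    stop_with("model comparison: all participants excluded")
  }
  per <- do.call(rbind, rows)

  key <- interaction(per$trial_type, per$cue_timing, per$model, drop = TRUE)
  agg <- do.call(rbind, lapply(split(per, key), function(g) {
    data.frame(
      trial_type = g$trial_type[1], cue_timing = g$cue_timing[1],
      model = g$model[1], n_free = g$n_free[1],
      n_participants = nrow(g),
      mean_rmse_loocv = mean(g$rmse_loocv),
      sem_rmse_loocv = stats::sd(g$rmse_loocv) / sqrt(nrow(g)),
      mean_rmse_train = mean(g$rmse_train),
      stringsAsFactors = FALSE
    )
  }))
  rownames(agg) <- NULL
  if (max(agg$n_participants) < 2) {
    stop_with("model comparison: fewer than 2 participants survived exclusion")
  }

  cond <- interaction(agg$trial_type, agg$cue_timing, drop = TRUE)
  winners <- do.call(rbind, lapply(split(agg, cond), function(g) {
    g <- g[order(g$mean_rmse_loocv, g$n_free, g$model), ]
    g[1, c("trial_type", "cue_timing", "model", "mean_rmse_loocv")]
  }))
  rownames(winners) <- NULL

  structure(list(per_participant = per, summary = agg, winners = winners),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  s <- x$summary
  s$mean_rmse_loocv <- round(s$mean_rmse_loocv, 3)
  s$sem_rmse_loocv <- round(s$sem_rmse_loocv, 4)
  print(s[order(s$trial_type, s$cue_timing, s$mean_rmse_loocv),
          c("trial_type", "cue_timing", "model", "n_free",
            "mean_rmse_loocv", "sem_rmse_loocv")],
        row.names = FALSE)
  cat("winners:\n")
  print(x$winners, row.names = FALSE)
  invisible(x)
}
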