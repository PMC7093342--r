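#' Synthetic image-norm rating table
#'
#' Generates a table of per-image beauty norms on the 1-7 scale, emulating the
#' kind of normative rating database (one mean beauty rating per image) from
#' which experimental stimuli are selected. Beauty values are drawn from a
#' scaled Beta(2, 2), a unimodal distribution that covers the whole scale with
#' thinner tails at the extremes, as norm sets typically do.
#'
#' @param n_images Number of images (default 900).
#' @param seed Integer seed; the table is deterministic given the seed.
#' @param beauty_scale Length-2 numeric bounds of the norm scale.
#' @return A data.frame with columns `image_id` and `beauty`.
#' @export
synthetic_rating_table <- function(n_images = 900, seed = 1,
                                   beauty_scale = c(1, 7)) {
  stopifnot(n_images >= 1)
  with_seed(derive_seed(seed, salt = 11L), {
    beauty <- beauty_scale[1] +
      diff(beauty_scale) * stats::rbeta(n_images, 2, 2)
    data.frame(
      image_id = sprintf("img%04d", seq_len(n_images)),
      beauty = beauty,
      stringsAsFactors = FALSE
    )
  })
}

validate_rating_table <- function(ratings, beauty_scale) {
  if (!is.data.frame(ratings) ||
      !all(c("image_id", "beauty") %in% names(ratings))) {
    stop_with("ratings must be a data.frame with columns image_id, beauty")
  }
  if (anyDuplicated(ratings$image_id)) {
    stop_with("duplicate image_id in rating table: %s",
              paste(unique(ratings$image_id[duplicated(ratings$image_id)]),
                    collapse = ", "))
  }
  if (!all(is.finite(ratings$beauty))) {
    stop_with("non-finite beauty values in rating table")
  }
  if (any(ratings$beauty < beauty_scale[1] | ratings$beauty > beauty_scale[2])) {
    stop_with("beauty values outside the declared scale [%g, %g]",
              beauty_scale[1], beauty_scale[2])
  }
  invisible(TRUE)
}

#' Select experimental stimuli from a rating table
#'
#' Reproduces the quintile-based stimulus selection: images are ranked by
#' beauty and split into five equal-count quintiles (quintile 1 = most
#' beautiful). The `n_per_quintile` most beautiful images are taken from the
#' top quintile, the `n_per_quintile` least beautiful from the bottom
#' quintile, and the images nearest each quintile's median beauty from the
#' three middle quintiles. The middle quintile additionally supplies the
#' training images: its `n_per_quintile` nearest-median images are split into
#' `n_per_quintile - n_training` main images (nearest) and `n_training`
#' training images (next nearest), so that with the defaults the catalog
#' holds exactly 36 main and 4 training images. Main images are assigned
#' alternately to sets A and B by beauty rank, so both sets span the beauty
#' range.
#'
#' @param ratings Data.frame with columns `image_id`, `beauty`.
#' @param n_per_quintile Images selected per quintile (default 8).
#' @param n_training Training images, drawn from the middle quintile
#'   (default 4; must not exceed `n_per_quintile`).
#' @param beauty_scale Bounds of the beauty norm scale (default 1-7).
#' @return A `stimulus_catalog`: data.frame with columns `image_id`,
#'   `beauty`, `role` ("main"/"training") and `set_label` ("A"/"B" for main
#'   images, `NA` for training images), ordered by descending beauty within
#'   role.
#' @export
select_stimuli <- function(ratings, n_per_quintile = 8, n_training = 4,
                           beauty_scale = c(1, 7)) {
  validate_rating_table(ratings, beauty_scale)
  n <- nrow(ratings)
  if (n < 5 * n_per_quintile) {
    stop_with("stimulus selection needs at least %d rows, got %d",
              5 * n_per_quintile, n)
  }
  if (n_training > n_per_quintile) {
    stop_with("n_training (%d) must not exceed n_per_quintile (%d)",
              n_training, n_per_quintile)
  }
  if (length(unique(ratings$beauty)) == 1) {
    stop_with("beauty values are all identical; selection is undefined")
  }

  # rank 1 = most beautiful; ties broken by image_id so selection is
  # independent of input row order
  ord <- order(-ratings$beauty, ratings$image_id)
  tab <- ratings[ord, c("image_id", "beauty")]
  rownames(tab) <- NULL

  q_sizes <- rep(n %/% 5, 5)
  if (n %% 5 > 0) q_sizes[seq_len(n %% 5)] <- q_sizes[seq_len(n %% 5)] + 1
  quintile <- rep(1:5, times = q_sizes)

  nearest_median <- function(idx, k) {
    med <- stats::median(tab$beauty[idx])
    idx[order(abs(tab$beauty[idx] - med), tab$image_id[idx])][seq_len(k)]
  }

  idx_q <- split(seq_len(n), quintile)
  sel_main <- c(
    idx_q[[1]][seq_len(n_per_quintile)],                     # most beautiful
    nearest_median(idx_q[[2]], n_per_quintile),
    nearest_median(idx_q[[4]], n_per_quintile),
    rev(idx_q[[5]])[seq_len(n_per_quintile)]                 # least beautiful
  )
  mid <- nearest_median(idx_q[[3]], n_per_quintile)
  sel_main <- c(sel_main, mid[seq_len(n_per_quintile - n_training)])
  sel_training <- mid[n_per_quintile - n_training + seq_len(n_training)]

  main <- tab[sort(sel_main), ]                # sorted = beauty rank order
  training <- tab[sort(sel_training), ]
  main$role <- "main"
  training$role <- "training"
  # alternate sets by beauty rank so both sets cover the range
  main$set_label <- rep_len(c("A", "B"), nrow(main))
  training$set_label <- NA_character_

  catalog <- rbind(main, training)
  rownames(catalog) <- NULL
  attr(catalog, "beauty_scale") <- beauty_scale
  class(catalog) <- c("stimulus_catalog", "data.frame")
  catalog
}

catalog_main <- function(catalog) catalog[catalog$role == "main", , drop = FALSE]

check_catalog <- function(catalog) {
  if (!all(c("image_id", "beauty", "role", "set_label") %in% names(catalog))) {
    stop_with("not a stimulus catalog (missing columns)")
  }
  main <- catalog_main(catalog)
  n_a <- sum(main$set_label == "A")
  n_b <- sum(main$set_label == "B")
  if (n_a != n_b) {
    stop_with("catalog has unequal set sizes (A: %d, B: %d)", n_a, n_b)
  }
  invisible(TRUE)
}

#' Build the trial sequence for one participant
#'
#' Generates the full deterministic trial list: 6 training trials, four
#' precued and four postcued blocks of 54 trials each (every main image once
#' as target, once as distractor among the 36 one-pleasure trials, and once
#' within one of the 18 combined-pleasure pairs), and a final baseline block
#' in which each main image appears alone on its counterbalanced side.
#' Set-to-side mapping alternates with participant parity: even participant
#' indices see set A on the left.
#'
#' Within each cued block the one-pleasure trials realize two independent
#' random bijections between left-set and right-set images (one for
#' left-target trials, one for right-target trials) and the combined trials a
#' third; trial order within every block is uniformly shuffled under the
#' design seed.
#'
#' @param catalog A `stimulus_catalog` from [select_stimuli()].
#' @param participant_index Non-negative integer identifying the participant.
#' @param seed Master integer seed; the design is deterministic given
#'   `(participant_index, seed)`.
#' @param n_cued_blocks_per_timing Cued blocks per cue timing (default 4).
#' @param first_timing Which cue timing the block alternation starts with.
#' @return An `experiment_design` object: a list with the side mapping, the
#'   image sets, and `trials`, a data.frame with columns `block`,
#'   `block_type`, `trial`, `cue`, `left_image`, `right_image`,
#'   `target_side`.
#' @export
build_design <- function(catalog, participant_index = 0, seed = 1,
                         n_cued_blocks_per_timing = 4,
                         first_timing = c("precued", "postcued")) {
  check_catalog(catalog)
  first_timing <- match.arg(first_timing)
  main <- catalog_main(catalog)
  training_ids <- catalog$image_id[catalog$role == "training"]

  left_set <- if (participant_index %% 2 == 0) "A" else "B"
  right_set <- setdiff(c("A", "B"), left_set)
  left_ids <- main$image_id[main$set_label == left_set]
  right_ids <- main$image_id[main$set_label == right_set]
  n_side <- length(left_ids)

  design_seed <- derive_seed(seed, participant_index, salt = 1L)
  timings <- rep(
    if (first_timing == "precued") c("precued", "postcued")
    else c("postcued", "precued"),
    n_cued_blocks_per_timing
  )

  trials <- with_seed(design_seed, {
    blocks <- list()

    # training block (block 0): one trial per cue type for each timing,
    # images drawn from the training set
    tr_cues <- rep(c("left", "right", "both"), 2)
    tr_rows <- lapply(seq_along(tr_cues), function(i) {
      imgs <- sample(training_ids, 2)
      data.frame(
        block = 0L, block_type = "training", trial = i, cue = tr_cues[i],
        left_image = imgs[1], right_image = imgs[2],
        target_side = c(left = "left", right = "right", both = "both")[[tr_cues[i]]],
        stringsAsFactors = FALSE
      )
    })
    blocks[[1]] <- do.call(rbind, tr_rows)

    for (b in seq_along(timings)) {
      perm_left_target <- sample(right_ids)   # distractors for left targets
      perm_right_target <- sample(left_ids)   # distractors for right targets
      perm_combined <- sample(right_ids)

      one_left <- data.frame(
        cue = "left", left_image = left_ids, right_image = perm_left_target,
        target_side = "left", stringsAsFactors = FALSE
      )
      one_right <- data.frame(
        cue = "right", left_image = perm_right_target, right_image = right_ids,
        target_side = "right", stringsAsFactors = FALSE
      )
      combined <- data.frame(
        cue = "both", left_image = left_ids, right_image = perm_combined,
        target_side = "both", stringsAsFactors = FALSE
      )
      blk <- rbind(one_left, one_right, combined)
      blk <- blk[sample(nrow(blk)), ]
      blk <- cbind(
        data.frame(block = b, block_type = timings[b],
                   trial = seq_len(nrow(blk))),
        blk
      )
      blocks[[length(blocks) + 1]] <- blk
    }

    # baseline block: each main image once, alone, on its assigned side
    base <- data.frame(
      left_image = ifelse(main$set_label == left_set, main$image_id,
                          NA_character_),
      right_image = ifelse(main$set_label == right_set, main$image_id,
                           NA_character_),
      stringsAsFactors = FALSE
    )
    base <- base[sample(nrow(base)), ]
    base <- cbind(
      data.frame(block = length(timings) + 1L, block_type = "baseline",
                 trial = seq_len(nrow(base)), cue = "none"),
      base,
      data.frame(target_side = "single", stringsAsFactors = FALSE)
    )
    blocks[[length(blocks) + 1]] <- base

    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
  })

  structure(
    list(
      participant_index = as.integer(participant_index),
      seed = as.integer(seed),
      side_mapping = c(left = left_set, right = right_set),
      left_images = left_ids,
      right_images = right_ids,
      training_images = training_ids,
      main_images = main$image_id,
      n_cued_blocks_per_timing = n_cued_blocks_per_timing,
      # display constants recorded as metadata only, never used in computation
      timing_ms = c(image = 200, cue = 1000),
      trials = trials
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> participant %d, seed %d, left side = set %s\n",
    x$participant_index, x$seed, x$side_mapping[["left"]]
  ))
  cat(sprintf("  %d trials in %d blocks\n", nrow(x$trials),
              length(unique(x$trials$block))))
  invisible(x)
}

#' Check an experiment design against its structural invariants
#'
#' Produces a report rather than raising: per-block trial counts, per-image
#' target/distractor/pair tallies in every cued block, side balance, and
#' set-membership of every pair.
#'
#' @param design An `experiment_design`.
#' @return A `design_report`: list with `checks` (data.frame of check name,
#'   pass flag, detail) and overall `pass`.
#' @export
validate_design <- function(design) {
  tr <- design$trials
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE
    )
  }

  cued <- tr[tr$block_type %in% c("precued", "postcued"), ]
  cued_blocks <- unique(cued$block)
  n_expected <- design$n_cued_blocks_per_timing

  add("n_precued_blocks",
      sum(tapply(tr$block_type, tr$block, function(x) x[1]) == "precued") ==
        n_expected,
      sprintf("expected %d", n_expected))
  add("n_postcued_blocks",
      sum(tapply(tr$block_type, tr$block, function(x) x[1]) == "postcued") ==
        n_expected,
      sprintf("expected %d", n_expected))
  add("n_cued_blocks_reported", TRUE, sprintf("%d", length(cued_blocks)))

  n_main <- length(design$main_images)
  sizes <- table(cued$block)
  add("cued_block_size",
      all(sizes == n_main / 2 * 3),
      sprintf("sizes: %s", paste(sizes, collapse = ",")))

  one <- cued[cued$cue %in% c("left", "right"), ]
  add("one_pleasure_per_block",
      all(table(one$block) == n_main),
      "each cued block: one-pleasure trials = n main images")
  add("combined_per_block",
      all(table(cued$block[cued$cue == "both"]) == n_main / 2),
      "each cued block: combined trials = n main / 2")
  add("target_side_balance",
      all(table(one$block, one$target_side) == n_main / 2),
      "18 left-target and 18 right-target per block at defaults")

  tally_ok <- TRUE
  pair_ok <- TRUE
  for (b in cued_blocks) {
    blk <- cued[cued$block == b, ]
    ones <- blk[blk$cue %in% c("left", "right"), ]
    targets <- ifelse(ones$cue == "left", ones$left_image, ones$right_image)
    distractors <- ifelse(ones$cue == "left", ones$right_image, ones$left_image)
    comb <- blk[blk$cue == "both", ]
    if (!identical(sort(targets), sort(design$main_images)) ||
        !identical(sort(distractors), sort(design$main_images))) {
      tally_ok <- FALSE
    }
    if (!identical(sort(c(comb$left_image, comb$right_image)),
                   sort(design$main_images))) {
      pair_ok <- FALSE
    }
  }
  add("each_image_target_once_distractor_once", tally_ok,
      "per cued block, counted over one-pleasure trials")
  add("each_image_in_one_pair", pair_ok, "per cued block, combined trials")

  sets_ok <- all(
    cued$left_image %in% design$left_images &
      cued$right_image %in% design$right_images
  )
  add("pairs_from_opposite_sets", sets_ok, "left/right images from own sets")
  add("cue_both_iff_target_both",
      all((cued$cue == "both") == (cued$target_side == "both")), "")

  base <- tr[tr$block_type == "baseline", ]
  shown <- ifelse(is.na(base$left_image), base$right_image, base$left_image)
  add("baseline_size", nrow(base) == n_main, sprintf("expected %d", n_main))
  add("baseline_each_image_once",
      identical(sort(shown), sort(design$main_images)), "")
  add("baseline_single_image",
      all(is.na(base$left_image) != is.na(base$right_image)),
      "exactly one image per baseline trial")
  add("baseline_counterbalanced_side",
      all(base$left_image %in% c(design$left_images, NA_character_)) &&
        all(base$right_image %in% c(design$right_images, NA_character_)), "")

  add("n_training_trials", sum(tr$block_type == "training") == 6, "")

  checks <- do.call(rbind, checks)
  structure(list(checks = checks, pass = all(checks$pass)),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> %s (%d/%d checks passed)\n",
              if (x$pass) "PASS" else "FAIL",
              sum(x$checks$pass), nrow(x$checks)))
  if (!x$pass) print(x$checks[!x$checks$pass, c("check", "detail")])
  invisible(x)
}

#' Write a design's trial list as long-format CSV
#'
#' @param design An `experiment_design`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  out <- cbind(participant = design$participant_index, design$trials)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
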