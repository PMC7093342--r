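test_that("quintile selection returns 36 main and 4 training images", {
  catalog <- select_stimuli(synthetic_rating_table(900, seed = 1))
  expect_equal(sum(catalog$role == "main"), 36)
  expect_equal(sum(catalog$role == "training"), 4)
  expect_equal(as.vector(table(catalog$set_label[catalog$role == "main"])),
               c(18L, 18L))
  expect_true(all(is.na(catalog$set_label[catalog$role == "training"])))
  expect_false(anyDuplicated(catalog$image_id) > 0)
})

test_that("a 40-row table is selected in full with no duplicates", {
  tab <- grid_rating_table(40)
  catalog <- select_stimuli(tab)
  expect_setequal(catalog$image_id, tab$image_id)
  expect_equal(nrow(catalog), 40)
})

test_that("selected main beauties reach the table extremes on a uniform grid", {
  tab <- grid_rating_table(120)
  catalog <- select_stimuli(tab)
  main <- catalog[catalog$role == "main", ]
  # brute-force reference: the global extremes must be the top-quintile max
  # and bottom-quintile min, hence selected
  expect_true(max(tab$beauty) %in% main$beauty)
  expect_true(min(tab$beauty) %in% main$beauty)
  # both sets span the range: set means within half a scale unit
  means <- tapply(main$beauty, main$set_label, mean)
  expect_lt(abs(diff(means)), 0.5)
})

test_that("selection is invariant to input row order and repeatable", {
  tab <- synthetic_rating_table(300, seed = 7)
  shuffled <- tab[sample(nrow(tab)), ]
  c1 <- select_stimuli(tab)
  c2 <- select_stimuli(shuffled)
  expect_equal(c1, c2)
  expect_equal(select_stimuli(tab), c1)
})

test_that("selection rejects degenerate rating tables", {
  expect_error(select_stimuli(grid_rating_table(39)), "at least 40")
  dup <- grid_rating_table(40)
  dup$image_id[2] <- dup$image_id[1]
  expect_error(select_stimuli(dup), "duplicate")
  flat <- grid_rating_table(40)
  flat$beauty <- 4
  expect_error(select_stimuli(flat), "identical")
  expect_error(select_stimuli(grid_rating_table(60), n_training = 9),
               "n_training")
})

test_that("each cued block holds 54 trials: 36 one-pleasure and 18 combined", {
  design <- build_design(test_catalog(), 0, seed = 1)
  cued <- design$trials[design$trials$block_type %in%
                          c("precued", "postcued"), ]
  sizes <- table(cued$block)
  expect_length(sizes, 8)
  expect_true(all(sizes == 54))
  by_cue <- table(cued$block, cued$cue)
  expect_true(all(by_cue[, "left"] == 18))
  expect_true(all(by_cue[, "right"] == 18))
  expect_true(all(by_cue[, "both"] == 18))
})

test_that("per cued block each image is target once, distractor once, paired once", {
  design <- build_design(test_catalog(), 3, seed = 11)
  cued <- design$trials[design$trials$block_type %in%
                          c("precued", "postcued"), ]
  for (b in unique(cued$block)) {
    blk <- cued[cued$block == b, ]
    ones <- blk[blk$cue != "both", ]
    targets <- ifelse(ones$cue == "left", ones$left_image, ones$right_image)
    distractors <- ifelse(ones$cue == "left", ones$right_image,
                          ones$left_image)
    expect_setequal(targets, design$main_images)
    expect_setequal(distractors, design$main_images)
    expect_false(anyDuplicated(targets) > 0)
    expect_false(anyDuplicated(distractors) > 0)
    comb <- blk[blk$cue == "both", ]
    expect_setequal(c(comb$left_image, comb$right_image),
                    design$main_images)
  }
})

test_that("baseline block shows every main image once on its own side", {
  design <- build_design(test_catalog(), 0, seed = 2)
  base <- design$trials[design$trials$block_type == "baseline", ]
  expect_equal(nrow(base), 36)
  expect_true(all(is.na(base$left_image) != is.na(base$right_image)))
  shown <- ifelse(is.na(base$left_image), base$right_image, base$left_image)
  expect_setequal(shown, design$main_images)
  expect_true(all(stats::na.omit(base$left_image) %in% design$left_images))
  expect_true(all(stats::na.omit(base$right_image) %in% design$right_images))
})

test_that("designs are deterministic and counterbalanced by participant parity", {
  d1 <- build_design(test_catalog(), 0, seed = 5)
  d2 <- build_design(test_catalog(), 0, seed = 5)
  expect_identical(d1$trials, d2$trials)
  expect_equal(unname(d1$side_mapping[["left"]]), "A")
  d3 <- build_design(test_catalog(), 1, seed = 5)
  expect_equal(unname(d3$side_mapping[["left"]]), "B")
  expect_equal(sum(d1$trials$block_type == "training"), 6)
})

test_that("design validation passes generated designs and flags broken ones", {
  design <- build_design(test_catalog(), 0, seed = 3)
  report <- validate_design(design)
  expect_true(report$pass)
  expect_equal(report$checks$detail[report$checks$check ==
                                      "n_cued_blocks_reported"], "8")

  broken <- design
  broken$trials <- broken$trials[-10, ]   # delete one cued trial
  rep2 <- validate_design(broken)
  expect_false(rep2$pass)
  expect_false(rep2$checks$pass[rep2$checks$check == "cued_block_size"])
})

test_that("designs validate across a sweep of seeds", {
  passes <- vapply(1:100, function(s) {
    validate_design(build_design(test_catalog(), s %% 4, seed = s))$pass
  }, logical(1))
  expect_equal(sum(passes), 100)
})

test_that("catalogs with unequal set sizes are rejected", {
  bad <- test_catalog()
  bad$set_label[bad$role == "main"][1] <- "B"
  expect_error(build_design(bad, 0, 1), "unequal set sizes")
})
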