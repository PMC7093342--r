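# tiny hand-built dataset: 2 participants, 2 images, baselines plus a few
# cued trials with known errors
tiny_error_dataset <- function() {
  row <- function(participant, block_type, cue, left, right, target_side,
                  rating, block = 1, trial = 1) {
    data.frame(participant = participant, block = block,
               block_type = block_type, trial = trial, cue = cue,
               left_image = left, right_image = right,
               target_side = target_side, rating = rating,
               stringsAsFactors = FALSE)
  }
  rbind(
    # baselines: P0 rates A1 = 4, B1 = 9; P1 rates A1 = 3, B1 = 9
    row(0, "baseline", "none", "A1", NA, "single", 4, block = 9),
    row(0, "baseline", "none", NA, "B1", "single", 9, block = 9),
    row(1, "baseline", "none", "A1", NA, "single", 3, block = 9),
    row(1, "baseline", "none", NA, "B1", "single", 9, block = 9),
    # P0 precued: one-pleasure trial on A1 rated 7 (error 3), B1 exact
    row(0, "precued", "left", "A1", "B1", "left", 7),
    row(0, "precued", "right", "A1", "B1", "right", 9),
    # P0 combined: rating 6.5 = mean(4, 9) -> error 0 for both images
    row(0, "precued", "both", "A1", "B1", "both", 6.5),
    row(1, "precued", "left", "A1", "B1", "left", 3),
    row(1, "precued", "right", "A1", "B1", "right", 8),
    row(1, "precued", "both", "A1", "B1", "both", 7)
  )
}

test_that("error matrices hold mean absolute deviations from single-pleasure", {
  dat <- tiny_error_dataset()
  m <- error_matrix(dat, "one_pleasure", "precued")
  expect_equal(m["0", "A1"], 3)       # |7 - 4|
  expect_equal(m["0", "B1"], 0)
  expect_equal(m["1", "B1"], 1)       # |8 - 9|
  mc <- error_matrix(dat, "combined", "precued")
  expect_equal(unname(mc["0", ]), c(0, 0))   # |6.5 - mean(4, 9)|
  expect_equal(unname(mc["1", ]), c(1, 1))   # |7 - 6|, both images
})

test_that("observers who always report baseline have an all-zero error matrix", {
  dat <- small_cohort(n = 3, late = 0, discretize = FALSE, scheme = "uniform")
  m <- error_matrix(dat, "one_pleasure", "postcued")
  expect_true(all(m == 0))
})

test_that("participants with missing single-pleasures are dropped, with warning", {
  dat <- tiny_error_dataset()
  dat$rating[dat$participant == 1 & dat$block_type == "baseline"][1] <- NA
  expect_warning(m <- error_matrix(dat, "one_pleasure", "precued"),
                 "dropped participant")
  expect_equal(rownames(m), "0")
})

test_that("Cronbach's alpha matches its defining variance decomposition", {
  # identical (nonconstant) columns -> alpha = 1
  col <- c(1, 3, 2, 5, 4)
  expect_equal(cronbach_alpha(matrix(rep(col, 6), ncol = 6)), 1)

  # two unit-variance items with sample correlation exactly 0.5:
  # alpha = 2 r / (1 + r) = 2/3
  set.seed(17)
  x <- as.numeric(scale(rnorm(12)))
  z <- residuals(lm(rnorm(12) ~ x))
  z <- as.numeric(scale(z))
  y <- 0.5 * x + sqrt(1 - 0.25) * z
  expect_equal(stats::cor(x, y), 0.5, tolerance = 1e-12)
  expect_equal(cronbach_alpha(cbind(x, y)), 2 * 0.5 / 1.5, tolerance = 1e-10)

  # independent items: alpha near zero
  set.seed(18)
  m <- matrix(rnorm(200 * 8), nrow = 200)
  expect_lt(abs(cronbach_alpha(m)), 0.15)

  expect_error(cronbach_alpha(matrix(1, 3, 3)), "zero total")
  expect_error(cronbach_alpha(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("alpha is invariant to shifting and positive rescaling", {
  set.seed(19)
  m <- matrix(rnorm(60), nrow = 10) + rep(rnorm(10, sd = 2), 6)
  a0 <- cronbach_alpha(m)
  expect_equal(cronbach_alpha(m + 3), a0)
  expect_equal(cronbach_alpha(m * 2.5), a0)
})

test_that("absolute-agreement ICC matches an ANOVA oracle", {
  # identical raters -> perfect agreement
  base <- c(2, 5, 7, 4)
  expect_equal(icc_absolute_agreement(rbind(base, base, base)), 1)

  # oracle: mean squares from aov() on the long two-way layout
  oracle_icc <- function(m, type = "agreement") {
    long <- data.frame(
      score = as.numeric(m),                   # column-major: raters fastest
      rater = factor(rep(seq_len(nrow(m)), times = ncol(m))),
      target = factor(rep(seq_len(ncol(m)), each = nrow(m)))
    )
    ms <- summary(aov(score ~ target + rater, data = long))[[1]]$`Mean Sq`
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    n <- ncol(m); k <- nrow(m)
    if (type == "agreement") {
      (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    } else {
      (msr - mse) / (msr + (k - 1) * mse)
    }
  }

  set.seed(23)
  toy <- matrix(rnorm(12, mean = 5), nrow = 3)   # 3 raters x 4 targets
  expect_equal(icc_absolute_agreement(toy), oracle_icc(toy),
               tolerance = 1e-8)

  # constant offset between raters hurts absolute agreement but not
  # consistency
  r1 <- c(1, 4, 6, 8)
  shifted <- rbind(r1, r1 + 2)
  expect_lt(icc_absolute_agreement(shifted), oracle_icc(shifted, "consistency"))

  expect_error(icc_absolute_agreement(matrix(3, 2, 4)), "constant")
})

test_that("the attenuation ceiling is the root product of reliabilities", {
  expect_equal(round(attenuation_ceiling(0.85, 0.81), 2), 0.83)
  expect_equal(attenuation_ceiling(1, 1), 1)
  expect_equal(attenuation_ceiling(0.92, 0.89), sqrt(0.92 * 0.89))
  expect_equal(attenuation_ceiling(0.6, 0.9), attenuation_ceiling(0.9, 0.6))
  # geometric mean lies between the two reliabilities
  expect_true(attenuation_ceiling(0.6, 0.9) >= 0.6 &&
                attenuation_ceiling(0.6, 0.9) <= 0.9)
  expect_error(attenuation_ceiling(0, 0.5), "alphas")
  expect_error(attenuation_ceiling(-0.2, 0.5), "alphas")
})

test_that("duplicated conditions correlate perfectly", {
  dat <- simulate_cohort(6, test_catalog(), "faithful",
                         late_noise_sd = c(0.5, 2.5), seed = 31)
  pre <- dat[dat$block_type == "precued", ]
  pre$block_type <- "postcued"
  dup <- rbind(dat[dat$block_type %in% c("baseline", "training", "precued"), ],
               pre)
  res <- error_correlations(dup)
  r <- res$correlations
  i <- r$condition_x == "one_pleasure_precued" &
    r$condition_y == "one_pleasure_postcued"
  expect_equal(r$r[i], 1)
})

test_that("shared error variance drives correlations toward their ceiling", {
  # participants differ widely in a noise level common to all conditions, so
  # precued and postcued error profiles share most of their variance
  dat <- simulate_cohort(16, test_catalog(), "faithful",
                         late_noise_sd = c(0.4, 2.6), seed = 33)
  res <- error_correlations(dat)
  r <- res$correlations
  i <- r$condition_x == "one_pleasure_precued" &
    r$condition_y == "one_pleasure_postcued"
  expect_gt(r$r[i], 0.7 * r$ceiling[i])
  expect_lte(r$r[i], 1)
})

test_that("homogeneous cohorts show no systematic cross-family correlation", {
  rs <- vapply(1:8, function(s) {
    dat <- simulate_cohort(8, test_catalog(), "faithful",
                           late_noise_sd = 1.4, seed = 300 + s)
    r <- error_correlations(dat)$correlations
    i <- r$condition_x == "one_pleasure_precued" &
      r$condition_y == "combined_postcued"
    r$r[i]
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.3)
})
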