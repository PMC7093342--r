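test_that("the linear combination rule computes exact predictions", {
  expect_equal(predict_rating(0, 1, 1, 3, 9), 3)
  expect_equal(predict_rating(0, 1, 0.5, 3, 9), 6)
  # cohort-mean combined-task fits: compressive and expansive parameters
  expect_equal(predict_rating(0.39, 0.85, 0.5, 5, 5), 4.64)
  expect_equal(predict_rating(-0.70, 1.05, 0.5, 2, 4), 2.45)
})

test_that("model specifications encode the family's constraints", {
  part <- model_spec("partial_averaging", "one_pleasure")
  expect_equal(part$fixed$a, 0)
  expect_equal(part$fixed$b, 1)
  expect_equal(part$lower[["w"]], 0.5)
  expect_equal(part$upper[["w"]], 1)
  expect_equal(model_spec("flexible", "one_pleasure")$name,
               "partial_averaging")
  comp <- model_spec("compressive", "combined")
  expect_equal(comp$fixed$w, 0.5)
  expect_true(comp$lower[["a"]] > 0 && comp$upper[["b"]] < 1)
  expa <- model_spec("expansive", "combined")
  expect_true(expa$upper[["a"]] < 0 && expa$lower[["b"]] > 1)
  expect_error(model_spec("compressive", "one_pleasure"), "combined")
  expect_error(model_spec("partial_averaging", "combined"), "one-pleasure")
})

test_that("noiseless matched data are fit exactly", {
  obs <- synthetic_obs(30, w = 1)
  f <- fit_model(obs, model_spec("faithful", "one_pleasure"))
  expect_equal(f$rmse_train, 0)
  # exact weight recovery from noise-free partial data
  obs7 <- synthetic_obs(30, w = 0.7)
  f7 <- fit_model(obs7, model_spec("partial_averaging", "one_pleasure"))
  expect_equal(f7$params[["w"]], 0.7, tolerance = 1e-4)
  f7o <- fit_model(obs7, model_spec("partial_averaging", "one_pleasure"),
                   method = "optim")
  expect_equal(f7o$params[["w"]], 0.7, tolerance = 1e-4)
})

test_that("mismatched-model residuals follow the closed form", {
  obs <- synthetic_obs(40, w = 0.5)   # averaging data
  f <- fit_model(obs, model_spec("faithful", "one_pleasure"))
  expect_equal(f$rmse_train, sqrt(mean(((obs$P2 - obs$P1) / 2)^2)))
})

test_that("missing single-pleasures flag the participant for exclusion", {
  obs <- synthetic_obs(10)
  obs$P1[3] <- NA
  expect_error(fit_model(obs, model_spec("faithful", "one_pleasure")),
               "exclusion")
  expect_error(
    fit_model(synthetic_obs(2), model_spec("faithful", "one_pleasure")),
    "at least"
  )
})

test_that("analytic constrained fits agree with multi-start optimization", {
  specs <- list(
    model_spec("partial_averaging", "one_pleasure"),
    model_spec("compressive", "combined"),
    model_spec("expansive", "combined"),
    model_spec("flexible", "combined")
  )
  pars <- expand.grid(a = c(-0.8, 0, 0.9), b = c(0.7, 1.5))
  for (s in seq_len(nrow(pars))) {
    obs <- synthetic_obs(25, a = pars$a[s], b = pars$b[s],
                         w = 0.5 + 0.08 * s, noise_sd = 1, seed = 100 + s)
    for (spec in specs) {
      fa <- fit_model(obs, spec, method = "analytic")
      fo <- fit_model(obs, spec, method = "optim")
      expect_equal(fa$rmse_train, fo$rmse_train, tolerance = 1e-6)
      expect_true(all(fa$params[spec$free] >= spec$lower - 1e-9) &&
                    all(fa$params[spec$free] <= spec$upper + 1e-9))
    }
  }
})

test_that("zero-free-parameter LOOCV equals the training RMSE exactly", {
  obs <- synthetic_obs(20, w = 1, noise_sd = 1.2)
  l <- loocv(obs, model_spec("faithful", "one_pleasure"))
  expect_identical(l$rmse_loocv, l$rmse_train)
  # noiseless matched model: LOOCV error is exactly zero
  l0 <- loocv(synthetic_obs(20, w = 0.8),
              model_spec("partial_averaging", "one_pleasure"))
  expect_equal(l0$rmse_loocv, 0, tolerance = 1e-12)
})

test_that("LOOCV matches brute-force refit oracles", {
  # tiny 5-trial case, free weight
  obs5 <- synthetic_obs(5, w = 0.85, noise_sd = 0.8, seed = 31)
  l5 <- loocv(obs5, model_spec("partial_averaging", "one_pleasure"))
  expect_equal(l5$rmse_loocv, oracle_loocv_w(obs5), tolerance = 1e-8)

  # free (a, b) boxes, including active constraints
  for (seed in 32:34) {
    obs <- synthetic_obs(12, a = 0.5, b = 0.8, w = 0.5, noise_sd = 1,
                         seed = seed, trial_type = "combined")
    for (name in c("compressive", "expansive", "flexible")) {
      spec <- model_spec(name, "combined")
      l <- loocv(obs, spec)
      expect_equal(
        l$rmse_loocv,
        oracle_loocv_ab(obs, spec$lower[spec$free], spec$upper[spec$free]),
        tolerance = 1e-6
      )
    }
  }
})

test_that("freer models never fit worse in sample (nesting)", {
  for (seed in 41:45) {
    obs <- synthetic_obs(30, w = 1, noise_sd = 1.4, seed = seed)
    f_faith <- fit_model(obs, model_spec("faithful", "one_pleasure"))
    f_part <- fit_model(obs, model_spec("partial_averaging", "one_pleasure"))
    expect_lte(f_part$rmse_train, f_faith$rmse_train + 1e-12)
  }
})

test_that("LOOCV penalizes the extra parameter on faithful data", {
  # with exact single-pleasures the faithful model is the true optimum and
  # the free-weight model can only fit noise out of sample
  diffs <- vapply(1:50, function(seed) {
    obs <- synthetic_obs(30, w = 1, noise_sd = 1.4, seed = 200 + seed)
    loocv(obs, model_spec("partial_averaging", "one_pleasure"))$rmse_loocv -
      loocv(obs, model_spec("faithful", "one_pleasure"))$rmse_loocv
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("summing observers are recovered as slope 2, rejecting averaging", {
  obs <- synthetic_obs(60, a = 0, b = 2, w = 0.5, noise_sd = 0.3,
                       seed = 51, trial_type = "combined")
  f <- fit_model(obs, model_spec("flexible", "combined"))
  expect_equal(f$params[["b"]], 2, tolerance = 0.1)
  f_avg <- fit_model(obs, model_spec("faithful", "combined"))
  expect_gt(f_avg$rmse_train, f$rmse_train)
})

test_that("predictions are equivariant to a common shift of ratings and a", {
  obs <- synthetic_obs(20, a = 0.5, b = 0.9, w = 0.5, noise_sd = 0.5,
                       seed = 61, trial_type = "combined")
  p1 <- predict_rating(0.5, 0.9, 0.5, obs$P1, obs$P2)
  p2 <- predict_rating(0.5 + 2, 0.9, 0.5, obs$P1, obs$P2)
  expect_equal(p2, p1 + 2)
})

test_that("cohort comparison aggregates, reports SEM and picks winners", {
  # noiseless continuous cohort: the generative model wins with zero error
  dat <- small_cohort(n = 3, model = "compulsory_averaging", late = 0,
                      discretize = FALSE, scheme = "uniform")
  cmp <- compare_models(dat, default_model_specs("one_pleasure"))
  expect_true(all(cmp$winners$model == "compulsory_averaging"))
  win <- cmp$summary[cmp$summary$model == "compulsory_averaging", ]
  expect_true(all(win$mean_rmse_loocv < 1e-10))
  expect_true(all(cmp$summary$sem_rmse_loocv >= 0))
  expect_equal(unique(cmp$summary$n_participants), 3)

  # tie-breaking: on noiseless faithful data the free-weight model also
  # reaches zero error; the winner is the model with fewer free parameters
  dat_f <- small_cohort(n = 3, model = "faithful", late = 0,
                        discretize = FALSE, scheme = "uniform")
  cmp_f <- compare_models(dat_f, default_model_specs("one_pleasure"))
  expect_true(all(cmp_f$winners$model == "faithful"))

  expect_error(compare_models(dat[dat$participant == 0, ]),
               "insufficient participants")
})
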