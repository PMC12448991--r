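test_that("the weight-difference gate is a normalised, symmetric Gaussian", {
  g0 <- weight_gate(0, 76.44)
  expect_equal(g0, 1 / (76.44 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(g0, 0.00522, tolerance = 1e-3)

  dw <- c(-300, -50, 0, 10, 150)
  expect_equal(weight_gate(dw, 80), weight_gate(-dw, 80))
  expect_lt(weight_gate(1e4, 76.44), 1e-300)
  expect_error(weight_gate(0, 0), class = "weightsense_validation_error")
  expect_error(weight_gate(0, -3), class = "weightsense_validation_error")
})

test_that("reference coefficients reproduce the known pair-level effects", {
  k <- swi_reference_coefficients()

  # equal-weight SWI pair, densities 0.577 vs 0.441: judged-minus-other
  # difference = 126.43*0.136 + (27814+17919)*0.136*gate(0) ~ 49.65 g
  dif <- predict_weight_difference(375, 0.577, 375, 0.441, k)
  oracle <- 126.43 * 0.136 + (27814 + 17919) * 0.136 * weight_gate(0, 76.44)
  expect_equal(dif, oracle, tolerance = 1e-6)
  expect_equal(dif, 49.65, tolerance = 1e-3)

  # combined density influence ~2.9x larger at zero weight difference
  expect_equal(effective_density_ratio(k), 2.888, tolerance = 1e-3)

  # identical stimuli: no difference
  expect_equal(predict_weight_difference(375, 0.5, 375, 0.5, k), 0)
})

test_that("the difference form is an exact identity of two single-object predictions", {
  set.seed(11)
  n <- 1000
  w1 <- runif(n, 100, 700); w2 <- runif(n, 100, 700)
  d1 <- runif(n, 0.2, 1); d2 <- runif(n, 0.2, 1)
  k <- descriptive_coefficients(C = runif(1, -50, 50), beta1 = runif(1, 0.5, 2),
                                beta2 = runif(1, 0, 300), beta3 = runif(1, -1, 1),
                                beta4 = runif(1, 0, 5e4), beta5 = runif(1, -5e4, 0),
                                sigma = runif(1, 20, 200))
  lhs <- predict_weight_difference(w1, d1, w2, d2, k)
  rhs <- predict_weight(w1, d1, w2, d2, k) - predict_weight(w2, d2, w1, d1, k)
  expect_lt(max(abs(lhs - rhs) / pmax(abs(rhs), 1e-9)), 1e-12)
})

test_that("density influence decreases monotonically in |weight difference|", {
  k <- swi_reference_coefficients()
  inf <- density_influence(k, seq(0, 500, by = 1))
  expect_true(all(diff(inf$combined) <= 1e-12))
  expect_equal(inf$judged[1], 126.43 + 27814 * weight_gate(0, 76.44))
  expect_lt(inf$other[1], 0)
})

test_that("fitting is invariant to participant relabelling and row order", {
  st <- fx_small_study()
  f1 <- fit_descriptive(st$recs, st$sim$cubes, n_starts = 8, seed = 3)

  shuffled <- withr::with_seed(1, st$recs[sample.int(nrow(st$recs)), ])
  shuffled$participant_id <- paste0("X_", shuffled$participant_id)
  f2 <- fit_descriptive(shuffled, st$sim$cubes, n_starts = 8, seed = 3)
  expect_equal(unclass(f1$coefficients), unclass(f2$coefficients), tolerance = 1e-6)
  expect_equal(f1$ssr, f2$ssr, tolerance = 1e-9)
})

test_that("component ladder is monotone and ends at the full-model fit", {
  st <- fx_small_study()
  lad <- suppressWarnings(component_ladder(st$recs, st$sim$cubes,
                                           n_starts = 6, seed = 5))
  expect_equal(nrow(lad), 5)
  expect_setequal(lad$component, weightsense:::descriptive_components)
  expect_true(all(diff(lad$r_squared) >= -1e-12))
  expect_true(all(diff(lad$ssr) <= 1e-6))

  full <- fit_descriptive(st$recs, st$sim$cubes, n_starts = 8, seed = 5)
  expect_equal(lad$r_squared[5], full$r_squared, tolerance = 1e-6)
})

test_that("ladder gains vanish for components absent from the generating model", {
  gen <- descriptive_coefficients(C = 0, beta1 = 1.23, beta2 = 126.43,
                                  beta3 = 0, beta4 = 0, beta5 = 0, sigma = 76.44)
  sim <- simulate_study(n_participants = 5, seed = 31,
                        model = generating_model("descriptive", gen))
  prep <- suppressWarnings(preprocess_estimates(sim$estimates))
  lad <- suppressWarnings(component_ladder(retained_estimates(prep), sim$cubes,
                                           n_starts = 6, seed = 6))
  absent <- c("weight_other", "gated_density_judged", "gated_density_other")
  gains <- diff(c(0, lad$r_squared))[match(absent, lad$component)]
  expect_true(all(gains < 0.01))
})

test_that("cross-validation prefers the generating model class", {
  # gated terms present in the generator: the full model should win LOO-CV
  # in a clear majority of replicates
  wins <- 0L
  for (s in 1:3) {
    sim <- simulate_study(n_participants = 6, seed = 400 + s)
    prep <- suppressWarnings(preprocess_estimates(sim$estimates))
    cv <- loo_cv_descriptive(retained_estimates(prep), sim$cubes,
                             variants = c("full", "linear"),
                             n_starts = 4, seed = s)
    wins <- wins + (cv$variant[1] == "full")
  }
  expect_gte(wins, 2L)

  # linear generator: the gated variant should not beat linear decisively
  genlin <- descriptive_coefficients(C = 0, beta1 = 1.23, beta2 = 126.43,
                                     beta3 = 0.13, beta4 = 0, beta5 = 0,
                                     sigma = 76.44)
  sim <- simulate_study(n_participants = 6, seed = 500,
                        model = generating_model("descriptive", genlin))
  prep <- suppressWarnings(preprocess_estimates(sim$estimates))
  # sigma is unidentified when the generator has no gated terms; the pinned-
  # bound warning is the expected diagnostic
  cv <- suppressWarnings(
    loo_cv_descriptive(retained_estimates(prep), sim$cubes,
                       variants = c("full", "linear"),
                       n_starts = 4, seed = 1)
  )
  err <- setNames(cv$cv_error, cv$variant)
  expect_lt(abs(err[["full"]] - err[["linear"]]) / err[["linear"]], 0.05)
})

test_that("zero-noise cross-validation error is essentially zero", {
  cl <- fx_clean_study(n = 3)
  cv <- loo_cv_descriptive(cl$recs, cl$sim$cubes, variants = "full",
                           n_starts = 4, seed = 2)
  expect_lt(cv$cv_error[1] / nrow(cl$recs), 1e-6)
})

test_that("volume-variant fits are supported and rankable", {
  st <- fx_small_study()
  cv <- loo_cv_descriptive(st$recs, st$sim$cubes,
                           variants = c("full", "volume_full"),
                           n_starts = 4, seed = 8)
  expect_equal(nrow(cv), 2)
  expect_true(all(cv$converged))
  expect_true(all(is.finite(cv$cv_error)))
})
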