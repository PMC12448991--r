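test_that("r_squared matches hand arithmetic and an independent oracle", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)),
               class = "weightsense_validation_error")
  expect_error(r_squared(1:3, 1:4), class = "weightsense_validation_error")

  set.seed(8)
  obs <- rnorm(50); pred <- obs + rnorm(50, 0, 0.3)
  expect_equal(r_squared(obs, pred), naive_r2(obs, pred), tolerance = 1e-12)
})

test_that("veridical estimates give a zero bias field with correct geometry", {
  cubes <- fx_cubes()
  tr <- build_trial_list(fx_pairs(), "M750", participants = c("P01", "P02"), seed = 3)
  # responses = true weight exactly
  recs <- dplyr::bind_rows(
    dplyr::mutate(tr, cube_id = left_cube, other_cube = right_cube),
    dplyr::mutate(tr, cube_id = right_cube, other_cube = left_cube)
  ) |>
    dplyr::left_join(cubes[, c("cube_id", "weight")], by = "cube_id") |>
    dplyr::mutate(normalised = weight)
  bf <- build_bias_field(recs, cubes)
  expect_equal(nrow(bf), 105)
  expect_equal(max(abs(bf$bias)), 0)
  # true log ratios satisfy logW - logV = log density ratio
  lk <- cubes[match(sub("\\|.*", "", bf$pair_id), cubes$cube_id), ]
  lk2 <- cubes[match(sub(".*\\|", "", bf$pair_id), cubes$cube_id), ]
  expect_equal(bf$logW_ratio - bf$logV_ratio, log(lk$density / lk2$density))
})

test_that("swapping pair orientation flips the bias sign exactly", {
  st <- fx_small_study()
  bf <- build_bias_field(st$recs, st$sim$cubes)
  # invert the per-trial ratios by swapping which cube is labelled object 1
  swapped <- st$recs
  parts <- strsplit(swapped$pair_id, "|", fixed = TRUE)
  # relabel so lexicographic order reverses: prefix flips ordering
  swapped$cube_id <- ifelse(swapped$cube_id == purrr::map_chr(parts, 1),
                            paste0("z_", swapped$cube_id), swapped$cube_id)
  swapped$other_cube <- ifelse(swapped$other_cube == purrr::map_chr(parts, 1),
                               paste0("z_", swapped$other_cube), swapped$other_cube)
  swapped$pair_id <- make_pair_id(swapped$cube_id, swapped$other_cube)
  cubes2 <- st$sim$cubes
  renamed <- dplyr::mutate(cubes2, cube_id = paste0("z_", cube_id))
  bf2 <- build_bias_field(swapped, dplyr::bind_rows(cubes2, renamed))
  canonical <- vapply(strsplit(gsub("z_", "", bf2$pair_id), "|", fixed = TRUE),
                      function(p) paste(sort(p), collapse = "|"), "")
  j <- match(bf$pair_id, canonical)
  expect_equal(bf2$bias[j], -bf$bias, tolerance = 1e-12)
})

test_that("descriptive-model estimates overestimate the denser equal-weight object", {
  cubes <- fx_cubes()
  tr <- build_trial_list(fx_pairs(), "M750", participants = "P01", seed = 5)
  obs <- observer_profile(noise_sd = 0, outlier_rate = 0)
  est <- simulate_session(tr, cubes, obs, generating_model())
  est <- to_grams(est); est$normalised <- est$grams
  bf <- build_bias_field(est, cubes)
  # W650 (denser) vs W850: equal weight, positive density difference for
  # object 1 -> positive bias, equal to the model's own log prediction ratio
  row <- bf[bf$pair_id == "W650|W850", ]
  expect_equal(row$logW_ratio, 0)
  expect_gt(row$bias, 0)
  cs <- cubes[match(c("W650", "W850"), cubes$cube_id), ]
  k <- swi_reference_coefficients()
  oracle <- log(predict_weight(cs$weight[1], cs$density[1], cs$weight[2], cs$density[2], k) /
                  predict_weight(cs$weight[2], cs$density[2], cs$weight[1], cs$density[1], k))
  expect_equal(row$bias, oracle, tolerance = 1e-9)
})

test_that("variance regressions recover planted structure", {
  pts <- fx_pair_space()
  bf <- dplyr::mutate(pts,
                      response_variance = 0.01 + 0.05 * abs(logW_ratio) +
                        withr::with_seed(4, runif(dplyr::n(), 0, 1e-9)),
                      bias = 0)
  vr <- variance_regressions(bf)
  r2 <- setNames(vr$r_squared, vr$predictors)
  expect_equal(r2[["abs_logW"]], 1, tolerance = 1e-6)

  bf2 <- dplyr::mutate(pts, response_variance = 0.02, bias = 0)
  bf2$response_variance <- bf2$response_variance +
    withr::with_seed(2, runif(nrow(bf2), 0, 1e-9))
  vr2 <- variance_regressions(bf2)
  expect_true(all(vr2$r_squared < 0.1))
})

test_that("model comparison tables rank consistently", {
  a <- fit_report(model_name = "m1", n_params = 3, ssr = 10, r2 = 0.9, cv_error = 12)
  b <- fit_report(model_name = "m2", n_params = 5, ssr = 8, r2 = 0.92, cv_error = 15)
  tab <- compare_models(a, b)
  expect_equal(tab$model[1], "m1") # ranked by CV error when available
  expect_equal(tab$ranked_by[1], "cv_error")

  tab2 <- compare_models(a, dplyr::mutate(b, cv_error = NA_real_))
  expect_equal(tab2$model[1], "m2") # falls back to SSR
  expect_equal(tab2$ranked_by[1], "ssr")

  # identical model twice: identical metric rows
  tab3 <- compare_models(a, a)
  expect_equal(tab3$ssr[1], tab3$ssr[2])
  expect_equal(tab3$cv_error[1], tab3$cv_error[2])

  # nested models on the same data: the full fit explains at least as much
  st <- fx_small_study()
  full <- fit_descriptive(st$recs, st$sim$cubes, n_starts = 6, seed = 2)
  lin <- fit_descriptive(st$recs, st$sim$cubes,
                         components = weightsense:::descriptive_components[1:3],
                         seed = 2)
  expect_gte(full$r_squared, lin$r_squared)
  expect_lte(full$ssr, lin$ssr)
})

test_that("interchange files round-trip through CSV", {
  dir <- withr::local_tempdir()
  cubes <- fx_cubes()
  write_stimuli(cubes, file.path(dir, "stimuli.csv"))
  back <- read_stimuli(file.path(dir, "stimuli.csv"))
  expect_equal(back$weight, cubes$weight)
  expect_equal(back$cube_id, cubes$cube_id)

  st <- fx_small_study()
  write_trials(st$sim$trials, file.path(dir, "trials.csv"))
  tr <- read_trials(file.path(dir, "trials.csv"))
  expect_equal(nrow(tr), nrow(st$sim$trials))

  write_estimates(st$prep$estimates, file.path(dir, "estimates.csv"))
  est <- read_estimates(file.path(dir, "estimates.csv"))
  expect_equal(est$raw_units, st$prep$estimates$raw_units)
  expect_equal(est$outlier_pass, st$prep$estimates$outlier_pass)
})

test_that("tidiers and plots produce well-formed objects", {
  st <- fx_small_study()
  fd <- fit_descriptive(st$recs, st$sim$cubes, n_starts = 6, seed = 2)
  td <- tidy(fd)
  expect_setequal(td$term, c("C", "beta1", "beta2", "beta3", "beta4", "beta5", "sigma"))
  gl <- glance(fd)
  expect_equal(gl$nobs, fd$n)
  expect_s3_class(autoplot(fd), "ggplot")
  expect_s3_class(plot_density_influence(swi_reference_coefficients()), "ggplot")

  bf <- build_bias_field(st$recs, st$sim$cubes)
  expect_s3_class(autoplot(bf), "ggplot")

  fc <- fit_cue_combination(st$recs, st$sim$cubes, n_starts = 4, seed = 2)
  expect_equal(tidy(fc)$term, c("beta1", "beta2", "x", "y"))
  expect_equal(glance(fc)$n_params, 4L)
})
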