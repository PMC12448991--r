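test_that("the mixture prior is a proper, origin-symmetric density", {
  pr <- fx_ratio_prior()

  # mixture value = weighted sum of component densities
  cmp <- pr$components
  manual <- 0
  for (k in 1:3) {
    manual <- manual + cmp$weight[k] *
      weightsense:::bvn_density(0.3, -0.2, cmp$sd_logV[k], cmp$sd_logW[k],
                                cmp$correlation[k])
  }
  expect_equal(prior_density(pr, 0.3, -0.2), manual, tolerance = 1e-12)

  # symmetry under joint sign flip
  expect_equal(prior_density(pr, 0.4, 0.1), prior_density(pr, -0.4, -0.1))

  # integrates to ~1 over a wide grid
  g <- seq(-8, 8, length.out = 321)
  h <- diff(g)[1]
  z <- outer(g, g, function(x, y) prior_density(pr, x, y))
  expect_equal(sum(z) * h^2, 1, tolerance = 1e-3)

  # single isotropic component peaks at the origin
  iso <- ratio_prior(tibble::tibble(sd_logV = 1, sd_logW = 1,
                                    correlation = 0, weight = 1))
  pts <- expand.grid(x = seq(-1, 1, 0.25), y = seq(-1, 1, 0.25))
  vals <- prior_density(iso, pts$x, pts$y)
  expect_equal(which.max(vals), which(pts$x == 0 & pts$y == 0))
})

test_that("predicted bias matches the closed form on a Gaussian slice", {
  s <- 0.5
  pr <- ratio_prior(tibble::tibble(sd_logV = 1, sd_logW = s,
                                   correlation = 0, weight = 1), C_b = 0.003)
  th <- c(-0.4, -0.1, 0.2, 0.5)
  # b = C_b d/dtheta (1/p^2) with p = dnorm(theta, 0, s); the renormalised
  # slice is exactly this density, so the closed form includes the 2*pi*s^2
  # normalisation factor
  closed <- 0.003 * 2 * pi * s^2 * (2 * th / s^2) * exp(th^2 / s^2)
  expect_equal(predict_bias(pr, rep(0.3, 4), th), closed, tolerance = 1e-6)

  # zero slope at the centre of any symmetric slice
  expect_equal(predict_bias(pr, 0.3, 0), 0)
  expect_equal(predict_bias(fx_ratio_prior(), 0, 0), 0, tolerance = 1e-12)
})

test_that("analytic bias gradient agrees with central finite differences", {
  pr <- fx_ratio_prior()
  fd_bias <- function(x, y, h = 1e-5) {
    p1 <- weightsense:::slice_density_deriv(pr, x, y + h)$p
    p0 <- weightsense:::slice_density_deriv(pr, x, y - h)$p
    pr$C_b * (1 / p1^2 - 1 / p0^2) / (2 * h)
  }
  pts <- expand.grid(x = c(-0.5, -0.1, 0, 0.2, 0.45),
                     y = c(-0.4, -0.05, 0.1, 0.35))
  an <- predict_bias(pr, pts$x, pts$y)
  nu <- mapply(fd_bias, pts$x, pts$y)
  expect_lt(max(abs(an - nu) / pmax(abs(nu), 1e-9)), 1e-6)
})

test_that("bias is odd under joint sign flip for origin-symmetric priors", {
  pr <- fx_ratio_prior()
  pts <- fx_pair_space()
  b1 <- predict_bias(pr, pts$logV_ratio, pts$logW_ratio)
  b2 <- predict_bias(pr, -pts$logV_ratio, -pts$logW_ratio)
  expect_equal(b2, -b1, tolerance = 1e-10)
})

test_that("predicted variance follows the reciprocal-squared-density law", {
  pr <- fx_ratio_prior()
  v <- predict_variance(pr, c(0.2, 0.2), c(0, 0.3), variance_scale = 2)
  p <- weightsense:::slice_density_deriv(pr, c(0.2, 0.2), c(0, 0.3))$p
  expect_equal(v, 2 / p^2)

  # doubling the slice density at a point quarters the predicted variance
  expect_equal(v[1] / v[2], (p[2] / p[1])^2)
  # near-uniform slice (very broad prior): variance ~ constant over stimuli
  flat <- ratio_prior(tibble::tibble(sd_logV = 1, sd_logW = 100,
                                     correlation = 0, weight = 1))
  vf <- predict_variance(flat, rep(0, 5), seq(-0.3, 0.3, length.out = 5))
  expect_lt(diff(range(vf)) / mean(vf), 1e-4)
  # Gaussian slice: variance minimal at the slice centre
  iso <- ratio_prior(tibble::tibble(sd_logV = 1, sd_logW = 0.5,
                                    correlation = 0, weight = 1))
  th <- seq(-0.5, 0.5, 0.1)
  vv <- predict_variance(iso, rep(0, length(th)), th)
  expect_equal(th[which.min(vv)], 0)
  expect_error(predict_variance(iso, 0, 0, variance_scale = 0),
               class = "weightsense_validation_error")
})

test_that("free-parameter counts: 12 for K=3, 4 for K=1", {
  # K components: 3K shape parameters, K-1 free weights, plus C_b
  pr <- fx_ratio_prior()
  expect_equal(pr$n_params, 12L)
  expect_equal(ratio_prior(tibble::tibble(sd_logV = 1, sd_logW = 1,
                                          correlation = 0, weight = 1))$n_params, 4L)
})

test_that("a noiseless single-component bias field is recovered by refitting", {
  gen <- ratio_prior(tibble::tibble(sd_logV = 0.6, sd_logW = 0.7,
                                    correlation = 0.9, weight = 1), C_b = 0.004)
  pts <- fx_pair_space()
  bf <- dplyr::mutate(pts, bias = predict_bias(gen, logV_ratio, logW_ratio))
  fit <- fit_ratio_model(bf, K = 1, n_starts = 8, seed = 2)
  expect_gt(r_squared(bf$bias, fit$predicted), 0.999)
})

test_that("an all-zero bias field yields a near-zero bias scale", {
  pts <- fx_pair_space()
  bf <- dplyr::mutate(pts, bias = 0)
  fit <- fit_ratio_model(bf, K = 1, n_starts = 4, seed = 3)
  expect_lt(max(abs(fit$predicted)), 1e-4)
})

test_that("variance predictions of a prior fitted to descriptive-model biases track volume ratio", {
  st <- fx_small_study()
  bf <- build_bias_field(st$recs, st$sim$cubes)
  fit <- memo("ratio_fit_eq1", fit_ratio_model(bf, K = 3, n_starts = 12, seed = 4))
  # the prior reproduces the bias field well...
  expect_gt(fit$r_squared, 0.9)
  # ...but its variance predictions are organised by log volume ratio, not
  # log weight ratio - the structural mismatch with weight-driven empirical
  # variance patterns
  vs <- fit_variance_scale(fit$prior, bf)
  mv <- predict_variance(fit$prior, bf$logV_ratio, bf$logW_ratio, vs)
  vr <- variance_regressions(bf, variance = mv)
  r2 <- setNames(vr$r_squared, vr$predictors)
  expect_gt(r2[["abs_logV"]], r2[["abs_logW"]])
})

test_that("the single-object model ignores pair context and recovers planted fields", {
  cubes <- fx_cubes()
  gen <- list(mu_logV = log(750), mu_logW = log(400), sd_logV = 0.5,
              sd_logW = 0.6, correlation = 0.85, weight = 1, C_b = 0.002)
  planted <- predict_single_object_bias(gen, log(cubes$volume), log(cubes$weight))
  expect_gt(max(abs(planted)), 0.01) # a non-trivial field

  # two noiseless records per cube with the planted bias applied
  recs <- tibble::tibble(
    participant_id = rep(c("A", "B"), each = nrow(cubes)),
    cube_id = rep(cubes$cube_id, 2),
    normalised = rep(cubes$weight * exp(planted), 2)
  )
  fit <- fit_single_object_model(recs, cubes, K = 1, n_starts = 12, seed = 5)
  expect_gt(r_squared(planted[match(fit$per_cube$cube_id, cubes$cube_id)],
                      fit$per_cube$predicted), 0.95)

  # context invariance: the prediction depends only on the cube itself
  b1 <- predict_single_object_bias(fit, log(750), log(375))
  expect_equal(predict_single_object_bias(fit, rep(log(750), 3), rep(log(375), 3)),
               rep(b1, 3))

  # zero-bias data drive the bias scale to zero
  recs0 <- dplyr::mutate(recs, normalised = rep(cubes$weight, 2))
  fit0 <- fit_single_object_model(recs0, cubes, K = 1, n_starts = 6, seed = 6)
  expect_lt(max(abs(fit0$per_cube$predicted)), 1e-4)
})
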