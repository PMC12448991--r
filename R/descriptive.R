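#' Descriptive-model coefficient set
#'
#' Container for the seven parameters of the descriptive model of perceived
#' weight. For a judged object with weight `w1` (g) and density `d1` (g/cm^3)
#' lifted alongside an object with weight `w2` and density `d2`, perceived
#' weight in grams is
#'
#' \deqn{\hat w_1 = C + \beta_1 w_1 + \beta_2 d_1 + \beta_3 w_2 +
#'       (\beta_4 d_1 + \beta_5 d_2)\, N(|w_1 - w_2|; 0, \sigma^2)}
#'
#' where `N` is the *normalised* Gaussian density (the gate carries units of
#' 1/g, so the gated terms are in grams). The gate magnifies the influence of
#' both objects' densities when the two weights are similar — the regime of
#' classic size-weight-illusion stimuli.
#'
#' @param C Intercept (g).
#' @param beta1 Coefficient on the judged object's weight (dimensionless).
#' @param beta2 Coefficient on the judged object's density (g per g/cm^3).
#' @param beta3 Coefficient on the other object's weight (dimensionless).
#' @param beta4 Gated coefficient on the judged object's density (g^2 per g/cm^3).
#' @param beta5 Gated coefficient on the other object's density (g^2 per g/cm^3).
#' @param sigma SD of the Gaussian weight-difference gate (g); must be > 0.
#' @return A named numeric vector of class `swi_coefficients`.
#' @export
descriptive_coefficients <- function(C = 0, beta1 = 1, beta2 = 0, beta3 = 0,
                                     beta4 = 0, beta5 = 0, sigma = 75) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    abort("sigma must be a single finite value > 0.", class = "weightsense_validation_error")
  }
  vals <- c(C = C, beta1 = beta1, beta2 = beta2, beta3 = beta3,
            beta4 = beta4, beta5 = beta5, sigma = sigma)
  if (any(!is.finite(vals))) {
    abort("All coefficients must be finite.", class = "weightsense_validation_error")
  }
  structure(vals, class = "swi_coefficients")
}

#' Reference coefficient set
#'
#' A reference parameterisation of the descriptive model, representative of
#' adult observers in a visuo-haptic paired cube-lifting task. It is the
#' package default ground truth for simulation and parameter-recovery
#' studies: both objects' weights and the judged object's density raise
#' perceived weight, the other object's density lowers it, and the density
#' terms are gated by a Gaussian over weight difference with SD 76.44 g.
#' The intercept is set to 0.
#'
#' @return A `swi_coefficients` vector: C = 0, beta1 = 1.23, beta2 = 126.43,
#'   beta3 = 0.13, beta4 = 27814, beta5 = -17919, sigma = 76.44.
#' @export
swi_reference_coefficients <- function() {
  descriptive_coefficients(C = 0, beta1 = 1.23, beta2 = 126.43, beta3 = 0.13,
                           beta4 = 27814, beta5 = -17919, sigma = 76.44)
}

#' Gaussian weight-difference gate
#'
#' The normalised Gaussian density with mean 0 and SD `sigma`, evaluated at
#' the absolute weight difference. Maximal at zero weight difference, even in
#' `delta_w`, and carries units of 1/g.
#'
#' @param delta_w Weight difference(s) in grams.
#' @param sigma Gate SD in grams (> 0).
#' @return Numeric vector of densities (1/g).
#' @export
#' @examples
#' weight_gate(0, 76.44) # ~ 0.00522 per gram
weight_gate <- function(delta_w, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    abort("sigma must be a single finite value > 0.", class = "weightsense_validation_error")
  }
  dnorm(abs(delta_w), mean = 0, sd = sigma)
}

#' Predict perceived weight for judged/other object pairs
#'
#' Evaluates the descriptive model. Inputs are vectorised: supply either
#' cube rows (tibbles with `weight`, `density`) or bare numeric vectors.
#'
#' @param w1,d1 Weight (g) and density (g/cm^3) of the judged object.
#' @param w2,d2 Weight and density of the other object in the pair.
#' @param coeffs A [descriptive_coefficients()] vector.
#' @return Predicted perceived weight(s) in grams.
#' @export
predict_weight <- function(w1, d1, w2, d2, coeffs) {
  k <- as.numeric(coeffs)
  names(k) <- names(coeffs)
  g <- weight_gate(w1 - w2, k[["sigma"]])
  k[["C"]] + k[["beta1"]] * w1 + k[["beta2"]] * d1 + k[["beta3"]] * w2 +
    (k[["beta4"]] * d1 + k[["beta5"]] * d2) * g
}

#' Predict perceived weight from cube rows
#'
#' Convenience wrapper over [predict_weight()] taking rows of the cube table.
#'
#' @param judged,other Data frames (recycled row-wise) with `weight`, `density`.
#' @param coeffs A [descriptive_coefficients()] vector.
#' @return Predicted perceived weight(s) in grams.
#' @export
predict_weight_cubes <- function(judged, other, coeffs) {
  predict_weight(judged$weight, judged$density, other$weight, other$density, coeffs)
}

#' Predicted difference in perceived weight
#'
#' The difference form of the descriptive model:
#' \deqn{\hat w_1 - \hat w_2 = (\beta_1 - \beta_3)(w_1 - w_2) +
#'   \beta_2 (d_1 - d_2) + (\beta_4 - \beta_5)(d_1 - d_2)
#'   N(|w_1 - w_2|; 0, \sigma^2)}
#' This is an exact algebraic identity with
#' `predict_weight(w1, d1, w2, d2) - predict_weight(w2, d2, w1, d1)`:
#' the intercept and symmetric terms cancel.
#'
#' @inheritParams predict_weight
#' @return Predicted perceived-weight difference(s), judged minus other, in grams.
#' @export
predict_weight_difference <- function(w1, d1, w2, d2, coeffs) {
  k <- as.numeric(coeffs)
  names(k) <- names(coeffs)
  g <- weight_gate(w1 - w2, k[["sigma"]])
  (k[["beta1"]] - k[["beta3"]]) * (w1 - w2) + k[["beta2"]] * (d1 - d2) +
    (k[["beta4"]] - k[["beta5"]]) * (d1 - d2) * g
}

#' Influence of density on perceived weight as a function of weight difference
#'
#' The effective density coefficients implied by a coefficient set: the judged
#' object's density acts with `beta2 + beta4 * gate(dw)`, the other object's
#' with `beta5 * gate(dw)`. Their combined magnitude shrinks as the weight
#' difference grows, which is why density matters most for equal-weight
#' (size-weight-illusion) pairs.
#'
#' @param coeffs A [descriptive_coefficients()] vector.
#' @param delta_w Weight differences (g) at which to evaluate.
#' @return A tibble with `delta_w`, `judged`, `other`, `combined`
#'   (`abs(judged) + abs(other)`), all in g per (g/cm^3).
#' @export
density_influence <- function(coeffs, delta_w = seq(0, 400, by = 5)) {
  g <- weight_gate(delta_w, coeffs[["sigma"]])
  tibble::tibble(
    delta_w = delta_w,
    judged = coeffs[["beta2"]] + coeffs[["beta4"]] * g,
    other = coeffs[["beta5"]] * g,
    combined = abs(judged) + abs(other)
  )
}

#' Ratio of effective density influence at zero vs large weight difference
#'
#' Summarises the gate's leverage: the summed magnitude of the effective
#' density coefficients at zero weight difference, relative to the asymptotic
#' value (`beta2`) at large weight difference. Approximately 2.9 for the
#' reference coefficient set — density influence is about three times larger
#' for equal-weight pairs than for pairs of very different weight.
#'
#' @param coeffs A [descriptive_coefficients()] vector with `beta2 != 0`.
#' @return A single dimensionless ratio.
#' @export
effective_density_ratio <- function(coeffs) {
  g0 <- weight_gate(0, coeffs[["sigma"]])
  (coeffs[["beta2"]] + (coeffs[["beta4"]] + abs(coeffs[["beta5"]])) * g0) /
    coeffs[["beta2"]]
}

# ---- fitting ---------------------------------------------------------------

descriptive_components <- c("weight_judged", "density_judged", "weight_other",
                            "gated_density_judged", "gated_density_other")

# Attach judged/other physical properties to estimate records.
# Records need `cube_id` and either `other_cube` or `pair_id`.
design_data <- function(records, cubes) {
  if (!"other_cube" %in% names(records)) {
    if (!"pair_id" %in% names(records)) {
      abort("records need an `other_cube` or `pair_id` column.",
            class = "weightsense_validation_error")
    }
    parts <- strsplit(records$pair_id, "|", fixed = TRUE)
    records$other_cube <- purrr::map2_chr(parts, records$cube_id,
                                          ~ setdiff(.x, .y)[1])
  }
  unknown <- setdiff(unique(c(records$cube_id, records$other_cube)), cubes$cube_id)
  if (length(unknown)) {
    abort(paste("Unknown cube ids:", paste(unknown, collapse = ", ")),
          class = "weightsense_validation_error")
  }
  lk <- cubes |> dplyr::select("cube_id", "weight", "density", "volume")
  records |>
    dplyr::left_join(dplyr::rename(lk, w1 = "weight", d1 = "density", v1 = "volume"),
                     by = "cube_id") |>
    dplyr::left_join(dplyr::rename(lk, cube_id2 = "cube_id", w2 = "weight",
                                   d2 = "density", v2 = "volume"),
                     by = c(other_cube = "cube_id2"))
}

# Pick the response column: preprocessed > grams.
response_column <- function(records) {
  for (col in c("normalised", "grams")) if (col %in% names(records)) return(col)
  abort("records carry neither a `normalised` nor a `grams` column; run to_grams()/preprocess_estimates() first.",
        class = "weightsense_validation_error")
}

# Design matrix for a component subset at a given sigma.
# `p1`/`p2` are the density (default) or volume predictors.
design_matrix <- function(dd, components, sigma, predictor = "density") {
  p1 <- if (predictor == "density") dd$d1 else dd$v1
  p2 <- if (predictor == "density") dd$d2 else dd$v2
  cols <- list(C = rep(1, nrow(dd)))
  if ("weight_judged" %in% components) cols$beta1 <- dd$w1
  if ("density_judged" %in% components) cols$beta2 <- p1
  if ("weight_other" %in% components) cols$beta3 <- dd$w2
  gated <- intersect(c("gated_density_judged", "gated_density_other"), components)
  if (length(gated)) {
    g <- weight_gate(dd$w1 - dd$w2, sigma)
    if ("gated_density_judged" %in% gated) cols$beta4 <- p1 * g
    if ("gated_density_other" %in% gated) cols$beta5 <- p2 * g
  }
  do.call(cbind, cols)
}

ssr_at_sigma <- function(sigma, y, dd, components, predictor) {
  X <- design_matrix(dd, components, sigma, predictor)
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit the descriptive model by pooled least squares
#'
#' Minimises the summed squared residuals between the response (normalised
#' estimates in grams) and the model prediction, pooled over all retained
#' records. The model is linear in `(C, beta1..beta5)` for fixed `sigma`, so
#' the fit profiles: a seeded multi-start search over `sigma` in \[1, 1000\] g
#' (log-spaced jittered starts plus Brent refinement around the best
#' candidates), solving the linear coefficients exactly at each `sigma`.
#' Deterministic given `seed`.
#'
#' @param records Estimate records (preprocessed; rows flagged by outlier
#'   removal are dropped automatically).
#' @param cubes Cube table from [build_stimulus_set()].
#' @param components Character vector of model components to include (any of
#'   `weight_judged`, `density_judged`, `weight_other`,
#'   `gated_density_judged`, `gated_density_other`); the intercept is always
#'   present.
#' @param predictor `"density"` (default) or `"volume"`: which inferred/sensed
#'   size-related property enters the non-weight terms.
#' @param n_starts Number of sigma starts for the profiled search.
#' @param seed Integer seed for the start jitter.
#' @param response Optional response column name; defaults to `normalised`
#'   if present, else `grams`.
#' @return An object of class `swi_descriptive_fit` with elements
#'   `coefficients` (a `swi_coefficients` vector; absent components are 0),
#'   `ssr`, `r_squared`, `n`, `components`, `predictor`, `fitted`,
#'   `residuals`, and the `sigma` profile diagnostics.
#' @export
fit_descriptive <- function(records, cubes, components = descriptive_components,
                            predictor = c("density", "volume"),
                            n_starts = 16, seed = 1L, response = NULL) {
  predictor <- match.arg(predictor)
  components <- match.arg(components, descriptive_components, several.ok = TRUE)
  records <- drop_removed(records)
  col <- response %||% response_column(records)
  dd <- design_data(records, cubes)
  y <- dd[[col]]
  if (any(!is.finite(y))) {
    abort("Non-finite response values.", class = "weightsense_validation_error")
  }

  gated <- any(grepl("^gated", components))
  if (!gated) {
    X <- design_matrix(dd, components, sigma = 1, predictor)
    lf <- lm.fit(X, y)
    sigma_hat <- NA_real_
    ssr <- sum(lf$residuals^2)
    est <- lf$coefficients
    profile <- NULL
  } else {
    lo <- 1; hi <- 1000
    starts <- exp(seq(log(2), log(800), length.out = max(n_starts, 2)))
    starts <- withr::with_seed(seed, starts * exp(runif(length(starts), -0.1, 0.1)))
    starts <- pmin(pmax(starts, lo), hi)
    f <- function(s) ssr_at_sigma(s, y, dd, components, predictor)
    vals <- vapply(starts, f, numeric(1))
    ord <- order(vals)
    best <- list(objective = Inf, minimum = starts[ord[1]])
    for (j in head(ord, 3)) {
      lo_j <- if (j == 1) lo else starts[j - 1]
      hi_j <- if (j == length(starts)) hi else starts[j + 1]
      opt <- optimize(f, c(lo_j, hi_j), tol = 1e-6)
      if (opt$objective < best$objective) best <- opt
    }
    sigma_hat <- best$minimum
    if (sigma_hat < lo * 1.01 || sigma_hat > hi * 0.99) {
      warn("Fitted sigma is pinned near its bound [1, 1000] g.")
    }
    X <- design_matrix(dd, components, sigma_hat, predictor)
    lf <- lm.fit(X, y)
    ssr <- sum(lf$residuals^2)
    est <- lf$coefficients
    profile <- tibble::tibble(sigma = starts, ssr = vals)
  }
  est[is.na(est)] <- 0

  full <- c(C = 0, beta1 = 0, beta2 = 0, beta3 = 0, beta4 = 0, beta5 = 0)
  full[names(est)] <- est
  coeffs <- descriptive_coefficients(
    C = full[["C"]], beta1 = full[["beta1"]], beta2 = full[["beta2"]],
    beta3 = full[["beta3"]], beta4 = full[["beta4"]], beta5 = full[["beta5"]],
    sigma = if (is.na(sigma_hat)) 1 else sigma_hat
  )
  sst <- sum((y - mean(y))^2)
  structure(list(
    coefficients = coeffs,
    sigma = sigma_hat,
    components = components,
    predictor = predictor,
    ssr = ssr,
    r_squared = 1 - ssr / sst,
    n = length(y),
    n_params = length(components) + 1L + as.integer(gated),
    fitted = y - lf$residuals,
    residuals = lf$residuals,
    response = col,
    sigma_profile = profile
  ), class = "swi_descriptive_fit")
}

#' @export
print.swi_descriptive_fit <- function(x, ...) {
  cat("Descriptive model of perceived weight (", x$predictor, " predictor)\n", sep = "")
  cat("  components:", paste(x$components, collapse = ", "), "\n")
  print(round(unclass(x$coefficients), 4))
  cat(sprintf("  n = %d records, SSR = %.4g g^2, R^2 = %.4f\n", x$n, x$ssr, x$r_squared))
  invisible(x)
}

# Predict from a fitted (possibly reduced) model on new design rows.
predict_fit_rows <- function(fit, dd) {
  k <- fit$coefficients
  p1 <- if (fit$predictor == "density") dd$d1 else dd$v1
  p2 <- if (fit$predictor == "density") dd$d2 else dd$v2
  g <- if (any(grepl("^gated", fit$components))) {
    weight_gate(dd$w1 - dd$w2, k[["sigma"]])
  } else 0
  k[["C"]] + k[["beta1"]] * dd$w1 + k[["beta2"]] * p1 + k[["beta3"]] * dd$w2 +
    (k[["beta4"]] * p1 + k[["beta5"]] * p2) * g
}

#' Greedy component ladder
#'
#' Forward selection over the five model components, starting from the
#' intercept-only model: at each step the component whose addition maximises
#' the gain in R^2 (refitting all active parameters, including `sigma` once a
#' gated component is active) is added. Ties are broken by the fixed
#' component order (weight of judged object, density of judged object, weight
#' of other object, gated density of judged object, gated density of other
#' object), with a warning.
#'
#' @inheritParams fit_descriptive
#' @param tie_tol Relative SSR difference below which two candidate gains are
#'   considered tied.
#' @return A tibble of class `swi_component_ladder` with one row per step:
#'   `step`, `component`, `r_squared`, `ssr`. R^2 is non-decreasing and SSR
#'   non-increasing along the ladder; the final row matches the full fit.
#' @export
component_ladder <- function(records, cubes, predictor = c("density", "volume"),
                             n_starts = 16, seed = 1L, response = NULL,
                             tie_tol = 1e-9) {
  predictor <- match.arg(predictor)
  records <- drop_removed(records)
  col <- response %||% response_column(records)
  active <- character(0)
  remaining <- descriptive_components
  out <- list()
  step <- 0L
  while (length(remaining)) {
    step <- step + 1L
    fits <- purrr::map(remaining, function(comp) {
      fit_descriptive(records, cubes, components = c(active, comp),
                      predictor = predictor, n_starts = n_starts,
                      seed = derive_seed(seed, step), response = col)
    })
    ssrs <- purrr::map_dbl(fits, "ssr")
    best <- which.min(ssrs)
    near <- which(ssrs <= ssrs[best] * (1 + tie_tol))
    if (length(near) > 1) {
      warn("Tie in R^2 gain; broken by fixed component order.")
      best <- near[1]
    }
    active <- c(active, remaining[best])
    out[[step]] <- tibble::tibble(
      step = step, component = remaining[best],
      r_squared = fits[[best]]$r_squared, ssr = fits[[best]]$ssr
    )
    remaining <- remaining[-best]
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("swi_component_ladder", class(res))
  res
}

#' Leave-one-participant-out cross-validation of model variants
#'
#' For each model variant, fits on all participants but one and accumulates
#' the summed squared prediction error on the held-out participant's records,
#' across all folds. Variants cover the full model, the linear (ungated)
#' reduction, and the volume-instead-of-density forms of both.
#'
#' @inheritParams fit_descriptive
#' @param variants Named list of variant specifications, each a list with
#'   `components` and `predictor`; or a character vector naming built-in
#'   variants (`"full"`, `"linear"`, `"volume_full"`, `"volume_linear"`).
#' @return A tibble with `variant`, `n_params`, `cv_error` (summed held-out
#'   SSR, g^2), `folds`, sorted by `cv_error`. Variants failing to fit in any
#'   fold are flagged (`converged = FALSE`) and excluded from the ranking
#'   order (placed last).
#' @export
loo_cv_descriptive <- function(records, cubes,
                               variants = c("full", "linear", "volume_full", "volume_linear"),
                               n_starts = 8, seed = 1L, response = NULL) {
  if (is.character(variants)) {
    builtin <- list(
      full = list(components = descriptive_components, predictor = "density"),
      linear = list(components = descriptive_components[1:3], predictor = "density"),
      volume_full = list(components = descriptive_components, predictor = "volume"),
      volume_linear = list(components = descriptive_components[1:3], predictor = "volume")
    )
    variants <- builtin[match.arg(variants, names(builtin), several.ok = TRUE)]
  }
  records <- drop_removed(records)
  col <- response %||% response_column(records)
  parts <- unique(records$participant_id)
  if (length(parts) < 3) {
    abort("Need at least 3 participants for leave-one-out cross-validation.",
          class = "weightsense_validation_error")
  }
  dd_all <- design_data(records, cubes)

  res <- purrr::imap(variants, function(v, nm) {
    errs <- rep(NA_real_, length(parts))
    npar <- NA_integer_
    ok <- TRUE
    for (i in seq_along(parts)) {
      train <- records[records$participant_id != parts[i], ]
      test_dd <- dd_all[dd_all$participant_id == parts[i], ]
      fit <- tryCatch(
        fit_descriptive(train, cubes, components = v$components,
                        predictor = v$predictor, n_starts = n_starts,
                        seed = derive_seed(seed, i), response = col),
        error = function(e) NULL
      )
      if (is.null(fit)) { ok <- FALSE; break }
      npar <- fit$n_params
      errs[i] <- sum((test_dd[[col]] - predict_fit_rows(fit, test_dd))^2)
    }
    tibble::tibble(variant = nm, n_params = npar,
                   cv_error = if (ok) sum(errs) else NA_real_,
                   folds = length(parts), converged = ok)
  })
  dplyr::bind_rows(res) |>
    dplyr::arrange(dplyr::desc(.data$converged), .data$cv_error)
}

# Drop records flagged by outlier removal.
drop_removed <- function(records) {
  if ("outlier_pass" %in% names(records)) {
    records <- records[is.na(records$outlier_pass), ]
  }
  records
}
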