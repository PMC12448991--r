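#' Three-sub-prior Bayesian mixture model
#'
#' A Bayesian observer over (log volume ratio, log weight ratio) whose prior
#' is a mixture of three origin-centred "ridge" Gaussians, each encoding a
#' categorical volume-weight relationship (e.g., equal density; smaller is
#' denser and heavier; smaller is much lighter). A component with ridge slope
#' `a` has its long axis along the direction `(1, a)`, with `sd_along` along
#' the ridge and `sd_across` (< `sd_along`) across it. Sensory evidence is a
#' Gaussian likelihood centred on the true log ratios with SDs
#' `noise_logW` and `noise_logV` (volume noise near zero mirrors the
#' precise-volume assumption of the ratio model).
#'
#' @param slopes Numeric length-3: ridge slopes of the components.
#' @param sd_along,sd_across Length-3: along- and across-ridge SDs (> 0,
#'   `sd_across < sd_along`).
#' @param weights Length-3 mixture weights (normalised to sum to 1).
#' @param noise_logW,noise_logV Sensory noise SDs (> 0).
#' @return A list of class `swi_subprior_model`.
#' @export
subprior_model <- function(slopes = c(1, -3, 3),
                           sd_along = c(1, 1, 1),
                           sd_across = c(0.1, 0.1, 0.1),
                           weights = c(1, 1, 1) / 3,
                           noise_logW = 0.2, noise_logV = 0.01) {
  stopifnot(length(slopes) == length(sd_along),
            length(slopes) == length(sd_across),
            length(slopes) == length(weights))
  if (any(sd_along <= 0) || any(sd_across <= 0) || noise_logW <= 0 || noise_logV <= 0) {
    abort("SDs must be > 0.", class = "weightsense_validation_error")
  }
  if (any(sd_across >= sd_along)) {
    abort("Each sub-prior must be a ridge: sd_across < sd_along.",
          class = "weightsense_validation_error")
  }
  if (any(weights < 0) || abs(sum(weights)) == 0) {
    abort("weights must be non-negative and not all zero.",
          class = "weightsense_validation_error")
  }
  structure(list(slopes = slopes, sd_along = sd_along, sd_across = sd_across,
                 weights = weights / sum(weights),
                 noise_logW = noise_logW, noise_logV = noise_logV),
            class = "swi_subprior_model")
}

# 2x2 covariance of ridge component k
subprior_cov <- function(model, k) {
  u <- c(1, model$slopes[k]) / sqrt(1 + model$slopes[k]^2)
  nvec <- c(-u[2], u[1])
  model$sd_along[k]^2 * tcrossprod(u) + model$sd_across[k]^2 * tcrossprod(nvec)
}

#' Posterior prediction of the sub-prior model
#'
#' For evidence at the true (log volume ratio, log weight ratio), computes
#' the posterior over the true log weight ratio under the mixture prior with
#' Gaussian likelihood, in closed form (Gaussian conjugacy per component):
#' component responsibilities are proportional to the mixture weight times
#' the marginal likelihood, and each component's posterior mean is
#' `Sigma_prior (Sigma_prior + Sigma_noise)^-1 m`. Returns the
#' posterior-mean log weight ratio minus the true value (the predicted bias),
#' with responsibilities and posterior means as attributes.
#'
#' @param model A [subprior_model()].
#' @param logV,logW True log volume and weight ratios (vectorised).
#' @return Numeric vector of predicted biases; attributes `responsibility`
#'   (n x K matrix) and `posterior_logW`.
#' @export
subprior_predict <- function(model, logV, logW) {
  n <- max(length(logV), length(logW))
  logV <- rep_len(logV, n); logW <- rep_len(logW, n)
  K <- length(model$slopes)
  Sn <- diag(c(model$noise_logV^2, model$noise_logW^2))
  gains <- list(); margs <- list()
  for (k in seq_len(K)) {
    Sp <- subprior_cov(model, k)
    gains[[k]] <- Sp %*% solve(Sp + Sn)
    margs[[k]] <- Sp + Sn
  }
  resp <- matrix(NA_real_, n, K)
  post_y <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    S <- margs[[k]]
    det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
    Sinv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) / det_s
    q <- Sinv[1, 1] * logV^2 + 2 * Sinv[1, 2] * logV * logW + Sinv[2, 2] * logW^2
    resp[, k] <- model$weights[k] * exp(-q / 2) / (2 * pi * sqrt(det_s))
    post_y[, k] <- gains[[k]][2, 1] * logV + gains[[k]][2, 2] * logW
  }
  resp <- resp / rowSums(resp)
  est <- rowSums(resp * post_y)
  out <- est - logW
  attr(out, "responsibility") <- resp
  attr(out, "posterior_logW") <- est
  out
}

#' Fit the sub-prior model to a bias field
#'
#' Least-squares fit of the sub-prior parameters (3 slopes, 3 along-ridge
#' SDs, 3 across-ridge log SD ratios, 2 mixture logits, 1 weight-noise SD;
#' volume noise held fixed and small) to the empirical per-pair biases in
#' log weight ratio, with seeded multi-start.
#'
#' @param bias_field Tibble from [build_bias_field()].
#' @param n_starts,seed Multi-start control.
#' @param noise_logV Fixed sensory SD for the (precise) volume ratio.
#' @return A list of class `swi_subprior_fit`: `model`, `predicted`, `ssr`,
#'   `r_squared` (NA with a message when the bias field is constant),
#'   `n_params`.
#' @export
fit_subprior_model <- function(bias_field, n_starts = 16, seed = 1L,
                               noise_logV = 0.01) {
  x <- bias_field$logV_ratio; y <- bias_field$logW_ratio; b <- bias_field$bias
  # theta: slopes (3), log sd_along (3), log(sd_across/sd_along) (3, < 0),
  # weight logits (2), log noise_logW
  make_model <- function(theta) {
    subprior_model(
      slopes = theta[1:3],
      sd_along = exp(theta[4:6]),
      sd_across = exp(theta[4:6] + theta[7:9]),
      weights = { w <- exp(c(theta[10:11], 0)); w / sum(w) },
      noise_logW = exp(theta[12]), noise_logV = noise_logV
    )
  }
  obj <- function(theta) {
    m <- tryCatch(make_model(theta), error = function(e) NULL)
    if (is.null(m)) return(1e12)
    pred <- as.numeric(subprior_predict(m, x, y))
    if (any(!is.finite(pred))) return(1e12)
    sum((b - pred)^2)
  }
  lower <- c(rep(-10, 3), rep(log(0.05), 3), rep(-6, 3), rep(-6, 2), log(0.01))
  upper <- c(rep(10, 3), rep(log(10), 3), rep(-0.05, 3), rep(6, 2), log(2))
  starts <- withr::with_seed(seed, purrr::map(seq_len(n_starts), function(i) {
    c(c(1, -3, 3) + rnorm(3, 0, 0.5), log(runif(3, 0.5, 2)),
      log(runif(3, 0.05, 0.5)), rnorm(2, 0, 0.5), log(runif(1, 0.05, 0.5)))
  }))
  best <- NULL
  for (theta0 in starts) {
    res <- tryCatch(optim(theta0, obj, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    abort("All starts failed to converge.", class = "weightsense_fit_error")
  }
  model <- make_model(best$par)
  pred <- as.numeric(subprior_predict(model, x, y))
  sst <- sum((b - mean(b))^2)
  structure(list(model = model, predicted = pred, ssr = best$value,
                 r_squared = if (sst > 0) 1 - best$value / sst else NA_real_,
                 n_params = 12L, bias_field = bias_field),
            class = "swi_subprior_fit")
}

# ---- cue combination -------------------------------------------------------

#' Cue-combination model parameters
#'
#' Perceived weight as a combination of power functions of the judged
#' object's weight and density: `w_hat = beta1 * w^x + beta2 * d^y`. The
#' model depends only on the judged object — it is contextually invariant by
#' construction.
#'
#' @param beta1,beta2 Scales on the weight and density terms.
#' @param x,y Exponents (> 0).
#' @return A list of class `swi_cue_params`.
#' @export
cue_combination_params <- function(beta1 = 1, beta2 = 0, x = 1, y = 1) {
  if (x <= 0 || y <= 0) {
    abort("Exponents must be > 0.", class = "weightsense_validation_error")
  }
  structure(list(beta1 = beta1, beta2 = beta2, x = x, y = y),
            class = "swi_cue_params")
}

#' Predict perceived weight under the cue-combination model
#'
#' @param params A [cue_combination_params()].
#' @param w,d Weight (g) and density (g/cm^3) of the judged object.
#' @return Predicted perceived weight (g); independent of any paired object.
#' @export
predict_cue_combination <- function(params, w, d) {
  params$beta1 * w^params$x + params$beta2 * d^params$y
}

#' Fit the cue-combination model
#'
#' Nonlinear least squares on single-object predictions. For fixed exponents
#' the model is linear in `(beta1, beta2)`, so the fit profiles: a bounded
#' 2-D search over `(x, y)` (seeded multi-start L-BFGS-B) with the scales
#' solved exactly at each step.
#'
#' @param records Preprocessed estimate records.
#' @param cubes Cube table.
#' @param n_starts,seed Multi-start control.
#' @param bounds Exponent bounds (applies to both x and y).
#' @return A list of class `swi_cue_fit`: `params`, `ssr`, `r_squared`, `n`,
#'   `n_params`, `fitted`.
#' @export
fit_cue_combination <- function(records, cubes, n_starts = 8, seed = 1L,
                                bounds = c(0.2, 4)) {
  records <- drop_removed(records)
  col <- response_column(records)
  dd <- design_data(records, cubes)
  yresp <- dd[[col]]
  lin <- function(xy) {
    X <- cbind(b1 = dd$w1^xy[1], b2 = dd$d1^xy[2])
    f <- lm.fit(X, yresp)
    list(ssr = sum(f$residuals^2), coef = f$coefficients, fitted = yresp - f$residuals)
  }
  obj <- function(xy) lin(xy)$ssr
  starts <- withr::with_seed(seed, purrr::map(seq_len(n_starts), function(i) {
    exp(runif(2, log(0.5), log(2)))
  }))
  best <- NULL
  for (xy0 in starts) {
    res <- tryCatch(optim(xy0, obj, method = "L-BFGS-B",
                          lower = rep(bounds[1], 2), upper = rep(bounds[2], 2)),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) abort("Fit failed.", class = "weightsense_fit_error")
  if (any(abs(best$par - bounds[1]) < 1e-6) || any(abs(best$par - bounds[2]) < 1e-6)) {
    warn("Cue-combination exponent at bound.")
  }
  sol <- lin(best$par)
  cf <- sol$coef; cf[is.na(cf)] <- 0
  sst <- sum((yresp - mean(yresp))^2)
  structure(list(
    params = cue_combination_params(cf[["b1"]], cf[["b2"]], best$par[1], best$par[2]),
    ssr = sol$ssr, r_squared = 1 - sol$ssr / sst, n = length(yresp),
    n_params = 4L, fitted = sol$fitted
  ), class = "swi_cue_fit")
}
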