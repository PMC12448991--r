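#' Mixture-of-Gaussians prior over log ratios
#'
#' The efficient-coding ratio model assumes observers hold a prior over the
#' two-dimensional stimulus space (log volume ratio, log weight ratio) of an
#' object pair, modelled as a mixture of `K` bivariate Gaussians all centred
#' on the origin (equal weight, equal volume). Under efficient coding with an
#' L2 loss, perceptual estimates are repelled from the prior peak: the bias
#' at a stimulus is proportional to the slope of the squared reciprocal of
#' the (slice through the) prior, with proportionality constant `C_b`.
#'
#' For `K = 3` the model has 12 free parameters: 3 shape parameters per
#' component (two SDs and a correlation), 2 free mixture weights, and `C_b`.
#'
#' @param components A data frame with one row per component and columns
#'   `sd_logV`, `sd_logW` (> 0), `correlation` (in (-1, 1)), `weight`
#'   (mixture weights, normalised to sum to 1).
#' @param C_b Bias scale constant (dimensionless).
#' @param density_floor Small positive floor on the prior density, keeping
#'   `1/p^2` finite; never active for stimuli inside the design range.
#' @return A list of class `swi_ratio_prior`.
#' @export
ratio_prior <- function(components, C_b = 1, density_floor = 1e-12) {
  components <- tibble::as_tibble(components)
  need <- c("sd_logV", "sd_logW", "correlation", "weight")
  if (!all(need %in% names(components))) {
    abort(paste("components needs columns:", paste(need, collapse = ", ")),
          class = "weightsense_validation_error")
  }
  if (any(components$sd_logV <= 0) || any(components$sd_logW <= 0)) {
    abort("Component SDs must be > 0.", class = "weightsense_validation_error")
  }
  if (any(abs(components$correlation) >= 1)) {
    abort("Correlations must lie in (-1, 1).", class = "weightsense_validation_error")
  }
  if (any(components$weight <= 0)) {
    abort("Mixture weights must be > 0.", class = "weightsense_validation_error")
  }
  components$weight <- components$weight / sum(components$weight)
  structure(list(components = components, C_b = C_b,
                 density_floor = density_floor,
                 n_params = 3L * nrow(components) + (nrow(components) - 1L) + 1L),
            class = "swi_ratio_prior")
}

# zero-mean bivariate Gaussian density
bvn_density <- function(x, y, sx, sy, rho) {
  z <- (x / sx)^2 - 2 * rho * (x / sx) * (y / sy) + (y / sy)^2
  exp(-z / (2 * (1 - rho^2))) / (2 * pi * sx * sy * sqrt(1 - rho^2))
}

#' Prior density over (log volume ratio, log weight ratio)
#'
#' @param prior A [ratio_prior()].
#' @param logV,logW Coordinates (vectorised).
#' @return Mixture density values, floored at `density_floor`. Symmetric
#'   under joint sign flip of both coordinates (components are origin-centred).
#' @export
prior_density <- function(prior, logV, logW) {
  cmp <- prior$components
  d <- 0
  for (k in seq_len(nrow(cmp))) {
    d <- d + cmp$weight[k] *
      bvn_density(logV, logW, cmp$sd_logV[k], cmp$sd_logW[k], cmp$correlation[k])
  }
  pmax(d, prior$density_floor)
}

# density and derivative of the renormalised conditional slice
# p(logW | logV) at theta; fully vectorised over (logV, theta) pairs.
# The conditional of a zero-mean Gaussian mixture is itself a mixture with
# weights a_k ~ w_k N(logV; 0, sdV_k), means rho_k sdW_k/sdV_k logV and
# SDs sdW_k sqrt(1 - rho_k^2).
slice_density_deriv <- function(prior, logV, theta) {
  cmp <- prior$components
  slice_pd(logV, theta, cmp$sd_logV, cmp$sd_logW, cmp$correlation, cmp$weight)
}

# vector-kernel version used in optimisation hot loops (no tibble handling)
slice_pd <- function(logV, theta, sdV, sdW, rho, w) {
  n <- max(length(logV), length(theta))
  logV <- rep_len(logV, n); theta <- rep_len(theta, n)
  K <- length(sdV)
  p <- numeric(n); dp <- numeric(n)
  a <- matrix(0, n, K)
  for (k in seq_len(K)) a[, k] <- w[k] * dnorm(logV, 0, sdV[k])
  tot <- rowSums(a)
  if (any(tot <= 0)) {
    abort("Slice density underflow.", class = "weightsense_validation_error")
  }
  for (k in seq_len(K)) {
    ak <- a[, k] / tot
    mk <- rho[k] * sdW[k] / sdV[k] * logV
    sk <- sdW[k] * sqrt(1 - rho[k]^2)
    phi <- dnorm(theta, mk, sk)
    p <- p + ak * phi
    dp <- dp - ak * phi * (theta - mk) / sk^2
  }
  list(p = p, dp = dp)
}

#' Predicted repulsion bias in log weight ratio
#'
#' Perceptual estimates of volume ratio are treated as precise, so the
#' relevant prior is the one-dimensional conditional slice through the 2-D
#' prior at the true log volume ratio, renormalised to a proper density
#' `p(theta)`. The predicted bias at the true log weight ratio `theta0` is
#' the likelihood-repulsion law
#' \deqn{b(\theta_0) = C_b \left(\frac{1}{p(\theta)^2}\right)'\Big|_{\theta_0}
#'      = -2 C_b \frac{p'(\theta_0)}{p(\theta_0)^3}.}
#' The derivative is computed analytically from the Gaussian mixture. Zero at
#' the slice centre of a symmetric slice; odd under joint sign flip of
#' `(logV, logW)` for the origin-symmetric prior.
#'
#' @param prior A [ratio_prior()].
#' @param logV,logW True log volume and log weight ratios (vectorised).
#' @return Predicted bias in log weight ratio (dimensionless).
#' @export
predict_bias <- function(prior, logV, logW) {
  sd <- slice_density_deriv(prior, logV, logW)
  if (any(sd$p <= prior$density_floor)) {
    abort("Slice density at or below floor: stimulus outside prior support.",
          class = "weightsense_validation_error")
  }
  -2 * prior$C_b * sd$dp / sd$p^3
}

#' Predicted response variance from the prior
#'
#' Efficient coding ties precision to prior density: discrimination
#' thresholds are proportional to the reciprocal of the prior, so response
#' variance is proportional to `1 / p(theta)^2` on the conditional slice.
#'
#' @inheritParams predict_bias
#' @param variance_scale Global scale factor (> 0).
#' @return Predicted variance of the log weight-ratio estimate.
#' @export
predict_variance <- function(prior, logV, logW, variance_scale = 1) {
  if (variance_scale <= 0) {
    abort("variance_scale must be > 0.", class = "weightsense_validation_error")
  }
  p <- slice_density_deriv(prior, logV, logW)$p
  capped <- p <= prior$density_floor
  if (any(capped)) {
    warn("Slice density at floor for some stimuli; variance capped.")
    p[capped] <- prior$density_floor
  }
  variance_scale / p^2
}

#' Least-squares variance scale for a fitted prior
#'
#' Fits the single global `variance_scale` mapping `1/p^2` to the empirical
#' per-pair response variances, by least squares through the origin.
#'
#' @param prior A [ratio_prior()].
#' @param bias_field A bias field from [build_bias_field()] with
#'   `response_variance`.
#' @return The fitted scale (dimensionless).
#' @export
fit_variance_scale <- function(prior, bias_field) {
  ok <- is.finite(bias_field$response_variance)
  x <- predict_variance(prior, bias_field$logV_ratio[ok], bias_field$logW_ratio[ok], 1)
  sum(bias_field$response_variance[ok] * x) / sum(x^2)
}

# ---- fitting the ratio model ----------------------------------------------

# parameter vector <-> prior. theta layout per component: log sdV, log sdW,
# atanh rho; then K-1 weight logits; then C_b.
theta_to_prior <- function(theta, K, density_floor = 1e-12) {
  m <- matrix(theta[seq_len(3 * K)], nrow = K, byrow = TRUE)
  wfree <- theta[3 * K + seq_len(K - 1)]
  w <- exp(c(wfree, 0)); w <- w / sum(w)
  ratio_prior(
    tibble::tibble(sd_logV = exp(m[, 1]), sd_logW = exp(m[, 2]),
                   correlation = tanh(m[, 3]), weight = w),
    C_b = theta[3 * K + K], density_floor = density_floor
  )
}

ratio_start_grid <- function(K, n_starts, seed) {
  # starts around ridge-like priors (strong logV-logW association), jittered
  withr::with_seed(seed, purrr::map(seq_len(n_starts), function(i) {
    sdv <- exp(runif(K, log(0.2), log(1.5)))
    sdw <- sdv * exp(runif(K, -0.3, 0.3))
    rho <- tanh(rnorm(K, 1.2, 0.6))
    c(rbind(log(sdv), log(sdw), atanh(rho)), rnorm(K - 1, 0, 0.5),
      rnorm(1, 0, 0.01))
  }))
}

#' Fit the efficient-coding ratio model to a bias field
#'
#' Minimises the summed squared difference between empirical per-pair biases
#' in log weight ratio and the repulsion-law predictions, over the prior's
#' free parameters (12 for `K = 3`). Bounded quasi-Newton optimisation on an
#' unconstrained reparameterisation (log SDs, atanh correlations, weight
#' logits), with seeded multi-start; best SSR wins.
#'
#' @param bias_field Tibble from [build_bias_field()] (one row per unique
#'   pair, with `logV_ratio`, `logW_ratio`, `bias`).
#' @param K Number of mixture components (1-5; 3 by default).
#' @param n_starts Number of seeded starts.
#' @param seed Integer seed.
#' @param density_floor Floor on the prior density.
#' @return A list of class `swi_ratio_fit`: `prior`, `ssr`, `r_squared`,
#'   `n_params`, `predicted`, `bias_field`, `convergence` diagnostics.
#' @export
fit_ratio_model <- function(bias_field, K = 3, n_starts = 16, seed = 1L,
                            density_floor = 1e-12) {
  stopifnot(K >= 1, K <= 5)
  x <- bias_field$logV_ratio
  y <- bias_field$logW_ratio
  b <- bias_field$bias
  obj <- function(theta) {
    m <- matrix(theta[seq_len(3 * K)], nrow = K, byrow = TRUE)
    w <- exp(c(theta[3 * K + seq_len(K - 1)], 0))
    sd <- slice_pd(x, y, exp(m[, 1]), exp(m[, 2]), tanh(m[, 3]), w / sum(w))
    if (any(sd$p <= density_floor)) return(1e12)
    pred <- -2 * theta[3 * K + K] * sd$dp / sd$p^3
    if (any(!is.finite(pred))) return(1e12)
    sum((b - pred)^2)
  }
  np <- 3 * K + (K - 1) + 1
  lower <- rep(-Inf, np); upper <- rep(Inf, np)
  sd_idx <- c(outer(c(1, 2), 3 * (seq_len(K) - 1), "+"))
  lower[sd_idx] <- log(0.02); upper[sd_idx] <- log(10)
  rho_idx <- 3 * seq_len(K)
  lower[rho_idx] <- atanh(-0.999); upper[rho_idx] <- atanh(0.999)

  best <- NULL
  fails <- 0L
  for (theta0 in ratio_start_grid(K, n_starts, seed)) {
    res <- tryCatch(
      optim(theta0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 400)),
      error = function(e) NULL
    )
    if (is.null(res)) { fails <- fails + 1L; next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort(sprintf("All %d starts failed to converge.", n_starts),
          class = "weightsense_fit_error")
  }
  prior <- theta_to_prior(best$par, K, density_floor)
  small_sd <- prior$components$sd_logV < 0.021 | prior$components$sd_logW < 0.021
  if (any(small_sd)) warn("Degenerate mixture component: SD at lower bound.")
  pred <- predict_bias(prior, x, y)
  sst <- sum((b - mean(b))^2)
  structure(list(prior = prior, ssr = best$value,
                 r_squared = if (sst > 0) 1 - best$value / sst else NA_real_,
                 n_params = prior$n_params, predicted = pred,
                 bias_field = bias_field,
                 convergence = list(code = best$convergence, failed_starts = fails)),
            class = "swi_ratio_fit")
}

#' @export
print.swi_ratio_fit <- function(x, ...) {
  cat(sprintf("Efficient-coding ratio model: K = %d, %d free parameters\n",
              nrow(x$prior$components), x$n_params))
  print(round(as.data.frame(x$prior$components), 4))
  cat(sprintf("  C_b = %.4g, SSR = %.4g, R^2 = %.4f\n",
              x$prior$C_b, x$ssr, x$r_squared))
  invisible(x)
}

# ---- single-object variant -------------------------------------------------

so_theta_to_prior <- function(theta, K) {
  m <- matrix(theta[seq_len(5 * K)], nrow = K, byrow = TRUE)
  wfree <- if (K > 1) theta[5 * K + seq_len(K - 1)] else numeric(0)
  w <- exp(c(wfree, 0)); w <- w / sum(w)
  list(mu_logV = m[, 1], mu_logW = m[, 2], sd_logV = exp(m[, 3]),
       sd_logW = exp(m[, 4]), correlation = tanh(m[, 5]), weight = w,
       C_b = theta[5 * K + K])
}

so_slice <- function(pr, logV, theta) {
  K <- length(pr$weight)
  n <- max(length(logV), length(theta))
  logV <- rep_len(logV, n); theta <- rep_len(theta, n)
  a <- outer(logV, seq_len(K),
             function(x, k) pr$weight[k] * dnorm(x, pr$mu_logV[k], pr$sd_logV[k]))
  a <- a / rowSums(a)
  m <- outer(logV, seq_len(K), function(x, k) {
    pr$mu_logW[k] + pr$correlation[k] * pr$sd_logW[k] / pr$sd_logV[k] * (x - pr$mu_logV[k])
  })
  s <- rep(pr$sd_logW * sqrt(1 - pr$correlation^2), each = n)
  phi <- dnorm(theta - m, 0, s)
  dim(phi) <- dim(m)
  z <- (theta - m) / matrix(s, n)^2
  list(p = rowSums(a * phi), dp = rowSums(-a * phi * z))
}

#' Predicted single-object bias in log perceived weight
#'
#' The single-object efficient-coding model holds a prior over the absolute
#' (log volume, log weight) of individual objects (component means free: the
#' single-object space is not origin-centred) and predicts bias in each
#' object's log perceived weight by the same repulsion law, on the slice at
#' the object's log volume. By construction the prediction for a cube does
#' not depend on what it is paired with — the model cannot produce contextual
#' effects.
#'
#' @param model A fitted object from [fit_single_object_model()] or its
#'   `prior` element.
#' @param logV,logW Log volume (cm^3) and log weight (g) of single objects.
#' @return Predicted bias in log perceived weight.
#' @export
predict_single_object_bias <- function(model, logV, logW) {
  pr <- if (!is.null(model$prior)) model$prior else model
  sd <- so_slice(pr, logV, logW)
  -2 * pr$C_b * sd$dp / pmax(sd$p, 1e-12)^3
}

#' Fit the single-object efficient-coding model
#'
#' Applies the efficient-coding machinery in absolute (log volume, log
#' weight) space. The empirical target is the per-cube mean bias in log
#' perceived weight, `mean(log(normalised estimate)) - log(true weight)`,
#' pooling every record of that cube regardless of its pair context.
#'
#' @param records Preprocessed estimate records.
#' @param cubes Cube table.
#' @param K Number of mixture components (1 by default: 6 free parameters
#'   against 15 per-cube biases).
#' @param n_starts,seed Multi-start control.
#' @return A list of class `swi_single_object_fit`: `prior` (with free
#'   means), `per_cube` (observed and predicted bias per cube), `ssr`,
#'   `r_squared`, `n_params`.
#' @export
fit_single_object_model <- function(records, cubes, K = 1, n_starts = 16,
                                    seed = 1L) {
  records <- drop_removed(records)
  col <- response_column(records)
  per_cube <- records |>
    dplyr::left_join(cubes[, c("cube_id", "volume", "weight")], by = "cube_id") |>
    dplyr::summarise(bias = mean(log(.data[[col]]) - log(.data$weight)),
                     logV = log(.data$volume[1]), logW = log(.data$weight[1]),
                     .by = "cube_id")
  x <- per_cube$logV; y <- per_cube$logW; b <- per_cube$bias
  obj <- function(theta) {
    pr <- so_theta_to_prior(theta, K)
    pred <- tryCatch(predict_single_object_bias(pr, x, y), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e12)
    sum((b - pred)^2)
  }
  np <- 5 * K + (K - 1) + 1
  starts <- withr::with_seed(seed, purrr::map(seq_len(n_starts), function(i) {
    c(rbind(mean(x) + rnorm(K, 0, 0.3), mean(y) + rnorm(K, 0, 0.3),
            log(exp(runif(K, log(0.2), log(1)))),
            log(exp(runif(K, log(0.2), log(1)))),
            atanh(tanh(rnorm(K, 1, 0.5)))),
      if (K > 1) rnorm(K - 1, 0, 0.5) else NULL, rnorm(1, 0, 0.01))
  }))
  lower <- rep(-Inf, np); upper <- rep(Inf, np)
  for (k in seq_len(K)) {
    lower[5 * (k - 1) + c(3, 4)] <- log(0.02)
    upper[5 * (k - 1) + c(3, 4)] <- log(10)
    lower[5 * (k - 1) + 5] <- atanh(-0.999)
    upper[5 * (k - 1) + 5] <- atanh(0.999)
  }
  best <- NULL
  for (theta0 in starts) {
    res <- tryCatch(optim(theta0, obj, method = "L-BFGS-B", lower = lower,
                          upper = upper, control = list(maxit = 400)),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) abort("All starts failed.", class = "weightsense_fit_error")
  pr <- so_theta_to_prior(best$par, K)
  per_cube$predicted <- predict_single_object_bias(pr, x, y)
  sst <- sum((b - mean(b))^2)
  structure(list(prior = pr, per_cube = per_cube, ssr = best$value,
                 r_squared = if (sst > 0) 1 - best$value / sst else NA_real_,
                 n_params = np),
            class = "swi_single_object_fit")
}
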