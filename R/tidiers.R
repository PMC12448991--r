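#' Tidy a fitted descriptive model
#'
#' @param x A `swi_descriptive_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, and the
#'   model `component` the term belongs to.
#' @export
tidy.swi_descriptive_fit <- function(x, ...) {
  comp <- c(C = "intercept", beta1 = "weight_judged", beta2 = "density_judged",
            beta3 = "weight_other", beta4 = "gated_density_judged",
            beta5 = "gated_density_other", sigma = "gate_sd")
  est <- unclass(x$coefficients)
  tibble::tibble(term = names(est), estimate = as.numeric(est),
                 component = unname(comp[names(est)]))
}

#' Glance at a fitted descriptive model
#'
#' @inheritParams tidy.swi_descriptive_fit
#' @return A one-row tibble: `r.squared`, `ssr`, `sigma`, `n_params`, `nobs`.
#' @export
glance.swi_descriptive_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, ssr = x$ssr, sigma = x$sigma,
                 n_params = x$n_params, nobs = x$n)
}

#' Tidy a fitted efficient-coding ratio model
#'
#' @param x A `swi_ratio_fit`.
#' @param ... Unused.
#' @return A tibble with one row per mixture component plus the bias scale.
#' @export
tidy.swi_ratio_fit <- function(x, ...) {
  cmp <- x$prior$components
  dplyr::bind_rows(
    tibble::tibble(term = paste0("component", seq_len(nrow(cmp))),
                   sd_logV = cmp$sd_logV, sd_logW = cmp$sd_logW,
                   correlation = cmp$correlation, weight = cmp$weight),
    tibble::tibble(term = "C_b", sd_logV = NA, sd_logW = NA,
                   correlation = NA, weight = NA)
  ) |>
    dplyr::mutate(estimate = c(rep(NA, nrow(cmp)), x$prior$C_b))
}

#' Glance at a fitted efficient-coding ratio model
#'
#' @inheritParams tidy.swi_ratio_fit
#' @return A one-row tibble: `r.squared`, `ssr`, `n_params`, `nobs`.
#' @export
glance.swi_ratio_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, ssr = x$ssr,
                 n_params = x$n_params, nobs = nrow(x$bias_field))
}

#' Tidy a fitted cue-combination model
#'
#' @param x A `swi_cue_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` for beta1, beta2, x, y.
#' @export
tidy.swi_cue_fit <- function(x, ...) {
  tibble::tibble(term = c("beta1", "beta2", "x", "y"),
                 estimate = as.numeric(unlist(x$params)))
}

#' Glance at a fitted cue-combination model
#'
#' @inheritParams tidy.swi_cue_fit
#' @return A one-row tibble: `r.squared`, `ssr`, `n_params`, `nobs`.
#' @export
glance.swi_cue_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, ssr = x$ssr,
                 n_params = x$n_params, nobs = x$n)
}

#' Tidy a fitted sub-prior model
#'
#' @param x A `swi_subprior_fit`.
#' @param ... Unused.
#' @return A tibble with one row per sub-prior component.
#' @export
tidy.swi_subprior_fit <- function(x, ...) {
  m <- x$model
  tibble::tibble(term = paste0("R", seq_along(m$slopes)),
                 slope = m$slopes, sd_along = m$sd_along,
                 sd_across = m$sd_across, weight = m$weights)
}

#' Glance at a fitted sub-prior model
#'
#' @inheritParams tidy.swi_subprior_fit
#' @return A one-row tibble: `r.squared`, `ssr`, `n_params`, `nobs`.
#' @export
glance.swi_subprior_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, ssr = x$ssr,
                 n_params = x$n_params, nobs = nrow(x$bias_field))
}
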