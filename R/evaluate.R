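#' Coefficient of determination
#'
#' `1 - SSR/SST` with SST taken about the mean of the observed vector.
#' Equals 1 iff predictions are exact; 0 when predicting the mean; can be
#' negative for models worse than the mean.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return A single dimensionless value.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    abort("observed and predicted must have equal length >= 2.",
          class = "weightsense_validation_error")
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    abort("observed vector is constant; R^2 undefined.",
          class = "weightsense_validation_error")
  }
  1 - sum((observed - predicted)^2) / sst
}

#' Empirical bias field over stimulus pairs
#'
#' For each unique pair, the mean over participants and repeats of the
#' per-trial log ratio of the two weight estimates, minus the true log weight
#' ratio. Orientation is fixed by the pair id: object 1 is the
#' lexicographically smaller cube id, so swapping orientation flips the sign
#' of every ratio quantity exactly. `response_variance` is the variance of
#' the same per-trial log ratios; pairs with fewer than 2 usable trials get
#' `NA` variance and are flagged.
#'
#' @param records Preprocessed estimate records (both objects' estimates must
#'   be present for a trial to contribute).
#' @param cubes Cube table.
#' @return A tibble of class `swi_bias_field`: `pair_id`, `logV_ratio`,
#'   `logW_ratio` (true values), `bias`, `response_variance`, `n_trials`.
#' @export
build_bias_field <- function(records, cubes) {
  records <- drop_removed(records)
  col <- response_column(records)
  parts <- strsplit(records$pair_id, "|", fixed = TRUE)
  records$obj <- ifelse(records$cube_id == purrr::map_chr(parts, 1), 1L, 2L)
  wide <- records |>
    dplyr::select("participant_id", "trial_index", "pair_id", "obj",
                  est = dplyr::all_of(col)) |>
    tidyr::pivot_wider(names_from = "obj", values_from = "est",
                       names_prefix = "est") |>
    dplyr::filter(is.finite(.data$est1), is.finite(.data$est2),
                  .data$est1 > 0, .data$est2 > 0)

  lk <- cubes |> dplyr::select("cube_id", "weight", "volume")
  truth <- tibble::tibble(pair_id = unique(records$pair_id)) |>
    dplyr::mutate(cube1 = purrr::map_chr(strsplit(.data$pair_id, "|", fixed = TRUE), 1),
                  cube2 = purrr::map_chr(strsplit(.data$pair_id, "|", fixed = TRUE), 2)) |>
    dplyr::left_join(dplyr::rename(lk, w1 = "weight", v1 = "volume"),
                     by = c(cube1 = "cube_id")) |>
    dplyr::left_join(dplyr::rename(lk, w2 = "weight", v2 = "volume"),
                     by = c(cube2 = "cube_id"))

  out <- wide |>
    dplyr::summarise(mean_log_ratio = mean(log(.data$est1 / .data$est2)),
                     response_variance = if (dplyr::n() >= 2)
                       var(log(.data$est1 / .data$est2)) else NA_real_,
                     n_trials = dplyr::n(), .by = "pair_id") |>
    dplyr::left_join(truth, by = "pair_id") |>
    dplyr::mutate(logV_ratio = log(.data$v1 / .data$v2),
                  logW_ratio = log(.data$w1 / .data$w2),
                  bias = .data$mean_log_ratio - .data$logW_ratio) |>
    dplyr::select("pair_id", "logV_ratio", "logW_ratio", "bias",
                  "response_variance", "n_trials") |>
    dplyr::arrange(.data$pair_id)
  class(out) <- c("swi_bias_field", class(out))
  out
}

#' Regressions of response variance on log-ratio magnitudes
#'
#' Ordinary least squares of per-pair response variance on the absolute log
#' weight ratio alone, the absolute log volume ratio alone, and both
#' together. A structural diagnostic: the efficient-coding ratio model ties
#' variance mainly to log volume ratio, whereas empirical variance tends to
#' track log weight ratio.
#'
#' @param bias_field A bias field with a `response_variance` column, or any
#'   tibble with `logV_ratio`, `logW_ratio`, `response_variance`.
#' @param variance Optional replacement variance vector (e.g. model-predicted
#'   variances at the same pairs).
#' @return A tibble with rows `abs_logW`, `abs_logV`, `both` and their R^2.
#' @export
variance_regressions <- function(bias_field, variance = NULL) {
  v <- variance %||% bias_field$response_variance
  ok <- is.finite(v)
  if (sum(ok) < 10) {
    abort("Need >= 10 pairs with defined variance.",
          class = "weightsense_validation_error")
  }
  d <- tibble::tibble(v = v[ok],
                      aw = abs(bias_field$logW_ratio[ok]),
                      av = abs(bias_field$logV_ratio[ok]))
  r2 <- function(f) summary(lm(f, data = d))$r.squared
  tibble::tibble(
    predictors = c("abs_logW", "abs_logV", "both"),
    r_squared = c(r2(v ~ aw), r2(v ~ av), r2(v ~ aw + av))
  )
}

#' Standardised fit report
#'
#' Normalises a fitted model object (or hand-assembled metrics) into one row
#' for [compare_models()].
#'
#' @param fit A fitted object (`swi_descriptive_fit`, `swi_cue_fit`,
#'   `swi_ratio_fit`, `swi_subprior_fit`) or `NULL` if supplying fields.
#' @param model_name Label for the model.
#' @param cv_error Optional cross-validation error (same units as SSR).
#' @param n_params,ssr,r2 Overrides when `fit` is `NULL`.
#' @return A one-row tibble: `model`, `n_params`, `ssr`, `r_squared`,
#'   `cv_error`.
#' @export
fit_report <- function(fit = NULL, model_name, cv_error = NA_real_,
                       n_params = NULL, ssr = NULL, r2 = NULL) {
  tibble::tibble(
    model = model_name,
    n_params = as.integer(n_params %||% fit$n_params),
    ssr = ssr %||% fit$ssr,
    r_squared = r2 %||% fit$r_squared,
    cv_error = cv_error
  )
}

#' Compare fitted models
#'
#' Stacks fit reports and ranks them: by cross-validation error where every
#' model has one, otherwise by SSR. All reports must concern the same
#' response vector for SSR/R^2 to be comparable; this is the caller's
#' contract.
#'
#' @param ... One-row tibbles from [fit_report()] (or a single list of them).
#' @return A tibble sorted by the ranking criterion with a `rank` column.
#' @export
compare_models <- function(...) {
  reports <- list(...)
  if (length(reports) == 1 && is.list(reports[[1]]) && !is.data.frame(reports[[1]])) {
    reports <- reports[[1]]
  }
  tab <- dplyr::bind_rows(reports)
  if (length(unique(tab$model)) < nrow(tab)) {
    tab$model <- make.unique(tab$model)
  }
  by_cv <- all(is.finite(tab$cv_error))
  tab <- if (by_cv) dplyr::arrange(tab, .data$cv_error) else dplyr::arrange(tab, .data$ssr)
  tab$rank <- seq_len(nrow(tab))
  tab$ranked_by <- if (by_cv) "cv_error" else "ssr"
  tab
}

# ---- cross-validated model comparison --------------------------------------

# Deterministic per-pair bias field implied by a fitted descriptive model.
descriptive_bias_field <- function(fit, pairs, cubes) {
  lk <- cubes |> dplyr::select("cube_id", "weight", "density", "volume")
  d <- pairs |>
    dplyr::left_join(dplyr::rename(lk, w1 = "weight", d1 = "density", v1 = "volume"),
                     by = c(cube_a = "cube_id")) |>
    dplyr::left_join(dplyr::rename(lk, w2 = "weight", d2 = "density", v2 = "volume"),
                     by = c(cube_b = "cube_id"))
  p1 <- if (fit$predictor == "density") d$d1 else d$v1
  p2 <- if (fit$predictor == "density") d$d2 else d$v2
  k <- fit$coefficients
  g <- weight_gate(d$w1 - d$w2, k[["sigma"]])
  pred1 <- k[["C"]] + k[["beta1"]] * d$w1 + k[["beta2"]] * p1 + k[["beta3"]] * d$w2 +
    (k[["beta4"]] * p1 + k[["beta5"]] * p2) * g
  pred2 <- k[["C"]] + k[["beta1"]] * d$w2 + k[["beta2"]] * p2 + k[["beta3"]] * d$w1 +
    (k[["beta4"]] * p2 + k[["beta5"]] * p1) * g
  tibble::tibble(pair_id = d$pair_id,
                 bias = log(pred1 / pred2) - log(d$w1 / d$w2))
}

#' Cross-validated comparison of the three perceived-weight models
#'
#' Leave-one-participant-out comparison on a single dataset, in the two
#' spaces where the models are defined:
#'
#' * record space (grams): the descriptive model vs the cue-combination
#'   model, each fitted to the training participants' records and scored by
#'   summed squared prediction error on the held-out participant's records;
#' * bias-field space (log weight ratio): the descriptive model (via the
#'   bias field its fitted coefficients imply) vs the sub-prior mixture
#'   model (fitted to the training participants' empirical bias field), each
#'   scored against the held-out participant's empirical per-pair biases.
#'
#' @param records Preprocessed estimate records.
#' @param cubes Cube table.
#' @param pairs Pair table from [enumerate_pairs()].
#' @param n_starts,seed Fitting control.
#' @return A tibble with one row per model: `model`, `space`, `n_params`,
#'   `cv_error`.
#' @export
cv_model_comparison <- function(records, cubes, pairs, n_starts = 6, seed = 1L) {
  records <- drop_removed(records)
  col <- response_column(records)
  parts <- unique(records$participant_id)
  dd_all <- design_data(records, cubes)
  err <- c(descriptive = 0, cue_combination = 0,
           descriptive_bias = 0, subprior = 0)
  npar <- c(descriptive = NA, cue_combination = NA,
            descriptive_bias = NA, subprior = 12)
  for (i in seq_along(parts)) {
    train <- records[records$participant_id != parts[i], ]
    test_dd <- dd_all[dd_all$participant_id == parts[i], ]
    s <- derive_seed(seed, i)

    fd <- fit_descriptive(train, cubes, n_starts = n_starts, seed = s, response = col)
    err[["descriptive"]] <- err[["descriptive"]] +
      sum((test_dd[[col]] - predict_fit_rows(fd, test_dd))^2)
    npar[["descriptive"]] <- fd$n_params

    fc <- fit_cue_combination(train, cubes, n_starts = n_starts, seed = s)
    err[["cue_combination"]] <- err[["cue_combination"]] +
      sum((test_dd[[col]] - predict_cue_combination(fc$params, test_dd$w1, test_dd$d1))^2)
    npar[["cue_combination"]] <- fc$n_params

    bf_train <- build_bias_field(train, cubes)
    bf_test <- build_bias_field(records[records$participant_id == parts[i], ], cubes)

    db <- descriptive_bias_field(fd, pairs, cubes)
    j <- match(bf_test$pair_id, db$pair_id)
    err[["descriptive_bias"]] <- err[["descriptive_bias"]] +
      sum((bf_test$bias - db$bias[j])^2)
    npar[["descriptive_bias"]] <- fd$n_params

    fs <- fit_subprior_model(bf_train, n_starts = n_starts, seed = s)
    jj <- match(bf_test$pair_id, bf_train$pair_id)
    err[["subprior"]] <- err[["subprior"]] +
      sum((bf_test$bias - fs$predicted[jj])^2)
  }
  tibble::tibble(
    model = names(err),
    space = c("records_g", "records_g", "log_ratio", "log_ratio"),
    n_params = as.integer(npar),
    cv_error = as.numeric(err)
  )
}
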