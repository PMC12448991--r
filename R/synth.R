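#' Observer profile for synthetic magnitude estimation
#'
#' Describes one simulated observer. Magnitude estimation with a reference
#' object anchors the scale only loosely, so observers differ in how they use
#' it: responses are multiplied by an idiosyncratic `scale_factor`. Response
#' noise is additive Gaussian in grams by default (`noise_model =
#' "additive"`); a Weber-like magnitude-proportional option is available for
#' robustness studies. A small fraction of responses are gross errors
#' (misheard or misspoken numbers), displaced by `outlier_magnitude` noise
#' SDs in a random direction.
#'
#' @param participant_id Participant label.
#' @param scale_factor Idiosyncratic response-scale multiplier (> 0).
#' @param noise_sd Response noise SD in grams (>= 0); under the proportional
#'   model this is the SD at the reference weight (375 g).
#' @param outlier_rate Probability a response is a gross error, in \[0, 1\].
#' @param outlier_magnitude Displacement of gross errors, in multiples of
#'   `noise_sd`.
#' @param noise_model `"additive"` (default) or `"proportional"`.
#' @param seed Integer seed for this observer's private response stream.
#' @return A list of class `swi_observer`.
#' @export
observer_profile <- function(participant_id = "P01", scale_factor = 1,
                             noise_sd = 25, outlier_rate = 0.004,
                             outlier_magnitude = 8,
                             noise_model = c("additive", "proportional"),
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (scale_factor <= 0) abort("scale_factor must be > 0.", class = "weightsense_validation_error")
  if (noise_sd < 0) abort("noise_sd must be >= 0.", class = "weightsense_validation_error")
  if (outlier_rate < 0 || outlier_rate > 1) {
    abort("outlier_rate must be in [0, 1].", class = "weightsense_validation_error")
  }
  structure(list(participant_id = participant_id, scale_factor = scale_factor,
                 noise_sd = noise_sd, outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "swi_observer")
}

#' Generate an observer cohort
#'
#' Draws `n` observer profiles. Scale factors are log-normal with median
#' `base$scale_factor` and log-SD `scale_spread`; each observer receives a
#' distinct private seed derived from `master_seed` and their index, so
#' growing the cohort leaves earlier observers unchanged.
#'
#' @param n Number of observers (>= 1).
#' @param base Template [observer_profile()].
#' @param scale_spread Log-SD of the scale-factor distribution (>= 0).
#' @param master_seed Integer master seed.
#' @return A list of `swi_observer` profiles with ids `P01`, `P02`, ...
#' @export
make_observer_cohort <- function(n, base = observer_profile(),
                                 scale_spread = 0.2, master_seed = 1L) {
  if (n < 1) abort("n must be >= 1.", class = "weightsense_validation_error")
  if (scale_spread < 0) abort("scale_spread must be >= 0.", class = "weightsense_validation_error")
  scales <- withr::with_seed(derive_seed(master_seed, 0),
                             base$scale_factor * exp(rnorm(n, 0, scale_spread)))
  purrr::map(seq_len(n), function(i) {
    o <- base
    o$participant_id <- sprintf("P%02d", i)
    o$scale_factor <- scales[i]
    o$seed <- derive_seed(master_seed, i)
    o
  })
}

#' Generating model for forward simulation
#'
#' Bundles a model kind with its parameters for [simulate_session()].
#'
#' @param kind `"descriptive"` (perceived weight from the gated descriptive
#'   model), `"cue_combination"` (weight-density power-law combination), or
#'   `"effcoding_ratio"` (efficient-coding ratio model: the predicted log
#'   weight-ratio bias of each pair is split equally, with opposite sign,
#'   between the two objects' log perceived weights).
#' @param parameters A [descriptive_coefficients()] vector, a
#'   [cue_combination_params()] object, or a [ratio_prior()] respectively.
#' @return A list of class `swi_generating_model`.
#' @export
generating_model <- function(kind = c("descriptive", "cue_combination", "effcoding_ratio"),
                             parameters = swi_reference_coefficients()) {
  kind <- match.arg(kind)
  ok <- switch(kind,
    descriptive = inherits(parameters, "swi_coefficients"),
    cue_combination = inherits(parameters, "swi_cue_params"),
    effcoding_ratio = inherits(parameters, "swi_ratio_prior")
  )
  if (!ok) {
    abort(paste0("parameters do not match model kind `", kind, "`."),
          class = "weightsense_validation_error")
  }
  structure(list(kind = kind, parameters = parameters),
            class = "swi_generating_model")
}

# Noise-free perceived weight (g) for judged/other rows under a generating model.
model_perceived_weight <- function(model, dd) {
  switch(model$kind,
    descriptive = predict_weight(dd$w1, dd$d1, dd$w2, dd$d2, model$parameters),
    cue_combination = predict_cue_combination(model$parameters, dd$w1, dd$d1),
    effcoding_ratio = {
      # orientation: bias defined for log(w_a/w_b) with a < b lexicographically
      orient <- ifelse(dd$cube_id < dd$other_cube, 1, -1)
      logv <- orient * (log(dd$v1) - log(dd$v2))
      logw <- orient * (log(dd$w1) - log(dd$w2))
      b <- predict_bias(model$parameters, logv, logw)
      dd$w1 * exp(orient * b / 2)
    }
  )
}

#' Simulate magnitude-estimation responses for one observer
#'
#' Forward-simulates a trial list: on each trial the observer reports the
#' perceived weight of both cubes. Reported raw units are
#' `scale_factor * (model prediction in grams + noise) / grams_per_unit`;
#' with probability `outlier_rate` a response is displaced by
#' `+/- outlier_magnitude * noise_sd` grams (planted gross errors are marked
#' in the `planted_outlier` column so removal sensitivity can be scored).
#' Reproducible given the observer's seed.
#'
#' @param trials Trial tibble (rows for this observer) from [build_trial_list()].
#' @param cubes Cube table.
#' @param observer An [observer_profile()].
#' @param model A [generating_model()].
#' @param grams_per_unit Grams per response unit; 7.5 by default (the 375 g
#'   reference cube is anchored to "50").
#' @return A tibble of estimate records: `participant_id`, `session`,
#'   `trial_index`, `cube_id`, `other_cube`, `position`, `pair_id`,
#'   `presentation`, `raw_units`, `planted_outlier`.
#' @export
simulate_session <- function(trials, cubes, observer, model = generating_model(),
                             grams_per_unit = 7.5) {
  recs <- dplyr::bind_rows(
    dplyr::mutate(trials, cube_id = .data$left_cube, other_cube = .data$right_cube,
                  position = "left"),
    dplyr::mutate(trials, cube_id = .data$right_cube, other_cube = .data$left_cube,
                  position = "right")
  ) |>
    dplyr::arrange(.data$trial_index, .data$position) |>
    dplyr::select("participant_id", "session", "trial_index", "cube_id",
                  "other_cube", "position", "pair_id", "presentation")
  recs$participant_id <- observer$participant_id

  dd <- design_data(recs, cubes)
  mu <- model_perceived_weight(model, dd)

  n <- nrow(recs)
  withr::with_seed(observer$seed, {
    sd_i <- if (observer$noise_model == "proportional") {
      observer$noise_sd * mu / 375
    } else {
      rep(observer$noise_sd, n)
    }
    grams <- mu + rnorm(n, 0, sd_i)
    is_out <- runif(n) < observer$outlier_rate
    sign_out <- sample(c(-1, 1), n, replace = TRUE)
    grams <- grams + is_out * sign_out * observer$outlier_magnitude * sd_i
  })
  recs$raw_units <- observer$scale_factor * grams / grams_per_unit
  recs$planted_outlier <- is_out
  recs
}

#' Simulate a complete study
#'
#' Convenience wrapper reproducing the full study design: builds the stimulus
#' set, enumerates pairs, constructs randomised 266-trial lists for each of
#' `n_participants` observers, and simulates their magnitude estimates.
#'
#' @param n_participants Cohort size (30 by default, as in the emulated study).
#' @param seed Master seed driving trial order, cohort draw and responses.
#' @param model A [generating_model()].
#' @param config A [stimulus_config()].
#' @param base Template [observer_profile()].
#' @param scale_spread Log-SD of scale-factor idiosyncrasy.
#' @param grams_per_unit Grams per response unit.
#' @return A list with `cubes`, `pairs`, `trials`, `estimates`, `observers`.
#' @export
simulate_study <- function(n_participants = 30, seed = 1L,
                           model = generating_model(),
                           config = stimulus_config(),
                           base = observer_profile(),
                           scale_spread = 0.2,
                           grams_per_unit = 7.5) {
  cubes <- build_stimulus_set(config)
  pairs <- enumerate_pairs(cubes)
  middle_id <- cubes$cube_id[cubes$subset == "shared_middle"]
  observers <- make_observer_cohort(n_participants, base, scale_spread,
                                    master_seed = seed)
  ids <- purrr::map_chr(observers, "participant_id")
  trials <- build_trial_list(pairs, middle_id, participants = ids,
                             seed = derive_seed(seed, 10^6))
  estimates <- purrr::map(observers, function(o) {
    simulate_session(trials[trials$participant_id == o$participant_id, ],
                     cubes, o, model, grams_per_unit)
  }) |> dplyr::bind_rows()
  list(cubes = cubes, pairs = pairs, trials = trials,
       estimates = estimates, observers = observers)
}
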