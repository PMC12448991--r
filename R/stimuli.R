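#' Default stimulus-set configuration
#'
#' The default reconstruction of the three-subset cube design used throughout
#' the package. Three subsets share a common middle cube (750 cm^3, 375 g,
#' 0.5 g/cm^3):
#'
#' * `equal_density` — density fixed at 0.5 g/cm^3; volumes step in 100 cm^3
#'   with additional 50 cm^3 steps either side of the middle cube, so weight
#'   increases linearly with volume ("normal" same-material objects).
#' * `equal_weight` — weight fixed at 375 g; density decreases with size
#'   (classic size-weight-illusion stimuli). Pairwise density ratios
#'   (less dense / denser) span 0.58–0.89.
#' * `increasing_density` — both weight and density increase with size;
#'   densities are linear in volume through the middle cube.
#'
#' All three lists must contain the middle volume. The set is fully
#' configurable so alternative reconstructions can be swapped in.
#'
#' @param equal_density_volumes,equal_weight_volumes,increasing_density_volumes
#'   Numeric vectors of cube volumes (cm^3) per subset.
#' @param middle_volume,middle_weight Volume (cm^3) and weight (g) of the
#'   shared middle cube. Its density is `middle_weight / middle_volume`.
#' @param increasing_density_slope Density change (g/cm^3) per cm^3 of volume
#'   in the `increasing_density` subset, anchored at the middle cube.
#'
#' @return A list of class `swi_stimulus_config`.
#' @export
#' @examples
#' cfg <- stimulus_config()
#' cubes <- build_stimulus_set(cfg)
stimulus_config <- function(equal_density_volumes = c(550, 650, 700, 750, 800, 850, 950),
                            equal_weight_volumes = c(550, 650, 750, 850, 950),
                            increasing_density_volumes = c(550, 650, 750, 850, 950),
                            middle_volume = 750,
                            middle_weight = 375,
                            increasing_density_slope = 0.045 / 100) {
  cfg <- list(
    equal_density_volumes = sort(equal_density_volumes),
    equal_weight_volumes = sort(equal_weight_volumes),
    increasing_density_volumes = sort(increasing_density_volumes),
    middle_volume = middle_volume,
    middle_weight = middle_weight,
    increasing_density_slope = increasing_density_slope
  )
  vols <- c(cfg$equal_density_volumes, cfg$equal_weight_volumes,
            cfg$increasing_density_volumes, middle_volume)
  if (any(!is.finite(vols)) || any(vols <= 0)) {
    abort("All volumes must be finite and strictly positive.", class = "weightsense_validation_error")
  }
  if (middle_weight <= 0) {
    abort("middle_weight must be strictly positive.", class = "weightsense_validation_error")
  }
  for (s in c("equal_density_volumes", "equal_weight_volumes", "increasing_density_volumes")) {
    if (!middle_volume %in% cfg[[s]]) {
      abort(paste0("Subset `", s, "` does not contain the middle volume (",
                   middle_volume, " cm^3); all subsets must share the middle cube."),
            class = "weightsense_config_error")
    }
  }
  structure(cfg, class = "swi_stimulus_config")
}

#' Build the cube stimulus set
#'
#' Constructs the full stimulus set from a configuration: three subsets with a
#' single shared middle cube, 15 cubes under the default configuration. The
#' middle cube is tagged `shared_middle` and appears exactly once.
#'
#' @param config A [stimulus_config()] object.
#'
#' @return A tibble with one row per cube: `cube_id`, `subset`
#'   (`equal_density`, `equal_weight`, `increasing_density`, `shared_middle`),
#'   `volume` (cm^3), `weight` (g), `density` (g/cm^3). Every row satisfies
#'   `density * volume == weight`.
#' @export
#' @examples
#' cubes <- build_stimulus_set()
#' nrow(cubes) # 15
build_stimulus_set <- function(config = stimulus_config()) {
  if (!inherits(config, "swi_stimulus_config")) config <- do.call(stimulus_config, config)
  mid_v <- config$middle_volume
  mid_w <- config$middle_weight
  mid_d <- mid_w / mid_v

  ed <- tibble::tibble(
    subset = "equal_density",
    volume = config$equal_density_volumes,
    density = mid_d,
    weight = density * volume
  )
  ew <- tibble::tibble(
    subset = "equal_weight",
    volume = config$equal_weight_volumes,
    weight = mid_w,
    density = weight / volume
  )
  id <- tibble::tibble(
    subset = "increasing_density",
    volume = config$increasing_density_volumes,
    density = mid_d + config$increasing_density_slope * (volume - mid_v),
    weight = density * volume
  )
  if (any(id$density <= 0)) {
    abort("increasing_density_slope produces non-positive densities.",
          class = "weightsense_config_error")
  }

  prefix <- c(equal_density = "D", equal_weight = "W", increasing_density = "I")
  cubes <- dplyr::bind_rows(ed, ew, id) |>
    dplyr::mutate(
      is_middle = .data$volume == mid_v,
      subset = ifelse(.data$is_middle, "shared_middle", .data$subset),
      cube_id = ifelse(.data$is_middle, paste0("M", mid_v),
                       paste0(prefix[.data$subset], .data$volume))
    ) |>
    dplyr::distinct(.data$cube_id, .keep_all = TRUE) |>
    dplyr::select("cube_id", "subset", "volume", "weight", "density") |>
    dplyr::arrange(.data$cube_id)

  stopifnot(all(abs(cubes$density * cubes$volume - cubes$weight) <=
                  1e-9 * pmax(cubes$weight, 1)))
  cubes
}

#' Order-invariant pair identifier
#'
#' @param a,b Character vectors of cube ids (recycled).
#' @return `pair_id` strings: sorted ids joined by `"|"`, so that
#'   `make_pair_id(a, b) == make_pair_id(b, a)`.
#' @export
make_pair_id <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Enumerate all unordered stimulus pairs
#'
#' All unordered pairs of distinct cubes; pairs of identical stimuli are
#' excluded by construction. For `n` cubes this yields `n * (n - 1) / 2`
#' pairs (105 for the default 15-cube set).
#'
#' @param cubes Cube tibble from [build_stimulus_set()].
#' @return A tibble with `pair_id`, `cube_a`, `cube_b` (ids, `cube_a < cube_b`).
#' @export
enumerate_pairs <- function(cubes) {
  ids <- cubes$cube_id
  if (length(ids) < 2) abort("Need at least 2 cubes.", class = "weightsense_validation_error")
  if (anyDuplicated(ids)) {
    abort("Duplicate cube_ids in stimulus set.", class = "weightsense_validation_error")
  }
  ids <- sort(ids)
  idx <- utils::combn(length(ids), 2)
  tibble::tibble(
    cube_a = ids[idx[1, ]],
    cube_b = ids[idx[2, ]],
    pair_id = make_pair_id(cube_a, cube_b)
  ) |>
    dplyr::select("pair_id", "cube_a", "cube_b")
}

#' Build randomised per-participant trial lists
#'
#' Reproduces the study design: a base list containing each unique pair once,
#' with every pair involving the shared middle cube entered three times
#' (105 + 2 x 14 = 133 base entries for the default set). Each base entry is
#' presented twice with left/right position switched, giving 266 trials per
#' participant, in a seeded random order, split evenly across two sessions.
#'
#' @param pairs Pair tibble from [enumerate_pairs()].
#' @param middle_id Cube id of the shared middle cube, or `NULL` for a design
#'   without the repeated-middle quirk (each pair then enters the base list
#'   once).
#' @param participants Character vector of participant ids.
#' @param seed Integer seed; trial order is a deterministic function of
#'   `(seed, participant)`.
#'
#' @return A tibble with `participant_id`, `session` (1 or 2), `trial_index`,
#'   `left_cube`, `right_cube`, `pair_id`, `presentation` (1 or 2; the two
#'   presentations of a base entry have left/right swapped).
#' @export
build_trial_list <- function(pairs, middle_id = NULL,
                             participants = sprintf("P%02d", 1:30),
                             seed = 1L) {
  if (is.null(middle_id)) {
    has_middle <- rep(FALSE, nrow(pairs))
  } else {
    has_middle <- pairs$cube_a == middle_id | pairs$cube_b == middle_id
    if (!any(has_middle)) {
      abort("middle_id does not occur in any pair.", class = "weightsense_validation_error")
    }
  }
  reps <- ifelse(has_middle, 3L, 1L)
  base <- pairs[rep(seq_len(nrow(pairs)), reps), ]
  base$entry <- seq_len(nrow(base))

  # each base entry -> two trials with left/right swapped
  trials <- dplyr::bind_rows(
    dplyr::mutate(base, left_cube = .data$cube_a, right_cube = .data$cube_b, presentation = 1L),
    dplyr::mutate(base, left_cube = .data$cube_b, right_cube = .data$cube_a, presentation = 2L)
  )

  purrr::map(seq_along(participants), function(i) {
    ord <- withr::with_seed(derive_seed(seed, i), sample.int(nrow(trials)))
    out <- trials[ord, ]
    n <- nrow(out)
    out$participant_id <- participants[i]
    out$trial_index <- seq_len(n)
    out$session <- ifelse(out$trial_index <= ceiling(n / 2), 1L, 2L)
    out
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("participant_id", "session", "trial_index",
                  "left_cube", "right_cube", "pair_id", "presentation")
}

# deterministic 32-bit substream seed from (master seed, index)
derive_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 48271 + i * 16807) %% 2147483647L)
}
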