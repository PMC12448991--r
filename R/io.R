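#' Read and write the package's delimited-text interchange files
#'
#' Plain CSV (header row, UTF-8, '.' decimal) versions of the three core
#' tables. Physical quantities carry explicit units in the file headers
#' (`volume_cm3`, `weight_g`, `density_g_cm3`, `raw_estimate_units`) and are
#' mapped to/from the package's internal column names.
#'
#' @param x Table to write.
#' @param path File path.
#' @name weightsense_io
NULL

#' @rdname weightsense_io
#' @export
write_stimuli <- function(x, path) {
  x |>
    dplyr::select("cube_id", "subset", volume_cm3 = "volume",
                  weight_g = "weight", density_g_cm3 = "density") |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname weightsense_io
#' @export
read_stimuli <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::rename(volume = "volume_cm3", weight = "weight_g",
                  density = "density_g_cm3")
}

#' @rdname weightsense_io
#' @export
write_trials <- function(x, path) {
  x |>
    dplyr::select("participant_id", "session", "trial_index", "left_cube",
                  "right_cube", "pair_id", "presentation") |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname weightsense_io
#' @export
read_trials <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname weightsense_io
#' @export
write_estimates <- function(x, path) {
  keep <- intersect(c("participant_id", "session", "trial_index", "cube_id",
                      "other_cube", "position", "pair_id", "presentation",
                      "grams", "normalised", "outlier_pass"), names(x))
  x |>
    dplyr::select(dplyr::all_of(keep), raw_estimate_units = "raw_units") |>
    readr::write_csv(path)
  invisible(path)
}

#' @rdname weightsense_io
#' @export
read_estimates <- function(path) {
  readr::read_csv(path, show_col_types = FALSE) |>
    dplyr::rename(raw_units = "raw_estimate_units")
}
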