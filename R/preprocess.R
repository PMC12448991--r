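#' Transform raw magnitude estimates to grams
#'
#' Responses are given in arbitrary units anchored to a reference cube
#' (375 g labelled "50", i.e. 7.5 g per unit by default).
#'
#' @param records Estimate records with a `raw_units` column.
#' @param grams_per_unit Grams per response unit (> 0).
#' @return `records` with a `grams` column (`raw_units * grams_per_unit`);
#'   row order preserved.
#' @export
#' @examples
#' to_grams(tibble::tibble(raw_units = c(50, 0, 100)))$grams # 375 0 750
to_grams <- function(records, grams_per_unit = 7.5) {
  if (grams_per_unit <= 0) {
    abort("grams_per_unit must be > 0.", class = "weightsense_validation_error")
  }
  bad <- which(!is.finite(records$raw_units))
  if (length(bad)) {
    abort(paste("Non-finite raw_units at rows:",
                paste(head(bad, 10), collapse = ", ")),
          class = "weightsense_validation_error")
  }
  records$grams <- records$raw_units * grams_per_unit
  records
}

#' Equalise participants' mean responses
#'
#' Removes individual differences in response-scale use: each participant's
#' retained estimates are multiplied by the ratio of the pooled grand mean to
#' that participant's grand mean, so that after normalisation every
#' participant has the same mean response, and the pooled grand mean is
#' unchanged. Rows already flagged by outlier removal are carried through
#' untouched and excluded from all means. The operation is idempotent.
#'
#' @param records Estimate records with a `grams` column (and optionally a
#'   `normalised` column from a previous pass, which is recomputed from the
#'   same `grams` baseline each time).
#' @return `records` with a `normalised` column (grams).
#' @export
normalise_estimates <- function(records) {
  if (!"grams" %in% names(records)) {
    abort("records lack a `grams` column; run to_grams() first.",
          class = "weightsense_validation_error")
  }
  kept <- drop_removed(records)
  if (!nrow(kept)) abort("No retained records.", class = "weightsense_validation_error")
  means <- kept |>
    dplyr::summarise(m = mean(.data$grams), .by = "participant_id")
  if (any(!is.finite(means$m)) || any(means$m == 0)) {
    abort("A participant has zero or undefined mean response.",
          class = "weightsense_validation_error")
  }
  pooled <- mean(kept$grams)
  means$scale <- pooled / means$m
  records |>
    dplyr::left_join(means[, c("participant_id", "scale")], by = "participant_id") |>
    dplyr::mutate(normalised = .data$grams * .data$scale) |>
    dplyr::select(-"scale")
}

#' Iterative per-condition outlier removal
#'
#' Removes outlying normalised estimates in successive sweeps with shrinking
#' thresholds (5, then 4, then 3.5 SDs by default). In each sweep, the mean
#' and SD (n-1 denominator) of the normalised estimate are computed across
#' observers within each condition cell — one cell per (unordered pair,
#' judged cube), pooling left/right positions and repeats — and records
#' beyond the sweep's threshold are flagged with the sweep number in
#' `outlier_pass`. Survivors are re-normalised after every sweep. Cells with
#' fewer than 3 surviving records are skipped for that sweep with a warning.
#'
#' @param records Normalised estimate records (see [normalise_estimates()]).
#' @param thresholds Numeric vector of SD multiples, applied in order.
#' @return A list of class `swi_preprocessed`: `estimates` (all rows, removed
#'   ones flagged via `outlier_pass` and excluded from `normalised`
#'   statistics) and `removal` (a tibble with per-pass counts and the total
#'   removed fraction as attribute `fraction_removed`).
#' @export
remove_outliers <- function(records, thresholds = c(5, 4, 3.5)) {
  if (!"normalised" %in% names(records)) {
    records <- normalise_estimates(records)
  }
  if (!"outlier_pass" %in% names(records)) records$outlier_pass <- NA_integer_
  records$.row <- seq_len(nrow(records))
  counts <- integer(length(thresholds))

  for (k in seq_along(thresholds)) {
    kept <- drop_removed(records)
    cells <- kept |>
      dplyr::mutate(cell_m = mean(.data$normalised),
                    cell_sd = sd(.data$normalised),
                    cell_n = dplyr::n(),
                    .by = c("pair_id", "cube_id"))
    small <- cells$cell_n < 3
    if (any(small)) {
      warn(sprintf("Pass %d: %d condition cells have < 3 surviving records; skipped.",
                   k, length(unique(cells$pair_id[small]))))
    }
    out <- !small & cells$cell_sd > 0 &
      abs(cells$normalised - cells$cell_m) > thresholds[k] * cells$cell_sd
    counts[k] <- sum(out)
    records$outlier_pass[match(cells$.row[out], records$.row)] <- k
    records <- normalise_estimates(records)
  }
  records$.row <- NULL
  removal <- tibble::tibble(pass = seq_along(thresholds),
                            threshold = thresholds, removed = counts)
  attr(removal, "fraction_removed") <- sum(counts) / nrow(records)
  structure(list(estimates = records, removal = removal),
            class = "swi_preprocessed")
}

#' Full preprocessing pipeline
#'
#' Grams transform, mean normalisation, and iterative outlier removal in one
#' call.
#'
#' @inheritParams to_grams
#' @inheritParams remove_outliers
#' @return A `swi_preprocessed` list (see [remove_outliers()]).
#' @export
preprocess_estimates <- function(records, grams_per_unit = 7.5,
                                 thresholds = c(5, 4, 3.5)) {
  records |>
    to_grams(grams_per_unit) |>
    normalise_estimates() |>
    remove_outliers(thresholds)
}

#' Retained (post-removal) estimate records
#'
#' @param x A `swi_preprocessed` object or an estimate tibble.
#' @return The estimate rows not flagged by outlier removal.
#' @export
retained_estimates <- function(x) {
  if (inherits(x, "swi_preprocessed")) x <- x$estimates
  drop_removed(x)
}

#' @export
print.swi_preprocessed <- function(x, ...) {
  n <- nrow(x$estimates)
  rem <- sum(x$removal$removed)
  cat(sprintf("Preprocessed magnitude estimates: %d records, %d removed (%.2f%%)\n",
              n, rem, 100 * rem / n))
  print(x$removal)
  invisible(x)
}
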