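#' Predict microbiota age for new samples
#'
#' Applies a fitted (sparse, if sparsified) microbiota-age model to an
#' abundance table. Extra features in the table are ignored; model features
#' absent from the table are zero-filled with a warning (abundances are
#' fractions of the whole community and are deliberately not renormalized to
#' the sparse subset). If more than half the model features are missing the
#' call errors, since that indicates a model/table mismatch rather than a few
#' undetected taxa.
#'
#' @param model A `maturity_model`.
#' @param table Abundance tibble (`sample_id` plus feature columns).
#'
#' @return A tibble with `sample_id` and `microbiota_age` (months).
#' @export
microbiota_age <- function(model, table) {
  stopifnot(inherits(model, "maturity_model"))
  table <- validate_abundance_table(table)
  feats <- model$sparse_features %||% model$features
  x <- align_features(table, feats)
  pred <- predict(model$regressor, data = x, num.threads = 1)$predictions
  tibble::tibble(sample_id = table$sample_id, microbiota_age = pred)
}

lookup_bins <- function(bins, ages) {
  idx <- rep(NA_integer_, length(ages))
  for (i in seq_len(nrow(bins))) {
    last <- i == nrow(bins)
    sel <- !is.na(ages) & ages >= bins$bin_lo[i] &
      (ages < bins$bin_hi[i] | (last & ages <= bins$bin_hi[i]))
    idx[sel] <- i
  }
  idx
}

#' Microbiota-for-age z-scores (MAZ) and relative maturity
#'
#' Scores microbiota-age predictions against the healthy reference
#' calibration:
#' `MAZ = (microbiota age - healthy median microbiota age at the same
#' chronological age) / healthy SD of microbiota age at that age`, and
#' `relative maturity = microbiota age - healthy median`, in months. Samples
#' whose chronological age falls outside the calibrated range are returned
#' with missing scores and flagged.
#'
#' @param scores Tibble from [microbiota_age()] (`sample_id`,
#'   `microbiota_age`).
#' @param meta Sample metadata with `sample_id` and `age` (months).
#' @param model A calibrated `maturity_model` (see [calibrate()]).
#'
#' @return A `maturity_scores` tibble: `sample_id`, `age`, `microbiota_age`,
#'   `relative_maturity`, `MAZ`, `in_calibrated_range`.
#' @export
maz <- function(scores, meta, model) {
  stopifnot(inherits(model, "maturity_model"))
  if (is.null(model$calibration)) {
    abort("model has no calibration; run calibrate() first",
          class = "gutmaturity_validation_error")
  }
  bins <- model$calibration$bins
  dat <- dplyr::inner_join(scores, meta[c("sample_id", "age")],
                           by = "sample_id")
  idx <- lookup_bins(bins, dat$age)
  if (anyNA(idx)) {
    warn(paste0(sum(is.na(idx)),
                " sample(s) outside the calibrated age range; MAZ set to NA"))
  }
  med <- bins$median_pred_age[idx]
  sdv <- bins$sd_pred_age[idx]
  out <- tibble::tibble(
    sample_id = dat$sample_id,
    age = dat$age,
    microbiota_age = dat$microbiota_age,
    relative_maturity = dat$microbiota_age - med,
    MAZ = (dat$microbiota_age - med) / sdv,
    in_calibrated_range = !is.na(idx)
  )
  class(out) <- c("maturity_scores", class(out))
  out
}

#' Fit, sparsify, calibrate and score in one call
#'
#' Convenience wrapper: predicts microbiota age for `table` with a calibrated
#' model and returns full maturity scores.
#'
#' @inheritParams maz
#' @param table Abundance tibble to score.
#' @return A `maturity_scores` tibble (see [maz()]).
#' @export
score_samples <- function(model, table, meta) {
  maz(microbiota_age(model, table), meta, model)
}

#' Correlate maturity scores with anthropometric indices
#'
#' Pearson correlation of MAZ (or relative maturity) against each requested
#' anthropometric index, with pairwise-complete handling of missing values
#' and Benjamini-Hochberg FDR across the indices tested. Zero-variance inputs
#' yield a missing estimate rather than an error.
#'
#' @param scores A `maturity_scores` tibble.
#' @param meta Metadata carrying the anthropometric columns.
#' @param indices Metadata columns to correlate against (default WHZ, HAZ,
#'   WAZ).
#' @param score_col Which maturity score to use (default `"MAZ"`).
#'
#' @return An association tibble: `feature_a`, `feature_b`, `method`,
#'   `estimate`, `p`, `q`, `n_pairs`.
#' @export
maturity_anthropometry_correlation <- function(scores, meta,
                                               indices = c("WHZ", "HAZ", "WAZ"),
                                               score_col = "MAZ") {
  indices <- intersect(indices, names(meta))
  if (length(indices) == 0) {
    abort("none of the requested indices are present in `meta`",
          class = "gutmaturity_validation_error")
  }
  dat <- dplyr::inner_join(scores, meta[c("sample_id", indices)],
                           by = "sample_id")
  x <- tibble::tibble(sample_id = dat$sample_id, score = dat[[score_col]])
  names(x)[2] <- score_col
  correlation_table(x, dat[c("sample_id", indices)], method = "pearson")
}
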