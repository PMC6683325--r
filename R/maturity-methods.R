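# S3 methods for the fitted maturity model and its scores.

#' @export
print.maturity_model <- function(x, ...) {
  cat("Microbiota-age maturity model\n")
  cat("  features (full):   ", length(x$features), "\n", sep = "")
  if (!is.null(x$sparse_features)) {
    cat("  sparse model size: ", length(x$sparse_features), "\n", sep = "")
  } else {
    cat("  sparse model size:  <not sparsified>\n")
  }
  cat("  training samples:  ", length(x$train$age), " (",
      length(unique(x$train$subject)), " subjects)\n", sep = "")
  cat("  age range (months): ", paste(range(x$train$age), collapse = " - "),
      "\n", sep = "")
  cat("  calibrated:        ", !is.null(x$calibration), "\n", sep = "")
  invisible(x)
}

#' Tidy the feature-importance ranking of a maturity model
#'
#' @param x A `maturity_model`.
#' @param ... Unused.
#' @return A tibble of features ranked by out-of-bag permutation importance,
#'   with a logical `sparse` column once [sparsify()] has been run.
#' @method tidy maturity_model
#' @export
tidy.maturity_model <- function(x, ...) {
  out <- x$full_importances
  out$sparse <- if (is.null(x$sparse_features)) NA else
    out$feature_id %in% x$sparse_features
  out
}

#' One-row summary of a maturity model
#'
#' @param x A `maturity_model`.
#' @param ... Unused.
#' @return A one-row tibble: feature counts, selected sparse size, grouped-CV
#'   MAE at the selected size, out-of-fold R-squared (when calibrated), and
#'   forest settings.
#' @method glance maturity_model
#' @export
glance.maturity_model <- function(x, ...) {
  cv_mae <- if (!is.null(x$cv_curve) && !is.null(x$sparse_features)) {
    x$cv_curve$cv_mae[match(length(x$sparse_features), x$cv_curve$n_features)]
  } else {
    NA_real_
  }
  oof_r2 <- if (!is.null(x$calibration)) {
    oof <- x$calibration$oof
    1 - sum((oof$predicted_age - oof$age)^2) / sum((oof$age - mean(oof$age))^2)
  } else {
    NA_real_
  }
  tibble::tibble(
    n_features = length(x$features),
    n_sparse = if (is.null(x$sparse_features)) NA_integer_ else length(x$sparse_features),
    cv_mae = cv_mae,
    oof_r_squared = oof_r2,
    num_trees = x$hyper$num_trees,
    n_samples = length(x$train$age),
    n_subjects = length(unique(x$train$subject))
  )
}

#' Plot the sparsification cross-validation curve
#'
#' Grouped-CV mean absolute error (+/- 1 SE) against sparse-model size, with
#' the selected size marked.
#'
#' @param object A sparsified `maturity_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot maturity_model
#' @export
autoplot.maturity_model <- function(object, ...) {
  if (is.null(object$cv_curve)) {
    abort("no cv_curve: run sparsify() first",
          class = "gutmaturity_validation_error")
  }
  curve <- object$cv_curve
  n_sel <- length(object$sparse_features)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_features, y = .data$cv_mae)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cv_mae - .data$se,
                                      ymax = .data$cv_mae + .data$se),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = n_sel, linetype = "dashed") +
    ggplot2::labs(x = "sparse model size (features)",
                  y = "grouped-CV MAE (months)",
                  title = sprintf("Sparse model selection: %d features", n_sel))
}

#' Plot maturity scores against chronological age
#'
#' Microbiota age versus chronological age, with the healthy-reference
#' calibration medians overlaid when the model is supplied.
#'
#' @param object A `maturity_scores` tibble.
#' @param model Optional calibrated `maturity_model` whose reference medians
#'   are drawn as a step line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot maturity_scores
#' @export
autoplot.maturity_scores <- function(object, model = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$age,
                                            y = .data$microbiota_age)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "chronological age (months)",
                  y = "microbiota age (months)")
  if (!is.null(model) && !is.null(model$calibration)) {
    bins <- model$calibration$bins
    ref <- tibble::tibble(age = (bins$bin_lo + bins$bin_hi) / 2,
                          microbiota_age = bins$median_pred_age)
    p <- p + ggplot2::geom_step(data = ref, colour = "firebrick")
  }
  p
}
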