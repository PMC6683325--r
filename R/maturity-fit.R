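# Sparse random-forest microbiota-age model: fitting, feature sparsification,
# and healthy-reference calibration. The same code path serves taxonomic
# (OTU/strain) tables and functional pathway-module tables.

# Assign each subject to one of k folds, balanced, deterministically.
assign_subject_folds <- function(subjects, k, seed) {
  subjects <- sort(unique(subjects))
  if (length(subjects) < k) {
    abort(paste0("only ", length(subjects), " subjects but ", k,
                 " folds requested; reduce `n_folds` to at most the number of subjects"),
          class = "gutmaturity_validation_error")
  }
  with_op_seed(seed, "folds", {
    fold <- sample(rep(seq_len(k), length.out = length(subjects)))
  })
  setNames(fold, subjects)
}

fit_ranger <- function(x, y, hyper, seed, importance = "none") {
  mtry <- hyper$mtry %||% ceiling(ncol(x) / 3)
  ranger::ranger(
    x = x, y = y,
    num.trees = hyper$num_trees,
    mtry = min(mtry, ncol(x)),
    min.node.size = hyper$min_node_size,
    importance = importance,
    seed = seed,
    num.threads = 1
  )
}

# Align a table's feature columns to `features`: drop extras, zero-fill
# absences (warning), error if more than half are missing.
align_features <- function(table, features) {
  missing <- setdiff(features, names(table))
  if (length(missing) > length(features) / 2) {
    abort(paste0(length(missing), " of ", length(features),
                 " model features are missing from the table; ",
                 "this looks like a model/table mismatch"),
          class = "gutmaturity_validation_error")
  }
  if (length(missing) > 0) {
    warn(paste0("zero-filling ", length(missing),
                " model features absent from the table: ",
                paste(head(missing, 5), collapse = ", ")))
    for (f in missing) table[[f]] <- 0
  }
  as.data.frame(table[features])
}

prepare_training_data <- function(table, meta) {
  table <- validate_abundance_table(table)
  if (!all(c("sample_id", "subject_id", "age") %in% names(meta))) {
    abort("metadata needs columns sample_id, subject_id, age",
          class = "gutmaturity_validation_error")
  }
  if ("cohort" %in% names(meta) && any(meta$cohort != "healthy")) {
    n_drop <- sum(meta$cohort != "healthy")
    inform(paste0("dropping ", n_drop,
                  " non-healthy samples from the reference fit"))
    meta <- dplyr::filter(meta, .data$cohort == "healthy")
  }
  dat <- dplyr::inner_join(meta, table, by = "sample_id")
  if (anyNA(dat$age)) {
    abort("every training sample must have an age",
          class = "gutmaturity_validation_error")
  }
  if (length(unique(dat$subject_id)) < 2) {
    abort("need at least 2 subjects to fit a reference model",
          class = "gutmaturity_validation_error")
  }
  list(x = as.data.frame(dat[feature_ids(table)]),
       age = dat$age, subject = dat$subject_id, sample_id = dat$sample_id)
}

#' Fit the full (pre-sparsification) microbiota-age random forest
#'
#' Trains a random-forest regression of chronological age (months) on
#' relative feature abundances in a healthy reference cohort, and ranks every
#' feature by out-of-bag permutation importance. The table may hold taxa or
#' functional pathway modules; the model is agnostic. Follow with
#' [sparsify()] to reduce to the most age-discriminatory features and
#' [calibrate()] to build the healthy reference statistics that MAZ scoring
#' needs.
#'
#' @param table Abundance tibble: `sample_id` column plus one numeric column
#'   per feature; rows sum to 1.
#' @param meta Sample metadata with `sample_id`, `subject_id`, `age`
#'   (months); if a `cohort` column is present, non-healthy samples are
#'   dropped with a message.
#' @param num_trees,mtry,min_node_size Forest hyperparameters. `mtry`
#'   defaults to one third of the feature count (rounded up).
#' @param seed Integer seed controlling the forest and all downstream
#'   cross-validation splits.
#'
#' @return A `maturity_model` object; see [tidy.maturity_model()] for the
#'   importance ranking and [glance.maturity_model()] for a fit summary.
#' @export
#' @examples
#' tr <- taxon_trajectories(20, 10, seed = 5)
#' ch <- generate_healthy_cohort(cohort_config(n_subjects = 6,
#'   sampling_ages = seq(2, 22, by = 4), n_taxa = 20, n_discriminatory = 10,
#'   seed = 5), tr)
#' m <- fit_age_model(ch$table, ch$meta, num_trees = 100, seed = 5)
#' head(tidy(m))
fit_age_model <- function(table, meta, num_trees = 500, mtry = NULL,
                          min_node_size = 5, seed = 1) {
  train <- prepare_training_data(table, meta)
  hyper <- list(num_trees = num_trees, mtry = mtry,
                min_node_size = min_node_size)
  rf <- fit_ranger(train$x, train$age, hyper,
                   seed = derive_seed(seed, "full_fit"),
                   importance = "permutation")
  imp <- rf$variable.importance
  # rank by importance, ties broken lexicographically by feature id
  ord <- order(-imp, names(imp))
  full_importances <- tibble::tibble(
    feature_id = names(imp)[ord],
    importance = unname(imp[ord]),
    rank = seq_along(imp)
  )
  structure(list(
    regressor = rf,
    features = names(train$x),
    full_importances = full_importances,
    sparse_features = NULL,
    cv_curve = NULL,
    calibration = NULL,
    hyper = hyper,
    seed = seed,
    train = train
  ), class = "maturity_model")
}

# Grouped-CV out-of-fold predictions for a given feature subset.
oof_predictions <- function(train, features, hyper, n_folds, seed) {
  folds <- assign_subject_folds(train$subject, n_folds, seed)
  fold_of_sample <- folds[train$subject]
  pred <- rep(NA_real_, length(train$age))
  for (f in seq_len(n_folds)) {
    test_idx <- which(fold_of_sample == f)
    train_idx <- which(fold_of_sample != f)
    rf <- fit_ranger(train$x[train_idx, features, drop = FALSE],
                     train$age[train_idx], hyper,
                     seed = derive_seed(seed, paste0("cvfit", f)))
    pred[test_idx] <- predict(
      rf, data = train$x[test_idx, features, drop = FALSE],
      num.threads = 1)$predictions
  }
  list(pred = pred, fold = unname(fold_of_sample))
}

#' Select the sparse age-discriminatory feature set
#'
#' Evaluates nested models on the top-n ranked features (by permutation
#' importance) over a grid of n, using cross-validation grouped by subject so
#' that no child contributes samples to both the training and test side of a
#' split. Selects the smallest n whose grouped-CV mean absolute error is
#' within one standard error of the minimum, then refits the forest on that
#' subset. The default ceiling of 30 features matches the size at which such
#' community-maturity models are conventionally reported.
#'
#' @param model A `maturity_model` from [fit_age_model()].
#' @param max_features Largest sparse-model size considered (clipped to the
#'   number of available features, with a warning).
#' @param n_folds Grouped cross-validation folds.
#' @param grid Candidate sizes; defaults to `2:max_features`.
#'
#' @return The model with `sparse_features` and `cv_curve` filled in and the
#'   regressor refit on the sparse subset.
#' @export
sparsify <- function(model, max_features = 30, n_folds = 5, grid = NULL) {
  stopifnot(inherits(model, "maturity_model"))
  p <- length(model$features)
  if (max_features > p) {
    warn(paste0("`max_features` (", max_features, ") exceeds the ", p,
                " available features; clipping"))
    max_features <- p
  }
  grid <- grid %||% seq(2L, max_features)
  grid <- sort(unique(pmin(grid, p)))
  ranked <- model$full_importances$feature_id

  curve <- purrr::map_dfr(grid, function(n) {
    oof <- oof_predictions(model$train, ranked[seq_len(n)], model$hyper,
                           n_folds, derive_seed(model$seed, "sparsify"))
    fold_mae <- tapply(abs(oof$pred - model$train$age), oof$fold, mean)
    tibble::tibble(n_features = n, cv_mae = mean(fold_mae),
                   se = sd(fold_mae) / sqrt(length(fold_mae)))
  })
  best <- which.min(curve$cv_mae)
  threshold <- curve$cv_mae[best] + curve$se[best]
  chosen <- curve$n_features[min(which(curve$cv_mae <= threshold))]

  model$cv_curve <- curve
  model$sparse_features <- ranked[seq_len(chosen)]
  model$regressor <- fit_ranger(
    model$train$x[model$sparse_features], model$train$age, model$hyper,
    seed = derive_seed(model$seed, "sparse_fit"))
  model$calibration <- NULL  # any earlier calibration refers to the old fit
  model
}

# Merge monthly age bins left-to-right until every bin holds >= min_n samples.
merge_age_bins <- function(ages, min_n) {
  lo <- floor(min(ages))
  hi <- ceiling(max(ages))
  if (hi == lo) hi <- lo + 1
  edges <- seq(lo, hi)
  counts <- tabulate(findInterval(ages, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  # greedy left-to-right: extend each bin rightwards until it holds >= min_n;
  # a short leftover tail is absorbed into the last emitted bin
  bin_lo <- numeric(0)
  bin_hi <- numeric(0)
  acc <- 0
  start <- edges[1]
  for (i in seq_along(counts)) {
    acc <- acc + counts[i]
    if (acc >= min_n) {
      bin_lo <- c(bin_lo, start)
      bin_hi <- c(bin_hi, edges[i + 1])
      start <- edges[i + 1]
      acc <- 0
    }
  }
  if (acc > 0) {
    if (length(bin_hi) > 0) {
      bin_hi[length(bin_hi)] <- edges[length(edges)]
    } else {
      bin_lo <- edges[1]
      bin_hi <- edges[length(edges)]
    }
  }
  tibble::tibble(bin_lo = bin_lo, bin_hi = bin_hi)
}

#' Calibrate the healthy reference for MAZ scoring
#'
#' Computes out-of-fold (subject-grouped cross-validation) microbiota-age
#' predictions for the healthy training samples, bins them by chronological
#' age (monthly bins, merged until each holds at least `min_bin_n` samples),
#' and stores the per-bin median and SD of predicted age. These reference
#' statistics define MAZ: the deviation of a sample's microbiota age from the
#' healthy median at the same chronological age, in units of the healthy SD.
#' Out-of-fold rather than resubstitution predictions are used so the
#' reference is not optimistically tight.
#'
#' @param model A sparsified `maturity_model`.
#' @param n_folds Grouped CV folds used for the out-of-fold predictions.
#' @param min_bin_n Minimum healthy samples per calibration bin.
#' @param sd_floor Lower bound (months) applied to any bin SD; degenerate
#'   near-zero spreads are floored and flagged rather than allowed to blow up
#'   the z-scores.
#'
#' @return The model with a `calibration` element: `bins` (bin edges, n,
#'   median and SD of predicted age, floor flag) and `oof` (the per-sample
#'   out-of-fold predictions the bins were built from).
#' @export
calibrate <- function(model, n_folds = 5, min_bin_n = 10, sd_floor = 0.25) {
  stopifnot(inherits(model, "maturity_model"))
  if (is.null(model$sparse_features)) {
    abort("run sparsify() before calibrate()",
          class = "gutmaturity_validation_error")
  }
  if (length(model$train$age) < min_bin_n) {
    abort(paste0("cannot calibrate: fewer than ", min_bin_n,
                 " healthy reference samples"),
          class = "gutmaturity_validation_error")
  }
  oof <- oof_predictions(model$train, model$sparse_features, model$hyper,
                         n_folds, derive_seed(model$seed, "calibrate"))
  bins <- merge_age_bins(model$train$age, min_bin_n)
  oof_tbl <- tibble::tibble(sample_id = model$train$sample_id,
                            age = model$train$age,
                            predicted_age = oof$pred)
  stats <- purrr::map_dfr(seq_len(nrow(bins)), function(i) {
    last <- i == nrow(bins)
    sel <- oof_tbl$age >= bins$bin_lo[i] &
      (oof_tbl$age < bins$bin_hi[i] | (last & oof_tbl$age <= bins$bin_hi[i]))
    tibble::tibble(n = sum(sel),
                   median_pred_age = median(oof_tbl$predicted_age[sel]),
                   sd_pred_age = sd(oof_tbl$predicted_age[sel]))
  })
  bins <- dplyr::bind_cols(bins, stats)
  if (any(bins$n == 0)) {
    abort("empty calibration bin after merging",
          class = "gutmaturity_validation_error")
  }
  bins$sd_floored <- !is.na(bins$sd_pred_age) & bins$sd_pred_age < sd_floor
  if (any(bins$sd_floored)) {
    inform(paste0("SD floor (", sd_floor, " months) applied in ",
                  sum(bins$sd_floored), " calibration bin(s)"))
  }
  bins$sd_pred_age <- pmax(bins$sd_pred_age, sd_floor)
  model$calibration <- list(bins = bins, oof = oof_tbl,
                            age_range = range(model$train$age))
  model
}
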