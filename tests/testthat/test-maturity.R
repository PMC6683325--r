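# Microbiota-age model: grouped CV, sparsification rule, calibration and MAZ.

test_that("an all-neutral cohort carries no age signal (held-out R^2 near 0)", {
  tr <- taxon_trajectories(20, 0, seed = 8)
  ch <- generate_healthy_cohort(
    cohort_config(n_subjects = 10, sampling_ages = seq(1, 23, by = 2),
                  n_taxa = 20, n_discriminatory = 0, seed = 8), tr)
  m <- fit_age_model(ch$table, ch$meta, num_trees = 200, seed = 8)
  oof <- gutmaturity:::oof_predictions(m$train, m$features, m$hyper,
                                       n_folds = 5, seed = 8)
  r2 <- 1 - sum((oof$pred - m$train$age)^2) /
    sum((m$train$age - mean(m$train$age))^2)
  expect_lte(r2, 0.1)
})

test_that("planted discriminatory taxa dominate the importance ranking", {
  ref <- small_reference()
  top <- head(ref$model$full_importances$feature_id,
              length(ref$cohort$ground_truth))
  expect_gte(mean(ref$cohort$ground_truth %in% top), 0.8)
})

test_that("refitting with the same seed reproduces ranking, sparse set and predictions", {
  tr <- taxon_trajectories(16, 8, seed = 13)
  ch <- generate_healthy_cohort(
    cohort_config(n_subjects = 6, sampling_ages = seq(2, 22, by = 5),
                  n_taxa = 16, n_discriminatory = 8, seed = 13), tr)
  fit_once <- function() {
    m <- fit_age_model(ch$table, ch$meta, num_trees = 150, seed = 13)
    sparsify(m, max_features = 10, n_folds = 3, grid = c(2, 5, 8, 10))
  }
  m1 <- fit_once()
  m2 <- fit_once()
  expect_identical(m1$full_importances, m2$full_importances)
  expect_identical(m1$sparse_features, m2$sparse_features)
  expect_identical(microbiota_age(m1, ch$table), microbiota_age(m2, ch$table))
})

test_that("grouped CV never places a subject on both sides of a split", {
  folds <- gutmaturity:::assign_subject_folds(
    rep(sprintf("s%02d", 1:12), each = 5), k = 4, seed = 2)
  expect_length(folds, 12)
  expect_setequal(unique(folds), 1:4)
  # every sample of a subject inherits exactly that subject's single fold,
  # so train/test membership is decided per subject by construction
  sample_folds <- folds[rep(sprintf("s%02d", 1:12), each = 5)]
  per_subject <- tapply(sample_folds, rep(sprintf("s%02d", 1:12), each = 5),
                        function(x) length(unique(x)))
  expect_true(all(per_subject == 1))
  expect_error(gutmaturity:::assign_subject_folds(c("a", "b"), k = 3, seed = 1),
               "reduce", class = "gutmaturity_validation_error")
})

test_that("sparsification selects a small model when signal sits in few features", {
  # 5 strong discriminatory taxa dominating the community; the neutral
  # remainder is a small-share background so closure leaks little age signal
  tr <- taxon_trajectories(25, 5, seed = 21, amplitude = 4)
  tr$baseline_log_abundance <- ifelse(tr$phase == "neutral", -2, 2)
  ch <- generate_healthy_cohort(
    cohort_config(n_subjects = 10, sampling_ages = seq(1, 24, by = 2),
                  n_taxa = 25, n_discriminatory = 5, seed = 21), tr)
  m <- fit_age_model(ch$table, ch$meta, num_trees = 200, seed = 21)
  m <- sparsify(m, max_features = 20, n_folds = 5)
  expect_lte(length(m$sparse_features), 10)
  expect_equal(m$cv_curve$n_features, 2:20)
  # selection obeys the one-SE rule on the recorded curve
  best <- which.min(m$cv_curve$cv_mae)
  thr <- m$cv_curve$cv_mae[best] + m$cv_curve$se[best]
  expect_equal(length(m$sparse_features),
               m$cv_curve$n_features[min(which(m$cv_curve$cv_mae <= thr))])
})

test_that("max_features beyond the feature count is clipped with a warning", {
  ref <- small_reference()
  expect_warning(
    m <- sparsify(ref$model, max_features = 99, n_folds = 3,
                  grid = c(2, 30)),
    "clipping")
  expect_lte(length(m$sparse_features), 30)
})

test_that("monthly calibration bins merge until they hold enough samples", {
  bins <- gutmaturity:::merge_age_bins(rep(1:24, each = 6) + 0.5, min_n = 10)
  expect_true(all(bins$bin_hi - bins$bin_lo == 2))
  expect_equal(bins$bin_lo[1], 1)
  expect_equal(bins$bin_hi[nrow(bins)], 25)
  # a leftover tail shorter than min_n is absorbed into the last bin
  bins2 <- gutmaturity:::merge_age_bins(c(rep(1.5, 10), rep(2.5, 3)), min_n = 10)
  expect_equal(nrow(bins2), 1)
})

test_that("MAZ follows its defining formula and flags out-of-range ages", {
  fake <- structure(list(calibration = list(
    bins = tibble::tibble(bin_lo = c(10, 12), bin_hi = c(12, 14),
                          n = c(20, 20), median_pred_age = c(12, 13),
                          sd_pred_age = c(1.5, 2), sd_floored = FALSE),
    age_range = c(10, 14))), class = "maturity_model")
  scores <- tibble::tibble(sample_id = c("a", "b", "c"),
                           microbiota_age = c(10.5, 13, 20))
  meta <- tibble::tibble(sample_id = c("a", "b", "c"), age = c(11, 12.5, 30))
  expect_warning(out <- maz(scores, meta, fake), "outside")
  expect_equal(out$MAZ[1], -1)                 # (10.5 - 12) / 1.5
  expect_equal(out$relative_maturity[1], -1.5)
  expect_equal(out$MAZ[2], 0)                  # equals the bin median
  expect_true(is.na(out$MAZ[3]))
  expect_false(out$in_calibrated_range[3])
})

test_that("a degenerate (too tight) calibration is floored and flagged", {
  ref <- small_reference()
  expect_message(m <- calibrate(ref$model, n_folds = 5, sd_floor = 50),
                 "floor")
  expect_true(all(m$calibration$bins$sd_floored))
  expect_true(all(m$calibration$bins$sd_pred_age == 50))
})

test_that("scoring zero-fills a few missing model features but rejects a mismatched table", {
  ref <- small_reference()
  model <- ref$model
  table <- ref$cohort$table
  dropped <- model$sparse_features[1]
  dropped_table <- table[setdiff(names(table), dropped)]
  dropped_table[setdiff(names(dropped_table), "sample_id")] <-
    dropped_table[setdiff(names(dropped_table), "sample_id")] /
    rowSums(dropped_table[setdiff(names(dropped_table), "sample_id")])
  expect_warning(pred <- microbiota_age(model, dropped_table), "zero-filling")
  expect_equal(nrow(pred), nrow(table))
  # a table from a different feature catalogue (no overlap) is a mismatch
  other <- generate_healthy_cohort(
    cohort_config(n_subjects = 2, sampling_ages = c(6, 18), n_taxa = 30,
                  n_discriminatory = 10, seed = 77),
    taxon_trajectories(30, 10, seed = 77))$table
  names(other) <- c("sample_id", sprintf("other_%02d", 1:30))
  expect_error(suppressWarnings(microbiota_age(model, other)),
               "mismatch", class = "gutmaturity_validation_error")
})

test_that("healthy out-of-fold MAZ scores are standard-normal-like", {
  ref <- small_reference()
  oof <- ref$model$calibration$oof
  scores <- maz(tibble::tibble(sample_id = oof$sample_id,
                               microbiota_age = oof$predicted_age),
                ref$cohort$meta, ref$model)
  expect_lte(abs(mean(scores$MAZ)), 0.15)
  expect_gt(sd(scores$MAZ), 0.85)
  expect_lt(sd(scores$MAZ), 1.15)
})

test_that("maturity-anthropometry correlation recovers programmed coupling", {
  ref <- small_reference()
  scores <- score_samples(ref$model, ref$cohort$table, ref$cohort$meta)
  set.seed(99)
  meta <- ref$cohort$meta
  meta$WHZ <- 0.3 * scores$MAZ + rnorm(nrow(meta), 0, 0.1)
  res <- maturity_anthropometry_correlation(scores, meta, indices = "WHZ")
  expect_equal(res$feature_b, "WHZ")
  truth <- 0.3 * sd(scores$MAZ) /
    sqrt((0.3 * sd(scores$MAZ))^2 + 0.01)
  expect_equal(res$estimate, truth, tolerance = 0.05)
  expect_lt(res$p, 1e-6)
  # identity: scores correlated with themselves
  meta$WHZ <- scores$MAZ
  expect_equal(maturity_anthropometry_correlation(scores, meta,
                                                  indices = "WHZ")$estimate, 1)
})

test_that("validation errors: missing ages, single subject, abundance drift", {
  tr <- taxon_trajectories(8, 4, seed = 1)
  ch <- generate_healthy_cohort(
    cohort_config(n_subjects = 3, sampling_ages = c(5, 15), n_taxa = 8,
                  n_discriminatory = 4, seed = 1), tr)
  meta_na <- ch$meta
  meta_na$age[1] <- NA
  expect_error(fit_age_model(ch$table, meta_na, num_trees = 50),
               class = "gutmaturity_validation_error")
  one_subject <- ch$meta
  one_subject$subject_id <- "only"
  expect_error(fit_age_model(ch$table, one_subject, num_trees = 50),
               class = "gutmaturity_validation_error")
  bad <- ch$table
  bad[[2]] <- bad[[2]] + 0.5
  expect_error(fit_age_model(bad, ch$meta, num_trees = 50),
               class = "gutmaturity_validation_error")
})
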