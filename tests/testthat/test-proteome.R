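# Discriminatory sets, treatment-effect maps, HAZ correlates and category
# labels.

test_that("discriminatory sets recover planted proteins and respect the threshold", {
  pp <- generate_proteome(proteome_config(n_proteins = 300,
                                          n_true_discriminatory = 20,
                                          n_per_group = 30, seed = 5))
  res <- moderated_differential(pp$panel, pp$meta)
  ds <- discriminatory_sets(res, k = 20)
  expect_gte(sum(ds$healthy_top$protein_id %in% pp$ground_truth$healthy), 18)
  expect_gte(sum(ds$sam_top$protein_id %in% pp$ground_truth$sam), 18)
  expect_length(intersect(ds$healthy_top$protein_id, ds$sam_top$protein_id), 0)
  expect_true(all(ds$healthy_top$p < 1e-7))
  expect_true(all(diff(ds$healthy_top$log2_fold_difference) <= 0))
  expect_true(all(diff(ds$sam_top$log2_fold_difference) >= 0))
})

test_that("an all-null panel yields empty discriminatory sets with a warning", {
  pp <- generate_proteome(proteome_config(n_proteins = 120,
                                          n_true_discriminatory = 0,
                                          log2_effect = 0, n_per_group = 10,
                                          seed = 6))
  res <- moderated_differential(pp$panel, pp$meta)
  expect_warning(ds <- discriminatory_sets(res, k = 50), "fewer than k")
  expect_equal(nrow(ds$healthy_top), 0)
  expect_equal(nrow(ds$sam_top), 0)
})

test_that("noise-free single-recovering-arm map matches the closed-form values", {
  eff <- 2
  pp <- generate_proteome(proteome_config(
    n_proteins = 24, n_true_discriminatory = 4, log2_effect = eff,
    arm_recovery = c(A = 1, B = 0, C = 0, D = 0), noise_sd = 0,
    n_per_group = 3, seed = 7))
  tm <- treatment_effect_map(pp$panel, pp$meta)
  healthy_true <- dplyr::filter(tm, .data$protein_id %in% pp$ground_truth$healthy)
  armA <- dplyr::filter(healthy_true, .data$arm == "A")
  rest <- dplyr::filter(healthy_true, .data$arm != "A")
  expect_equal(armA$normalized_log2_fc, rep(eff * 3 / 4, nrow(armA)))
  expect_equal(rest$normalized_log2_fc, rep(-eff / 4, nrow(rest)))
  # SAM-discriminatory proteins move down by the same arithmetic
  sam_true <- dplyr::filter(tm, .data$protein_id %in% pp$ground_truth$sam,
                            .data$arm == "A")
  expect_equal(sam_true$normalized_log2_fc, rep(-eff * 3 / 4, nrow(sam_true)))
  # untouched proteins: all zeros
  neutral <- dplyr::filter(tm, !.data$protein_id %in% unlist(pp$ground_truth))
  expect_equal(neutral$mean_log2_fc, rep(0, nrow(neutral)))
})

test_that("identical pre and post panels give an all-zero effect map", {
  pp <- generate_proteome(proteome_config(
    n_proteins = 10, n_true_discriminatory = 2, arm_recovery = c(A = 0, B = 0),
    noise_sd = 0, n_per_group = 3, seed = 8))
  tm <- treatment_effect_map(pp$panel, pp$meta)
  expect_equal(tm$mean_log2_fc, rep(0, nrow(tm)))
  expect_equal(tm$normalized_log2_fc, rep(0, nrow(tm)))
})

test_that("arm normalization always sums to zero per protein and ranks the strong arm first", {
  pp <- generate_proteome(proteome_config(
    n_proteins = 150, n_true_discriminatory = 15,
    arm_recovery = c(A = 1, B = 0.3, C = 0.3, D = 0.1), n_per_group = 15,
    seed = 9))
  tm <- treatment_effect_map(pp$panel, pp$meta)
  sums <- tapply(tm$normalized_log2_fc, tm$protein_id, sum)
  expect_lt(max(abs(sums)), 1e-9)
  # arm A shows the largest mean shift DOWN on the planted SAM set
  sam_shift <- tm |>
    dplyr::filter(.data$protein_id %in% pp$ground_truth$sam) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(shift = mean(.data$normalized_log2_fc))
  expect_equal(sam_shift$arm[which.min(sam_shift$shift)], "A")
  healthy_shift <- tm |>
    dplyr::filter(.data$protein_id %in% pp$ground_truth$healthy) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(shift = mean(.data$normalized_log2_fc))
  expect_equal(healthy_shift$arm[which.max(healthy_shift$shift)], "A")
})

test_that("subjects missing a visit are excluded with a message", {
  pp <- generate_proteome(proteome_config(
    n_proteins = 10, n_true_discriminatory = 2, arm_recovery = c(A = 0.5),
    n_per_group = 5, seed = 10))
  incomplete <- pp$meta$sample_id[match("A_subj_001_post", pp$meta$sample_id)]
  panel <- pp$panel[pp$panel$sample_id != incomplete, ]
  meta <- pp$meta[pp$meta$sample_id != incomplete, ]
  expect_message(tm <- treatment_effect_map(panel, meta), "missing a visit")
  expect_equal(unique(tm$n_subjects), 4)
})

test_that("HAZ correlates find a planted coupling and reject constant HAZ", {
  set.seed(31)
  n <- 113
  ids <- sprintf("s%03d", 1:n)
  haz <- rnorm(n)
  m <- matrix(rnorm(n * 40), n, dimnames = list(ids, sprintf("p%02d", 1:40)))
  # plant r ~ 0.5 couplings in the first 4 proteins, negative in the next 4
  for (j in 1:4) m[, j] <- haz + rnorm(n, 0, sqrt(3))
  for (j in 5:8) m[, j] <- -haz + rnorm(n, 0, sqrt(3))
  panel <- gutmaturity:::matrix_to_table(m)
  meta <- tibble::tibble(sample_id = ids, HAZ = haz)
  hz <- haz_correlates(panel, meta)
  expect_setequal(hz$protein_id[hz$set == "positive"], sprintf("p%02d", 1:4))
  expect_setequal(hz$protein_id[hz$set == "negative"], sprintf("p%02d", 5:8))
  # identity: a protein equal to HAZ itself
  m[, 9] <- haz
  hz2 <- haz_correlates(gutmaturity:::matrix_to_table(m), meta)
  expect_equal(hz2$r[9], 1)
  expect_equal(hz2$set[9], "positive")
  meta$HAZ <- 1
  expect_error(haz_correlates(panel, meta),
               class = "gutmaturity_validation_error")
  expect_error(haz_correlates(panel[1:5, ], meta[1:5, ]),
               class = "gutmaturity_validation_error")
})

test_that("null HAZ screens rarely admit a protein (FDR calibration)", {
  false_pos <- sapply(1:30, function(i) {
    set.seed(400 + i)
    n <- 60
    m <- matrix(rnorm(n * 100), n,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("p%03d", 1:100)))
    meta <- tibble::tibble(sample_id = rownames(m), HAZ = rnorm(n))
    sum(haz_correlates(gutmaturity:::matrix_to_table(m), meta)$set != "none")
  })
  expect_lt(mean(false_pos), 1)
})

test_that("category labels apply the strict 30% fold rule per direction", {
  results <- tibble::tibble(
    protein_id = c("up_strong", "up_boundary", "up_weak_q", "down_strong",
                   "null_p"),
    log2_fold_difference = c(1, log2(1.3), 1, -1, 0.01),
    moderated_t = 0, p = c(1e-9, 1e-9, 1e-9, 1e-9, 0.9),
    q = c(1e-8, 1e-8, 0.2, 1e-8, 0.95),
    df_prior = 4, df_total = 10, constant = FALSE
  )
  cats <- list(bone = c("up_strong", "up_boundary", "up_weak_q", "down_strong",
                        "null_p", "not_measured"))
  expect_warning(lab <- category_discriminatory_labels(results, cats),
                 "absent")
  expect_equal(nrow(lab), 5)  # unknown id dropped
  labs <- setNames(lab$label, lab$protein_id)
  expect_equal(unname(labs["up_strong"]), "healthy_growth_discriminatory")
  expect_equal(unname(labs["up_boundary"]), "none")  # exactly 30%: excluded
  expect_equal(unname(labs["up_weak_q"]), "none")    # fails FDR
  expect_equal(unname(labs["down_strong"]), "SAM_discriminatory")
  expect_equal(unname(labs["null_p"]), "none")
})

test_that("a planted half-shifted category is labeled exactly", {
  pp <- generate_proteome(proteome_config(
    n_proteins = 60, n_true_discriminatory = 10, log2_effect = 1,
    arm_recovery = c(A = 0.5), noise_sd = 0.2, n_per_group = 25, seed = 12))
  res <- moderated_differential(pp$panel, pp$meta)
  cat_members <- c(pp$ground_truth$healthy, sprintf("prot_%04d", 41:50))
  lab <- category_discriminatory_labels(res, list(planted = cat_members))
  labelled <- lab$protein_id[lab$label == "healthy_growth_discriminatory"]
  expect_setequal(labelled, pp$ground_truth$healthy)
})
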