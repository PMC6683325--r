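#' Build a set of taxon age-trajectories for the cohort simulator
#'
#' Defines, per taxon, a two-parameter logistic trajectory in log abundance
#' over the first 24 months of life. Discriminatory taxa are split between a
#' milk phase (abundant early, declining through weaning) and a weaning phase
#' (rising with age); the remainder are neutral, with age-constant expected
#' log abundance. The community composition at age `a` is the softmax of the
#' per-taxon log abundances, so succession is relative, as in real
#' compositional data.
#'
#' @param n_taxa Total number of taxa.
#' @param n_discriminatory Number of age-discriminatory taxa (split evenly
#'   between milk and weaning phases).
#' @param seed Integer seed; trajectories are deterministic given the seed.
#' @param amplitude Total swing of the logistic in log-abundance units.
#'
#' @return A tibble with one row per taxon: `feature_id`, `phase`
#'   (milk/weaning/neutral), `midpoint_age` (months), `slope` (per-month
#'   logit rate), `baseline_log_abundance`, `direction` (+1 rises with age,
#'   -1 declines, 0 neutral) and `amplitude`.
#' @export
#' @examples
#' taxon_trajectories(10, 4, seed = 1)
taxon_trajectories <- function(n_taxa, n_discriminatory, seed = 1,
                               amplitude = 4) {
  n_taxa <- check_count(n_taxa, "n_taxa")
  n_discriminatory <- check_count(n_discriminatory, "n_discriminatory", min = 0)
  if (n_discriminatory > n_taxa) {
    abort("`n_discriminatory` cannot exceed `n_taxa`",
          class = "gutmaturity_validation_error")
  }
  n_milk <- floor(n_discriminatory / 2)
  n_wean <- n_discriminatory - n_milk
  with_op_seed(seed, "trajectories", {
    phase <- c(rep("milk", n_milk), rep("weaning", n_wean),
               rep("neutral", n_taxa - n_discriminatory))
    tibble::tibble(
      feature_id = sprintf("taxon_%03d", seq_len(n_taxa)),
      phase = phase,
      midpoint_age = ifelse(phase == "neutral", 12, runif(n_taxa, 4, 20)),
      slope = ifelse(phase == "neutral", 0, runif(n_taxa, 0.4, 1.2)),
      baseline_log_abundance = rnorm(n_taxa, 0, 1),
      direction = dplyr::case_when(phase == "milk" ~ -1,
                                   phase == "weaning" ~ 1,
                                   TRUE ~ 0),
      amplitude = amplitude
    )
  })
}

validate_trajectories <- function(trajectories) {
  need <- c("feature_id", "phase", "midpoint_age", "slope",
            "baseline_log_abundance", "direction")
  if (!is.data.frame(trajectories) || !all(need %in% names(trajectories))) {
    abort(paste0("trajectories must contain columns: ",
                 paste(need, collapse = ", ")),
          class = "gutmaturity_validation_error")
  }
  if (anyDuplicated(trajectories$feature_id)) {
    abort("duplicated feature ids in trajectories",
          class = "gutmaturity_validation_error")
  }
  bad_dir <- (trajectories$phase == "milk" & trajectories$direction != -1) |
    (trajectories$phase == "weaning" & trajectories$direction != 1) |
    (trajectories$phase == "neutral" & trajectories$slope != 0)
  if (any(bad_dir)) {
    abort("trajectory phase/direction/slope combination violates invariants",
          class = "gutmaturity_validation_error")
  }
  if (any(trajectories$midpoint_age < 0 | trajectories$midpoint_age > 24)) {
    abort("midpoint_age must lie in [0, 24]",
          class = "gutmaturity_validation_error")
  }
  if (!"amplitude" %in% names(trajectories)) trajectories$amplitude <- 4
  trajectories
}

# Expected (deterministic) composition at a vector of ages: softmax over taxa
# of the logistic log-abundance curves. Returns length(ages) x n_taxa matrix.
expected_composition <- function(trajectories, ages) {
  tr <- validate_trajectories(trajectories)
  loga <- vapply(ages, function(a) {
    tr$baseline_log_abundance +
      tr$direction * tr$amplitude * stats::plogis(tr$slope * (a - tr$midpoint_age))
  }, numeric(nrow(tr)))
  comp <- apply(loga, 2, softmax)
  t(comp)
}

#' Configuration for the synthetic birth-cohort generator
#'
#' @param n_subjects Number of subjects.
#' @param sampling_ages Ages (months) at which every subject is sampled.
#' @param n_taxa Total taxa in the community.
#' @param n_discriminatory Number of age-discriminatory taxa.
#' @param immaturity_factor Age-compression factor `c` in (0, 1]: a sample
#'   taken at chronological age `a` is drawn from the healthy generative law
#'   at effective age `c * a`. `c = 1` is healthy development.
#' @param dispersion Dirichlet concentration scalar; larger values give
#'   samples closer to the expected composition.
#' @param seed Integer seed.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 25, sampling_ages = 1:24, n_taxa = 60,
                          n_discriminatory = 30, immaturity_factor = 1,
                          dispersion = 300, seed = 1) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_taxa <- check_count(n_taxa, "n_taxa")
  n_discriminatory <- check_count(n_discriminatory, "n_discriminatory", min = 0)
  if (n_discriminatory > n_taxa) {
    abort("`n_discriminatory` cannot exceed `n_taxa`",
          class = "gutmaturity_validation_error")
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    abort("`dispersion` must be positive",
          class = "gutmaturity_validation_error")
  }
  if (!is.numeric(immaturity_factor) || immaturity_factor <= 0 ||
      immaturity_factor > 1) {
    abort("`immaturity_factor` must lie in (0, 1]",
          class = "gutmaturity_validation_error")
  }
  structure(list(n_subjects = n_subjects, sampling_ages = sampling_ages,
                 n_taxa = n_taxa, n_discriminatory = n_discriminatory,
                 immaturity_factor = immaturity_factor,
                 dispersion = dispersion, seed = seed),
            class = "cohort_config")
}

generate_cohort_samples <- function(config, trajectories, cohort_label) {
  tr <- validate_trajectories(trajectories)
  if (nrow(tr) != config$n_taxa) {
    abort("trajectories must cover exactly `n_taxa` features",
          class = "gutmaturity_validation_error")
  }
  ages <- config$sampling_ages
  grid <- tidyr::expand_grid(
    subject_id = sprintf("subj_%03d", seq_len(config$n_subjects)),
    age = ages
  )
  grid$sample_id <- sprintf("%s_m%05.1f", grid$subject_id, grid$age)
  eff_age <- config$immaturity_factor * grid$age
  comp <- expected_composition(tr, eff_age)

  with_op_seed(config$seed, "cohort_samples", {
    values <- if (is.infinite(config$dispersion)) {
      comp
    } else {
      rdirichlet_rows(config$dispersion * comp)
    }
    colnames(values) <- tr$feature_id
    rownames(values) <- grid$sample_id
    whz_mean <- switch(cohort_label, healthy = 0, MAM = -2.5, SAM = -3.5, 0)
    meta <- tibble::tibble(
      sample_id = grid$sample_id,
      subject_id = grid$subject_id,
      age = grid$age,
      cohort = cohort_label,
      WHZ = rnorm(nrow(grid), whz_mean, 0.5),
      HAZ = rnorm(nrow(grid), whz_mean / 2, 0.8),
      WAZ = rnorm(nrow(grid), whz_mean / 2, 0.8),
      timepoint = sprintf("m%g", grid$age),
      arm = NA_character_
    )
    list(table = matrix_to_table(values), meta = meta)
  })
}

#' Generate a synthetic healthy reference birth cohort
#'
#' Emulates a healthy cohort sampled repeatedly over the first two years of
#' life: each sample's expected composition is the softmax of the taxon
#' log-abundance trajectories at the sample's age, and the observed
#' composition is a Dirichlet draw centred on it (concentration =
#' `dispersion` times the expected proportions). Milk-phase taxa decline and
#' weaning-phase taxa rise with age; neutral taxa carry no age signal.
#'
#' @param config A [cohort_config()] with `immaturity_factor = 1`.
#' @param trajectories Taxon trajectories from [taxon_trajectories()].
#'
#' @return A list with `table` (abundance tibble, rows sum to 1), `meta`
#'   (sample metadata tibble) and `ground_truth` (character vector of the
#'   age-discriminatory feature ids).
#' @export
#' @examples
#' tr <- taxon_trajectories(12, 6, seed = 2)
#' ch <- generate_healthy_cohort(cohort_config(n_subjects = 3, n_taxa = 12,
#'                                             n_discriminatory = 6, seed = 2), tr)
#' dim(ch$table)
generate_healthy_cohort <- function(config, trajectories) {
  if (config$immaturity_factor != 1) {
    abort("healthy cohort requires `immaturity_factor = 1`",
          class = "gutmaturity_validation_error")
  }
  out <- generate_cohort_samples(config, trajectories, "healthy")
  out$ground_truth <-
    trajectories$feature_id[trajectories$phase != "neutral"]
  out
}

#' Generate a cohort with programmed microbiota immaturity
#'
#' Each sample taken at chronological age `a` is drawn from the healthy
#' generative law evaluated at effective age `c * a`, where
#' `c = immaturity_factor < 1`. Metadata records the chronological age, so a
#' healthy-trained age model scores these communities as resembling
#' chronologically younger children.
#'
#' @param config A [cohort_config()] with `immaturity_factor` in (0, 1).
#' @param trajectories Taxon trajectories from [taxon_trajectories()].
#' @param cohort_label Cohort label recorded in metadata (default "SAM").
#'
#' @return A list with `table` and `meta` tibbles.
#' @export
generate_immature_cohort <- function(config, trajectories,
                                     cohort_label = "SAM") {
  # c = 1 is allowed and reproduces the healthy generative law exactly;
  # cohort_config() already rejects c outside (0, 1].
  generate_cohort_samples(config, trajectories, cohort_label)
}
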