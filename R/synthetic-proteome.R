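#' Configuration for the synthetic plasma-proteome generator
#'
#' @param n_proteins Total proteins on the panel.
#' @param n_true_discriminatory Number of planted discriminatory proteins per
#'   direction (higher in healthy, and higher in SAM).
#' @param log2_effect Mean log2 shift between healthy and SAM groups on the
#'   planted proteins.
#' @param arm_recovery Named numeric vector, one entry per treatment arm, each
#'   in \[0, 1\]: the fraction of the healthy-vs-SAM effect reversed from the
#'   pre- to the post-intervention visit in that arm.
#' @param noise_sd Gaussian noise SD on the log2 scale (also used for the
#'   per-subject intercept, so paired visits share subject-level variation).
#' @param n_per_group Subjects per group (healthy, SAM, and per arm).
#' @param seed Integer seed.
#'
#' @return A `proteome_config` list.
#' @export
proteome_config <- function(n_proteins = 1305, n_true_discriminatory = 50,
                            log2_effect = 1,
                            arm_recovery = c(A = 1, B = 0.3, C = 0.3, D = 0.1),
                            noise_sd = 0.5, n_per_group = 30, seed = 1) {
  n_proteins <- check_count(n_proteins, "n_proteins")
  n_true_discriminatory <- check_count(n_true_discriminatory,
                                       "n_true_discriminatory", min = 0)
  if (2 * n_true_discriminatory > n_proteins) {
    abort("need `n_true_discriminatory * 2 <= n_proteins`",
          class = "gutmaturity_validation_error")
  }
  if (is.null(names(arm_recovery)) || any(!nzchar(names(arm_recovery)))) {
    abort("`arm_recovery` must be a named vector (one name per arm)",
          class = "gutmaturity_validation_error")
  }
  if (any(arm_recovery < 0 | arm_recovery > 1)) {
    abort("`arm_recovery` values must lie in [0, 1]",
          class = "gutmaturity_validation_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be >= 0", class = "gutmaturity_validation_error")
  }
  structure(list(n_proteins = n_proteins,
                 n_true_discriminatory = n_true_discriminatory,
                 log2_effect = log2_effect, arm_recovery = arm_recovery,
                 noise_sd = noise_sd,
                 n_per_group = check_count(n_per_group, "n_per_group"),
                 seed = seed),
            class = "proteome_config")
}

#' Generate synthetic plasma-proteome panels with planted group shifts
#'
#' Emulates an aptamer-panel proteome experiment: a healthy reference group, a
#' SAM (severe acute malnutrition) group, and, per treatment arm, paired pre-
#' and post-intervention samples from trial children. Healthy and SAM group
#' means differ by +/- `log2_effect` on the planted discriminatory proteins
#' and are identical elsewhere. Pre-intervention trial samples follow the SAM
#' distribution; each arm's post-intervention mean moves every shifted protein
#' toward the healthy mean by `arm_recovery[arm]` times the effect. Values are
#' log2-scale abundances with Gaussian noise; paired visits share a
#' per-subject intercept.
#'
#' @param config A [proteome_config()].
#'
#' @return A list with `panel` (tibble: `sample_id` plus one column per
#'   protein, log2 scale), `meta` (tibble: `sample_id`, `subject_id`, `group`,
#'   `visit`, `arm`), `ground_truth` (list of planted protein ids:
#'   `healthy`, `sam`) and the `config`.
#' @export
#' @examples
#' pp <- generate_proteome(proteome_config(n_proteins = 40,
#'   n_true_discriminatory = 5, n_per_group = 6, seed = 3))
#' table(pp$meta$group, pp$meta$visit, useNA = "ifany")
generate_proteome <- function(config) {
  if (!inherits(config, "proteome_config")) config <- do.call(proteome_config, config)
  p <- config$n_proteins
  k <- config$n_true_discriminatory
  protein_ids <- sprintf("prot_%04d", seq_len(p))
  healthy_set <- protein_ids[seq_len(k)]
  sam_set <- protein_ids[k + seq_len(k)]
  arms <- names(config$arm_recovery)

  with_op_seed(config$seed, "proteome", {
    baseline <- rnorm(p, 10, 1)
    # healthy - SAM contrast: +effect on healthy-discriminatory proteins,
    # -effect on SAM-discriminatory proteins, 0 elsewhere
    delta <- numeric(p)
    delta[seq_len(k)] <- config$log2_effect
    delta[k + seq_len(k)] <- -config$log2_effect
    sam_mean <- baseline
    healthy_mean <- baseline + delta

    # total per-observation SD is noise_sd; half the variance sits in a
    # per-subject intercept shared by paired visits, half in visit noise
    comp_sd <- config$noise_sd / sqrt(2)

    draw_group <- function(mean_vec, n, prefix) {
      subj <- matrix(rnorm(n * p, 0, comp_sd), n, p)
      obs <- matrix(rnorm(n * p, 0, comp_sd), n, p)
      m <- sweep(subj + obs, 2, mean_vec, "+")
      rownames(m) <- sprintf("%s_%03d", prefix, seq_len(n))
      colnames(m) <- protein_ids
      m
    }

    n <- config$n_per_group
    healthy <- draw_group(healthy_mean, n, "healthy")
    sam <- draw_group(sam_mean, n, "sam")

    panels <- list(healthy, sam)
    meta <- list(
      tibble::tibble(sample_id = rownames(healthy),
                     subject_id = rownames(healthy),
                     group = "healthy", visit = NA_character_,
                     arm = NA_character_),
      tibble::tibble(sample_id = rownames(sam), subject_id = rownames(sam),
                     group = "SAM", visit = NA_character_, arm = NA_character_)
    )

    for (arm in arms) {
      rec <- config$arm_recovery[[arm]]
      subj_ids <- sprintf("%s_subj_%03d", arm, seq_len(n))
      subj_eff <- matrix(rnorm(n * p, 0, comp_sd), n, p)
      pre <- sweep(subj_eff + matrix(rnorm(n * p, 0, comp_sd), n, p),
                   2, sam_mean, "+")
      post <- sweep(subj_eff + matrix(rnorm(n * p, 0, comp_sd), n, p),
                    2, sam_mean + rec * delta, "+")
      rownames(pre) <- paste0(subj_ids, "_pre")
      rownames(post) <- paste0(subj_ids, "_post")
      colnames(pre) <- colnames(post) <- protein_ids
      panels <- c(panels, list(pre, post))
      meta <- c(meta, list(
        tibble::tibble(sample_id = rownames(pre), subject_id = subj_ids,
                       group = "MAM", visit = "pre", arm = arm),
        tibble::tibble(sample_id = rownames(post), subject_id = subj_ids,
                       group = "MAM", visit = "post", arm = arm)
      ))
    }

    list(panel = matrix_to_table(do.call(rbind, panels)),
         meta = dplyr::bind_rows(meta),
         ground_truth = list(healthy = healthy_set, sam = sam_set),
         config = config)
  })
}
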