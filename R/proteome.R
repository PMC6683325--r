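# Plasma-proteome response scoring: moderated differential abundance,
# discriminatory protein sets, arm-normalized treatment-effect maps,
# anthropometry correlate sets and category labeling.

panel_matrix <- function(panel) {
  if (!is.data.frame(panel) || !"sample_id" %in% names(panel)) {
    abort("panel must be a data frame with a `sample_id` column",
          class = "gutmaturity_validation_error")
  }
  m <- abundance_matrix(panel)
  if (any(!is.finite(m))) {
    abort("panel values must be finite", class = "gutmaturity_validation_error")
  }
  m
}

#' Moderated differential protein abundance between two groups
#'
#' Per-protein two-group contrast on log2-scale abundances with an
#' empirical-Bayes moderated t: residual variances are shrunk toward a common
#' prior estimated by method-of-moments on the log sample variances, and the
#' statistic is referenced to (prior + residual) degrees of freedom.
#' Benjamini-Hochberg FDR is computed across all proteins on the panel.
#'
#' @param panel Tibble: `sample_id` plus one numeric column per protein,
#'   log2 scale.
#' @param meta Tibble with `sample_id` and `group`.
#' @param group_a,group_b Group labels to contrast; the reported
#'   `log2_fold_difference` is mean(`group_a`) - mean(`group_b`).
#' @param prior_df Force the prior degrees of freedom d0 instead of
#'   estimating them. `prior_df = 0` gives the ordinary pooled-variance
#'   two-sample t.
#'
#' @return A tibble with one row per protein: `protein_id`,
#'   `log2_fold_difference`, `moderated_t`, `p`, `q`, `df_prior`,
#'   `df_total`, `constant` (variance-floored flag).
#' @export
#' @examples
#' pp <- generate_proteome(proteome_config(n_proteins = 60,
#'   n_true_discriminatory = 8, n_per_group = 10, seed = 9))
#' res <- moderated_differential(pp$panel, pp$meta, "healthy", "SAM")
#' head(dplyr::arrange(res, p))
moderated_differential <- function(panel, meta, group_a = "healthy",
                                   group_b = "SAM", prior_df = NULL) {
  m <- panel_matrix(panel)
  meta <- meta[match(rownames(m), meta$sample_id), ]
  if (anyNA(meta$sample_id)) {
    abort("every panel sample needs a metadata row",
          class = "gutmaturity_validation_error")
  }
  a <- m[meta$group %in% group_a, , drop = FALSE]
  b <- m[meta$group %in% group_b, , drop = FALSE]
  na <- nrow(a)
  nb <- nrow(b)
  if (na < 2 || nb < 2) {
    abort("need at least 2 samples per group",
          class = "gutmaturity_validation_error")
  }
  df <- na + nb - 2
  effect <- colMeans(a) - colMeans(b)
  s2 <- (colSums(sweep(a, 2, colMeans(a))^2) +
           colSums(sweep(b, 2, colMeans(b))^2)) / df
  res <- moderated_t_core(effect, s2, df, sqrt(1 / na + 1 / nb), prior_df)
  if (any(res$constant)) {
    warn(paste0(sum(res$constant),
                " constant protein(s): variance floored for testing"))
  }
  tibble::tibble(
    protein_id = colnames(m),
    log2_fold_difference = unname(effect),
    moderated_t = unname(res$t),
    p = unname(res$p),
    q = p.adjust(res$p, method = "BH"),
    df_prior = res$df_prior,
    df_total = res$df_total,
    constant = unname(res$constant)
  )
}

# Paired (one-sample on within-subject differences) moderated test.
moderated_paired <- function(diffs, prior_df = NULL) {
  n <- nrow(diffs)
  if (n < 2) {
    abort("need at least 2 paired subjects",
          class = "gutmaturity_validation_error")
  }
  effect <- colMeans(diffs)
  s2 <- colSums(sweep(diffs, 2, effect)^2) / (n - 1)
  res <- moderated_t_core(effect, s2, n - 1, sqrt(1 / n), prior_df)
  tibble::tibble(
    protein_id = colnames(diffs),
    log2_fold_difference = unname(effect),
    moderated_t = unname(res$t),
    p = unname(res$p),
    q = p.adjust(res$p, method = "BH"),
    df_prior = res$df_prior,
    df_total = res$df_total,
    constant = unname(res$constant)
  )
}

#' Healthy-growth- and SAM-discriminatory protein sets
#'
#' Ranks proteins by the healthy-vs-SAM fold difference and returns the top
#' `k` per direction among those passing the significance threshold: the `k`
#' most elevated in healthy children ("healthy growth-discriminatory") and
#' the `k` most elevated in children with SAM ("SAM-discriminatory"). If
#' fewer than `k` proteins pass in a direction, all that do are returned with
#' a warning.
#'
#' @param results Output of [moderated_differential()] (healthy vs SAM).
#' @param k Set size per direction (default 50).
#' @param p_threshold Raw p-value threshold a protein must pass (default
#'   1e-7).
#'
#' @return A `discriminatory_sets` list with tibbles `healthy_top` and
#'   `sam_top`, each ordered by fold difference.
#' @export
discriminatory_sets <- function(results, k = 50, p_threshold = 1e-7) {
  if (nrow(results) < 2 * k) {
    warn(paste0("results cover ", nrow(results), " proteins; fewer than 2k = ",
                2 * k))
  }
  pass <- dplyr::filter(results, .data$p < p_threshold)
  healthy_top <- pass |>
    dplyr::filter(.data$log2_fold_difference > 0) |>
    dplyr::arrange(dplyr::desc(.data$log2_fold_difference)) |>
    head(k)
  sam_top <- pass |>
    dplyr::filter(.data$log2_fold_difference < 0) |>
    dplyr::arrange(.data$log2_fold_difference) |>
    head(k)
  if (nrow(healthy_top) < k || nrow(sam_top) < k) {
    warn(paste0("fewer than k = ", k, " proteins pass p < ", p_threshold,
                " (healthy: ", nrow(healthy_top), ", SAM: ", nrow(sam_top), ")"))
  }
  structure(list(healthy_top = healthy_top, sam_top = sam_top,
                 k = k, p_threshold = p_threshold),
            class = "discriminatory_sets")
}

#' @export
print.discriminatory_sets <- function(x, ...) {
  cat("Discriminatory protein sets (top ", x$k, " per direction, p < ",
      format(x$p_threshold), ")\n", sep = "")
  cat("  healthy growth-discriminatory: ", nrow(x$healthy_top), "\n", sep = "")
  cat("  SAM-discriminatory:            ", nrow(x$sam_top), "\n", sep = "")
  invisible(x)
}

#' Arm-normalized treatment-effect map
#'
#' For each treatment arm, the mean within-subject pre-to-post log2
#' fold-change per protein, then normalized per protein by subtracting the
#' across-arm mean fold-change, so each protein's normalized values sum to
#' zero over arms and arms are compared relative to one another. Paired
#' significance per arm comes from the moderated framework applied to the
#' within-subject differences. Subjects missing either visit are excluded
#' with a message.
#'
#' @param panel Proteome panel tibble (log2 scale).
#' @param meta Tibble with `sample_id`, `subject_id`, `visit` (pre/post) and
#'   `arm`.
#' @param proteins Optional protein subset (e.g. a discriminatory set); the
#'   map covers all panel proteins by default.
#'
#' @return A `treatment_effect` tibble, one row per protein x arm:
#'   `protein_id`, `arm`, `mean_log2_fc`, `normalized_log2_fc`,
#'   `moderated_t`, `p`, `q`, `n_subjects`.
#' @export
treatment_effect_map <- function(panel, meta, proteins = NULL) {
  m <- panel_matrix(panel)
  if (!is.null(proteins)) {
    missing <- setdiff(proteins, colnames(m))
    if (length(missing) > 0) {
      warn(paste0("dropping ", length(missing),
                  " requested proteins absent from the panel"))
    }
    m <- m[, intersect(proteins, colnames(m)), drop = FALSE]
  }
  trial <- dplyr::filter(meta, !is.na(.data$visit), !is.na(.data$arm),
                         .data$sample_id %in% rownames(m))
  arms <- sort(unique(trial$arm))
  if (length(arms) < 1) {
    abort("no arm/visit-labelled samples in the panel",
          class = "gutmaturity_validation_error")
  }
  per_arm <- purrr::map(arms, function(a) {
    am <- dplyr::filter(trial, .data$arm == a)
    wide <- tidyr::pivot_wider(am[c("subject_id", "visit", "sample_id")],
                               names_from = "visit", values_from = "sample_id")
    if (!all(c("pre", "post") %in% names(wide))) {
      abort(paste0("arm ", a, " lacks pre or post samples"),
            class = "gutmaturity_validation_error")
    }
    incomplete <- is.na(wide$pre) | is.na(wide$post)
    if (any(incomplete)) {
      inform(paste0("arm ", a, ": excluding ", sum(incomplete),
                    " subject(s) missing a visit"))
      wide <- wide[!incomplete, ]
    }
    diffs <- m[wide$post, , drop = FALSE] - m[wide$pre, , drop = FALSE]
    stats <- moderated_paired(diffs)
    stats$arm <- a
    stats$n_subjects <- nrow(diffs)
    stats
  })
  out <- dplyr::bind_rows(per_arm)
  out <- out |>
    dplyr::rename(mean_log2_fc = "log2_fold_difference") |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::mutate(normalized_log2_fc =
                    .data$mean_log2_fc - mean(.data$mean_log2_fc)) |>
    dplyr::ungroup() |>
    dplyr::select("protein_id", "arm", "mean_log2_fc", "normalized_log2_fc",
                  "moderated_t", "p", "q", "n_subjects")
  class(out) <- c("treatment_effect", class(out))
  out
}

#' Heatmap of an arm-normalized treatment-effect map
#'
#' @param object A `treatment_effect` tibble from [treatment_effect_map()].
#' @param proteins Optional protein ordering/subset for the rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot treatment_effect
#' @export
autoplot.treatment_effect <- function(object, proteins = NULL, ...) {
  dat <- object
  if (!is.null(proteins)) {
    dat <- dplyr::filter(dat, .data$protein_id %in% proteins)
    dat$protein_id <- factor(dat$protein_id, levels = rev(proteins))
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$arm, y = .data$protein_id,
                                    fill = .data$normalized_log2_fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "treatment arm", y = NULL,
                  fill = "normalized\nlog2 fold-change")
}

#' Proteins correlated with height-for-age (HAZ)
#'
#' Per-protein Pearson correlation against HAZ with Benjamini-Hochberg FDR
#' across the panel; proteins with |r| above `r_threshold` and q below
#' `q_threshold` form the positively and negatively HAZ-correlated sets.
#'
#' @param panel Proteome panel tibble (log2 scale).
#' @param meta Tibble with `sample_id` and `HAZ`.
#' @param r_threshold Absolute correlation threshold (default 0.25).
#' @param q_threshold FDR threshold (default 0.05).
#'
#' @return A tibble with `protein_id`, `r`, `p`, `q`, `n_pairs` and `set`
#'   (`"positive"`, `"negative"` or `"none"`).
#' @export
haz_correlates <- function(panel, meta, r_threshold = 0.25,
                           q_threshold = 0.05) {
  m <- panel_matrix(panel)
  meta <- meta[match(rownames(m), meta$sample_id), ]
  haz <- meta$HAZ
  ok <- !is.na(haz)
  if (sum(ok) < 10) {
    abort("need at least 10 samples with HAZ",
          class = "gutmaturity_validation_error")
  }
  haz <- haz[ok]
  m <- m[ok, , drop = FALSE]
  if (sd(haz) == 0) {
    abort("HAZ is constant; correlations undefined",
          class = "gutmaturity_validation_error")
  }
  n <- length(haz)
  r <- suppressWarnings(as.numeric(cor(m, haz)))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[!is.finite(r)] <- NA
  q <- p.adjust(p, method = "BH")
  tibble::tibble(
    protein_id = colnames(m),
    r = r, p = p, q = q, n_pairs = n,
    set = dplyr::case_when(
      !is.na(r) & r > r_threshold & q < q_threshold ~ "positive",
      !is.na(r) & r < -r_threshold & q < q_threshold ~ "negative",
      TRUE ~ "none"
    )
  )
}

#' Label proteins within annotation categories as growth-discriminatory
#'
#' Given healthy-vs-SAM differential results and caller-supplied annotation
#' categories (e.g. GO Biological Process sets parsed from a GMT file),
#' labels each category member "healthy growth-discriminatory" if it is more
#' than 30% more abundant in healthy than SAM plasma (linear fold-change
#' strictly above `fold_threshold`) at q below `q_threshold`,
#' "SAM-discriminatory" for the mirror-image criterion, and leaves it
#' unlabeled otherwise. Boundary ties (fold-change exactly at the threshold)
#' are not labeled.
#'
#' @param results Output of [moderated_differential()] (healthy vs SAM).
#' @param categories Named list mapping category name to protein ids (see
#'   [read_gmt()]).
#' @param fold_threshold Linear fold-change threshold (default 1.3, i.e. a
#'   30% difference).
#' @param q_threshold FDR threshold (default 0.05).
#'
#' @return A tibble with `category`, `protein_id`, `log2_fold_difference`,
#'   `q` and `label` (`"healthy_growth_discriminatory"`,
#'   `"SAM_discriminatory"` or `"none"`).
#' @export
category_discriminatory_labels <- function(results, categories,
                                           fold_threshold = 1.3,
                                           q_threshold = 0.05) {
  if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
    abort("`categories` must be a named list of protein-id vectors",
          class = "gutmaturity_validation_error")
  }
  unknown <- setdiff(unique(unlist(categories)), results$protein_id)
  if (length(unknown) > 0) {
    warn(paste0("dropping ", length(unknown),
                " category protein(s) absent from the results"))
  }
  long <- purrr::imap_dfr(categories, function(ids, nm) {
    tibble::tibble(category = nm,
                   protein_id = intersect(ids, results$protein_id))
  })
  long <- dplyr::left_join(
    long, results[c("protein_id", "log2_fold_difference", "q")],
    by = "protein_id")
  fold <- 2^long$log2_fold_difference
  long$label <- dplyr::case_when(
    fold > fold_threshold & long$q < q_threshold ~
      "healthy_growth_discriminatory",
    (1 / fold) > fold_threshold & long$q < q_threshold ~ "SAM_discriminatory",
    TRUE ~ "none"
  )
  long
}
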