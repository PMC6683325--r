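# Generic rank-correlation screening: all-pairs Spearman/Pearson tables with
# screen-wide BH-FDR, used for the diet-ingredient/strain screen and for
# protein-anthropometry-taxon correlation tables.

# All permutations of 1..n, built by repeated insertion (rows = n!).
perm_matrix <- function(n) {
  m <- matrix(1L, 1, 1)
  if (n == 1) return(m)
  for (k in 2:n) {
    K <- nrow(m)
    new <- matrix(0L, K * k, k)
    for (pos in seq_len(k)) {
      rows <- (pos - 1) * K + seq_len(K)
      new[rows, pos] <- k
      new[rows, -pos] <- m
    }
    m <- new
  }
  m
}

# Two-sided exact permutation p-value for a correlation of `x` and `y`
# (already ranked, for Spearman): proportion of permutations of y whose
# |correlation| is at least the observed one.
exact_perm_p <- function(x, y, perms) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (denom == 0) return(NA_real_)
  obs <- sum(xc * yc) / denom
  yp <- matrix(yc[perms], nrow(perms), ncol(perms))
  rho_perm <- as.numeric(yp %*% xc) / denom
  mean(abs(rho_perm) >= abs(obs) - 1e-12)
}

correlate_one_pair <- function(x, y, method, exact_n_max, perm_cache) {
  ok <- complete.cases(x, y)
  n <- sum(ok)
  if (n < 4) {
    return(list(estimate = NA_real_, p = NA_real_, n = n, note = "n<4"))
  }
  x <- x[ok]
  y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(estimate = NA_real_, p = NA_real_, n = n, note = "constant"))
  }
  if (method == "spearman") {
    x <- rank(x)  # average ranks for ties
    y <- rank(y)
  }
  est <- cor(x, y)
  if (method == "spearman" && n <= exact_n_max) {
    key <- as.character(n)
    if (is.null(perm_cache[[key]])) perm_cache[[key]] <- perm_matrix(n)
    p <- exact_perm_p(x, y, perm_cache[[key]])
  } else {
    tt <- est * sqrt((n - 2) / max(1 - est^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(estimate = est, p = p, n = n, note = NA_character_)
}

correlate_pairs <- function(x, y, method, exact_n_max = 9) {
  stopifnot(is.data.frame(x), is.data.frame(y),
            "sample_id" %in% names(x), "sample_id" %in% names(y))
  shared <- intersect(x$sample_id, y$sample_id)
  if (length(shared) < 4) {
    warn(paste0("only ", length(shared),
                " shared samples between the two tables; returning an empty screen"))
    return(tibble::tibble(feature_a = character(), feature_b = character(),
                          method = character(), estimate = numeric(),
                          p = numeric(), q = numeric(), n_pairs = integer()))
  }
  xm <- x[match(shared, x$sample_id), feature_ids(x), drop = FALSE]
  ym <- y[match(shared, y$sample_id), feature_ids(y), drop = FALSE]
  perm_cache <- new.env(parent = emptyenv())
  grid <- tidyr::expand_grid(feature_a = names(xm), feature_b = names(ym))
  res <- purrr::map2(grid$feature_a, grid$feature_b, function(a, b) {
    correlate_one_pair(xm[[a]], ym[[b]], method, exact_n_max, perm_cache)
  })
  out <- tibble::tibble(
    feature_a = grid$feature_a,
    feature_b = grid$feature_b,
    method = method,
    estimate = purrr::map_dbl(res, "estimate"),
    p = purrr::map_dbl(res, "p"),
    n_pairs = purrr::map_int(res, "n")
  )
  n_excluded <- sum(is.na(out$p))
  if (n_excluded > 0) {
    warn(paste0(n_excluded,
                " pair(s) with constant or insufficient data excluded from FDR"))
  }
  # one FDR family per screen, not per row feature
  out$q <- p.adjust(out$p, method = "BH")
  out[c("feature_a", "feature_b", "method", "estimate", "p", "q", "n_pairs")]
}

#' All-pairs Spearman rank-correlation screen
#'
#' Correlates every column of `x` against every column of `y` (matched by
#' `sample_id`, pairwise-complete) using Spearman's rank correlation with
#' average ranks for ties. For small screens (`n <= exact_n_max` paired
#' observations) the two-sided p-value is exact, from full enumeration of all
#' n! permutations; otherwise the t approximation on the rank correlation is
#' used. Benjamini-Hochberg FDR is applied once across all pairs in the
#' screen, matching how such screens are read as a single heatmap. This is
#' the screen used to relate complementary-food-ingredient inclusion levels
#' to the relative abundances of age-discriminatory bacterial strains.
#'
#' @param x,y Tibbles: `sample_id` plus numeric feature columns.
#' @param exact_n_max Largest n for which the exact permutation p-value is
#'   computed (default 9).
#'
#' @return An association tibble: `feature_a`, `feature_b`, `method`,
#'   `estimate` (rho), `p`, `q`, `n_pairs`. Constant columns yield missing
#'   estimates and are excluded from the FDR family.
#' @export
#' @examples
#' dd <- generate_diet_design(14, 6, 8,
#'   data.frame(ingredient = "ingredient_01", strain = "strain_01", slope = 4),
#'   seed = 4)
#' scr <- spearman_screen(dd$design, dd$abundance)
#' head(dplyr::arrange(scr, q))
spearman_screen <- function(x, y, exact_n_max = 9) {
  correlate_pairs(x, y, method = "spearman", exact_n_max = exact_n_max)
}

#' All-pairs correlation table (Pearson or Spearman)
#'
#' As [spearman_screen()], with a method switch; Pearson is used for
#' maturity-anthropometry correlations.
#'
#' @inheritParams spearman_screen
#' @param method `"pearson"` or `"spearman"`.
#' @return An association tibble (see [spearman_screen()]).
#' @export
correlation_table <- function(x, y, method = c("pearson", "spearman"),
                              exact_n_max = 9) {
  method <- match.arg(method)
  correlate_pairs(x, y, method = method, exact_n_max = exact_n_max)
}

#' Heatmap of an association screen
#'
#' @param object An association tibble from [spearman_screen()] or
#'   [correlation_table()].
#' @param q_threshold Pairs at or above this FDR are left unmarked; those
#'   below are dotted.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_association_heatmap <- function(object, q_threshold = 0.05, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$feature_a,
                                       y = .data$feature_b,
                                       fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(object, !is.na(.data$q),
                                             .data$q < q_threshold),
                        size = 0.8) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "correlation") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
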