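# Independent oracles, deliberately written as plain loops so they share no
# code with the implementation they check.

# Benjamini-Hochberg step-up, straight from the definition.
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- rep(NA_real_, m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# Ordinary pooled-variance two-sample t and its p-value, per protein.
pooled_t_oracle <- function(a, b) {
  na <- nrow(a)
  nb <- nrow(b)
  t_out <- p_out <- numeric(ncol(a))
  for (j in seq_len(ncol(a))) {
    sp2 <- (sum((a[, j] - mean(a[, j]))^2) + sum((b[, j] - mean(b[, j]))^2)) /
      (na + nb - 2)
    t_out[j] <- (mean(a[, j]) - mean(b[, j])) / sqrt(sp2 * (1 / na + 1 / nb))
    p_out[j] <- 2 * pt(-abs(t_out[j]), df = na + nb - 2)
  }
  list(t = t_out, p = p_out)
}

# Exhaustive two-sided permutation p-value for Spearman's rho at small n,
# enumerating permutations recursively one at a time.
spearman_exact_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- abs(cor(rx, ry))
  count <- 0
  total <- 0
  recurse <- function(remaining, chosen) {
    if (length(remaining) == 0) {
      total <<- total + 1
      if (abs(cor(rx, ry[chosen])) >= obs - 1e-12) count <<- count + 1
      return(invisible())
    }
    for (i in seq_along(remaining)) {
      recurse(remaining[-i], c(chosen, remaining[i]))
    }
  }
  recurse(seq_along(y), integer(0))
  count / total
}

# Small healthy cohort + fitted sparse calibrated model, cached across tests.
.gm_cache <- new.env(parent = emptyenv())

small_reference <- function() {
  if (is.null(.gm_cache$small)) {
    tr <- taxon_trajectories(30, 16, seed = 42)
    ch <- generate_healthy_cohort(
      cohort_config(n_subjects = 10, sampling_ages = seq(1, 24, by = 2),
                    n_taxa = 30, n_discriminatory = 16, seed = 42), tr)
    m <- fit_age_model(ch$table, ch$meta, num_trees = 200, seed = 42)
    m <- sparsify(m, max_features = 16, n_folds = 5,
                  grid = c(2, 4, 6, 8, 10, 12, 14, 16))
    m <- suppressMessages(calibrate(m, n_folds = 5))
    .gm_cache$small <- list(trajectories = tr, cohort = ch, model = m)
  }
  .gm_cache$small
}

# The full-size healthy reference used by the acceptance checks (25 subjects
# x 24 monthly samples, 60 taxa / 30 discriminatory), fitted once.
acceptance_reference <- function(seed = 101) {
  key <- paste0("ref", seed)
  if (is.null(.gm_cache[[key]])) {
    tr <- taxon_trajectories(60, 30, seed = seed)
    ch <- generate_healthy_cohort(cohort_config(seed = seed), tr)
    m <- fit_age_model(ch$table, ch$meta, seed = seed)
    m <- sparsify(m, max_features = 30, n_folds = 5)
    m <- suppressMessages(calibrate(m, n_folds = 5))
    .gm_cache[[key]] <- list(trajectories = tr, cohort = ch, model = m)
  }
  .gm_cache[[key]]
}
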