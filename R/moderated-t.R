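# Empirical-Bayes moderated t-statistics for protein panels.
#
# Per-protein sample variances s2 with d residual df are shrunk toward a
# common prior: s2_post = (d0*s02 + d*s2) / (d0 + d), where the prior df d0
# and prior variance s02 are estimated by method-of-moments on log(s2)
# (a scaled chi-square has a known log-mean and log-variance, so matching
# the observed mean and variance of log s2 identifies d0 and s02). The
# moderated t is the mean contrast over its posterior standard error,
# referenced to d0 + d degrees of freedom.

# Invert trigamma by Newton's method (monotone decreasing, so this converges
# globally from the asymptotic start).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

# Estimate (d0, s02) from per-protein variances s2 on df residual df each.
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(df_prior = 0, s2_prior = mean(s2[ok], na.rm = TRUE)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # observed log-variances no more dispersed than chi-square sampling noise:
    # infinite prior df, all variances shrunk to the common value
    list(df_prior = Inf, s2_prior = exp(mean(e)))
  } else {
    df_prior <- 2 * trigamma_inverse(evar)
    list(df_prior = df_prior,
         s2_prior = exp(mean(e) + digamma(df_prior / 2) - log(df_prior / 2)))
  }
}

# Core moderated test. `effect` is the per-protein contrast estimate, `s2`
# its residual variance on `df` df, `stdev_unscaled` the unscaled SE
# multiplier (sqrt(1/na + 1/nb) two-sample, sqrt(1/n) paired).
moderated_t_core <- function(effect, s2, df, stdev_unscaled, prior_df = NULL) {
  constant <- !is.finite(s2) | s2 <= 0
  if (any(constant)) {
    floor_val <- if (all(constant)) 1e-12 else max(min(s2[!constant]), 1e-12)
    s2[constant] <- floor_val
  }
  if (is.null(prior_df)) {
    prior <- estimate_variance_prior(s2, df)
  } else {
    prior <- list(df_prior = prior_df,
                  s2_prior = if (prior_df > 0) estimate_variance_prior(s2, df)$s2_prior else 0)
  }
  d0 <- prior$df_prior
  s2_post <- if (is.infinite(d0)) {
    rep(prior$s2_prior, length(s2))
  } else {
    (d0 * prior$s2_prior + df * s2) / (d0 + df)
  }
  t_stat <- unname(effect / (sqrt(s2_post) * stdev_unscaled))
  df_total <- d0 + df
  p <- 2 * pt(-abs(t_stat), df = df_total)
  s2_post <- unname(s2_post)
  constant <- unname(constant)
  list(t = t_stat, p = p, s2_post = s2_post, df_prior = d0,
       s2_prior = prior$s2_prior, df_total = df_total, constant = constant)
}
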