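# Empirical-Bayes variance / dispersion shrinkage.
#
# Per-feature variances s^2 on d residual df are modelled as scaled-F
# draws around a prior s0^2 with d0 prior df. (d0, s0^2) are estimated by
# moment-matching the log variances: for s^2 ~ s0^2 * F(d, d0),
#   E[log s^2] = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
#   Var[log s^2] = trigamma(d/2) + trigamma(d0/2).
# The posterior variance is the df-weighted average
#   s^2_post = (d0 s0^2 + d s^2) / (d0 + d),
# which always lies between the prior (trend) value and the raw value.

trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

fit_f_dist <- function(s2, df, covariate = NULL) {
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df > 0
  if (sum(ok) < 2) return(list(df_prior = Inf, s2_prior = rep(mean(s2[ok]), length(s2))))
  z <- log(s2[ok])
  d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  if (!is.null(covariate) &&
      (sum(ok) < 10 || length(unique(covariate[ok])) < 2)) {
    covariate <- NULL   # too few points for a trend: constant prior
  }
  if (!is.null(covariate)) {
    lw <- lowess(covariate[ok], e, f = 0.5)
    etrend_ok <- approx(lw$x, lw$y, xout = covariate[ok], rule = 2, ties = mean)$y
    etrend <- approx(lw$x, lw$y, xout = covariate, rule = 2, ties = mean)$y
    resid_e <- e - etrend_ok
  } else {
    etrend <- rep(mean(e), length(s2))
    resid_e <- e - mean(e)
  }
  evar <- var(resid_e) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(etrend + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s2_prior <- exp(etrend)
  }
  list(df_prior = d0, s2_prior = s2_prior)
}

#' Shrink per-feature variances toward a common (or trended) prior
#'
#' Moment-matching empirical-Bayes shrinkage of per-feature sample variances
#' (or GLM dispersion estimates): estimates a prior variance (optionally a
#' lowess trend against `covariate`) and prior degrees of freedom from the
#' spread of the observed log variances, then returns the posterior
#' df-weighted variances. With `df_prior = 0` the raw values are returned
#' unchanged; with `df_prior = Inf` every feature receives the prior value.
#'
#' @param s2 per-feature variance / dispersion estimates (positive)
#' @param df residual degrees of freedom (scalar or per-feature)
#' @param covariate optional per-feature covariate (e.g. log mean count) for
#'   a trended prior
#' @param df_prior optional fixed prior df overriding the moment-matching
#'   estimate (0 and `Inf` give the no-pooling / complete-pooling limits)
#' @return list with `s2_post`, `s2_prior`, `df_prior`
#' @export
squeeze_var <- function(s2, df, covariate = NULL, df_prior = NULL) {
  df <- rep_len(df, length(s2))
  if (is.null(df_prior)) {
    fit <- fit_f_dist(s2, df, covariate)
  } else {
    prior <- if (!is.null(covariate)) {
      e <- log(s2) - digamma(df / 2) + log(df / 2)
      lw <- lowess(covariate, e, f = 0.5)
      exp(approx(lw$x, lw$y, xout = covariate, rule = 2, ties = mean)$y)
    } else {
      rep(exp(mean(log(s2[s2 > 0 & is.finite(s2)]))), length(s2))
    }
    fit <- list(df_prior = df_prior, s2_prior = prior)
  }
  d0 <- fit$df_prior
  s2_post <- if (!is.finite(d0)) {
    fit$s2_prior
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * fit$s2_prior + df * s2) / (d0 + df)
  }
  list(s2_post = s2_post, s2_prior = fit$s2_prior, df_prior = d0)
}

#' Shrink count dispersions toward a mean-dispersion trend
#'
#' Geometric-scale interpolation between per-feature raw dispersions and a
#' lowess trend of log dispersion against log mean. By default the
#' interpolation weight is estimated by empirical Bayes: the across-feature
#' spread of log dispersions in excess of the delta-method sampling
#' variance `(2/df) * (1 + 1/(raw * mean))^2` sets the prior precision
#' (normal-normal on the log scale), so homogeneous dispersions are pooled
#' almost completely while genuinely heterogeneous ones keep their
#' feature-specific estimates. A fixed `prior_df` gives the classic
#' df-weighted interpolation instead. The shrunken value always lies
#' between the raw and trend values. Used by the negative-binomial
#' differential-expression test.
#'
#' @param raw per-feature dispersion estimates (>= `floor`)
#' @param mean_count per-feature mean normalized counts
#' @param df residual df per feature (weight of the raw estimate)
#' @param prior_df optional fixed trend weight expressed as prior df;
#'   `NULL` (default) estimates the weight by moment matching
#' @param floor lower bound applied to dispersions (default 1e-8)
#' @return list with `raw`, `trend`, `shrunk`
#' @export
shrink_dispersion <- function(raw, mean_count, df, prior_df = NULL,
                              floor = 1e-8) {
  raw <- pmax(raw, floor)
  raw[!is.finite(raw)] <- floor
  trend <- if (length(raw) < 10 || length(unique(mean_count)) < 2) {
    rep(exp(mean(log(raw))), length(raw))
  } else {
    lw <- lowess(log(mean_count), log(raw), f = 0.5)
    exp(approx(lw$x, lw$y, xout = log(mean_count), rule = 2, ties = mean)$y)
  }
  df <- rep_len(df, length(raw))
  if (is.null(prior_df)) {
    v_sample <- (2 / df) * (1 + 1 / pmax(raw * mean_count, 0.05))^2
    resid <- log(raw) - log(trend)
    tau2 <- max(0, var(resid) - mean(v_sample))
    if (!is.finite(tau2)) tau2 <- 0
    w <- tau2 / (tau2 + v_sample)
  } else {
    w <- df / (df + prior_df)
  }
  shrunk <- exp(w * log(raw) + (1 - w) * log(trend))
  list(raw = raw, trend = trend, shrunk = shrunk, weight = w)
}
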