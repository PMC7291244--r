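# Pooled quasi-Poisson regression of exon usage on flanking-intron
# methylation.
#
# The observation unit is the flank pair: inclusion counts and gene totals
# are summed over a group's samples and the predictor is the group-mean
# beta value of the intronic probe, so n equals the number of pairs. The
# "logistic regression in quasi-Poisson distribution" of the source design
# is realized as a Poisson log-link GLM with a log gene-total offset and
# quasi-likelihood dispersion (Pearson chi-square / df), i.e. the exon
# usage fraction is modelled multiplicatively and standard errors are
# inflated by sqrt(dispersion); inference on the methylation coefficient
# is t-based on the residual df.

#' Fit the flank quasi-Poisson usage model to pair-level data
#'
#' Low-level fitting routine behind [flank_regression()], usable directly
#' on simulated pair-level data. Response `y` (pair inclusion counts),
#' offset `log(total)` (gene totals), predictor `beta` (methylation), and
#' optionally `log10(distance)` as adjustment covariate.
#'
#' @param y pair-level inclusion counts (non-negative)
#' @param total pair-level gene-total counts (> 0 required; zero-total
#'   pairs are removed with a logged count)
#' @param beta pair-level methylation values
#' @param distance pair distances in bp (required when
#'   `adjust_distance = TRUE`)
#' @param adjust_distance include `log10(distance)` as covariate?
#' @param group,kind labels stored on the result
#' @param log_path optional log file
#' @return an object of class `"flank_fit"` with the methylation
#'   coefficient, scaled standard error, t statistic, p-value, dispersion
#'   and pair count; see [coef.flank_fit()], [confint.flank_fit()]
#' @export
fit_flank_glm <- function(y, total, beta, distance = NULL,
                          adjust_distance = FALSE, group = NA_character_,
                          kind = NA_character_, log_path = NULL) {
  keep <- total > 0
  n_zero <- sum(!keep)
  if (n_zero) {
    log_line(log_path, "fit_flank_glm", zero_total_pairs_dropped = n_zero)
    y <- y[keep]; total <- total[keep]; beta <- beta[keep]
    if (!is.null(distance)) distance <- distance[keep]
  }
  if (length(y) < 10) stop("fewer than 10 usable pairs")
  if (var(beta) == 0) stop("degenerate predictor: methylation has no variance")
  X <- cbind(`(Intercept)` = 1, methylation = beta)
  if (adjust_distance) {
    if (is.null(distance)) stop("distance required when adjust_distance = TRUE")
    X <- cbind(X, log10_distance = log10(distance))
  }
  fit <- glm.fit(X, y, family = poisson(), offset = log(total),
                 control = list(epsilon = 1e-10, maxit = 50))
  if (fit$rank < ncol(X)) stop("rank-deficient flank design")
  dfr <- length(y) - ncol(X)
  mu <- fit$fitted.values
  phi <- sum((fit$y - mu)^2 / mu) / dfr
  cov_u <- glm_cov_unscaled(fit)
  se <- sqrt(diag(cov_u) * phi)
  names(se) <- colnames(X)
  tstat <- fit$coefficients / se
  pval <- 2 * pt(-abs(tstat), df = dfr)
  structure(list(
    coefficients = fit$coefficients,
    se = se,
    statistic = tstat,
    p.value = pval,
    coefficient = unname(fit$coefficients["methylation"]),
    coefficient_se = unname(se["methylation"]),
    coefficient_p = unname(pval["methylation"]),
    dispersion = phi,
    n = length(y),
    df.residual = dfr,
    group = group,
    kind = kind,
    adjusted = adjust_distance
  ), class = "flank_fit")
}

#' Genome-wide flank regression of exon usage on intronic methylation
#'
#' Pools all flank pairs of one kind (`intron-exon` or `exon-intron`)
#' within one group (e.g. DCM or control): per pair, the response is the
#' bin's inclusion count summed over the group's samples, the offset the
#' log gene-total count summed over the same samples, and the predictor
#' the group-mean beta value of the intronic probe; optionally adjusted by
#' `log10(distance)`. Pairs whose probe or bin did not survive QC are
#' dropped with a logged count.
#'
#' @param pairs pair table from [build_flank_pairs()]
#' @param counts inclusion-count matrix with rows named `gene:bin`, or a
#'   list with an `inclusion` element
#' @param beta probes x samples beta-value matrix
#' @param sheet sample sheet with `sample_id` and `condition`
#' @param group condition label selecting the samples
#' @param kind `"intron-exon"` or `"exon-intron"`
#' @param adjust_distance include `log10(distance)`? (default FALSE)
#' @param log_path optional log file
#' @return a `"flank_fit"` object (see [fit_flank_glm()])
#' @export
flank_regression <- function(pairs, counts, beta, sheet, group, kind,
                             adjust_distance = FALSE, log_path = NULL) {
  kind <- match.arg(kind, c("intron-exon", "exon-intron"))
  incl <- as.matrix(if (is.list(counts)) counts$inclusion else counts)
  samples <- sheet$sample_id[sheet$condition == group]
  if (!length(samples)) stop("no samples in group ", group)
  incl <- incl[, samples, drop = FALSE]
  beta <- as.matrix(beta)[, samples, drop = FALSE]

  pp <- pairs[pairs$kind == kind, , drop = FALSE]
  bin_key <- paste(pp$gene_id, pp$bin_id, sep = ":")
  usable <- bin_key %in% rownames(incl) & pp$probe_id %in% rownames(beta)
  log_line(log_path, "flank_regression", group = group, kind = kind,
           pairs_in = nrow(pp), pairs_after_qc = sum(usable))
  pp <- pp[usable, , drop = FALSE]
  bin_key <- bin_key[usable]

  gene <- sub(":[^:]+$", "", rownames(incl))
  gene_tot <- rowsum(rowSums(incl), gene)
  y <- rowSums(incl[bin_key, , drop = FALSE])
  total <- gene_tot[pp$gene_id, 1]
  x <- rowMeans(beta[pp$probe_id, , drop = FALSE])
  fit_flank_glm(y, total, x, distance = pp$distance,
                adjust_distance = adjust_distance, group = group,
                kind = kind, log_path = log_path)
}

#' Fit the flank regression for every group/kind/adjustment combination
#'
#' Convenience wrapper producing the standard four- or eight-row summary
#' table (group x kind, unadjusted and distance-adjusted).
#'
#' @inheritParams flank_regression
#' @param groups condition labels (default `c("DCM", "control")`)
#' @param kinds pair kinds (default both)
#' @param adjusted logical vector of adjustment settings (default both)
#' @return data.frame with columns `adjusted`, `kind`, `group`,
#'   `coefficient`, `se`, `p`, `dispersion`, `n`
#' @export
flank_regression_table <- function(pairs, counts, beta, sheet,
                                   groups = c("DCM", "control"),
                                   kinds = c("intron-exon", "exon-intron"),
                                   adjusted = c(FALSE, TRUE),
                                   log_path = NULL) {
  rows <- list()
  for (adj in adjusted) for (k in kinds) for (g in groups) {
    f <- flank_regression(pairs, counts, beta, sheet, group = g, kind = k,
                          adjust_distance = adj, log_path = log_path)
    rows[[length(rows) + 1L]] <- data.frame(
      adjusted = adj, kind = k, group = g,
      coefficient = f$coefficient, se = f$coefficient_se,
      p = f$coefficient_p, dispersion = f$dispersion, n = f$n,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.flank_fit <- function(x, ...) {
  cat("Flank quasi-Poisson usage regression\n")
  cat(sprintf("  group: %s   kind: %s   distance-adjusted: %s\n",
              x$group, x$kind, x$adjusted))
  cat(sprintf("  n pairs: %d   dispersion: %.3f\n", x$n, x$dispersion))
  cat(sprintf("  methylation coefficient: %.6f (se %.6f), t = %.2f, p = %.3g\n",
              x$coefficient, x$coefficient_se,
              x$statistic["methylation"], x$coefficient_p))
  invisible(x)
}

#' @export
coef.flank_fit <- function(object, ...) object$coefficients

#' @export
summary.flank_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$statistic, `Pr(>|t|)` = object$p.value)
  structure(list(fit = object, coefficients = tab),
            class = "summary.flank_fit")
}

#' @export
print.summary.flank_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' Confidence intervals for a flank fit
#'
#' t-based Wald intervals at the quasi-likelihood (dispersion-scaled)
#' standard errors.
#'
#' @param object a `flank_fit`
#' @param parm coefficients to include (default all)
#' @param level confidence level
#' @param ... unused
#' @return matrix of lower/upper bounds
#' @export
confint.flank_fit <- function(object, parm = NULL, level = 0.95, ...) {
  q <- qt(1 - (1 - level) / 2, df = object$df.residual)
  est <- object$coefficients
  lo <- est - q * object$se
  hi <- est + q * object$se
  out <- cbind(lo, hi)
  colnames(out) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                                trim = TRUE), "%")
  if (!is.null(parm)) out <- out[parm, , drop = FALSE]
  out
}
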