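# Simplified genome-wide differential tests: negative-binomial Wald DGE,
# quasi-binomial DEU with empirical-Bayes dispersion shrinkage, and a
# moderated-t differential methylation test. These are statistically
# equivalent simplifications of the standard count/array pipelines, built
# on stats::glm.fit / MASS::negative.binomial, and are validated by
# simulation calibration rather than bit-level agreement with any
# particular package.

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjusted p-values, monotonized and capped at 1. `NA`/`NaN`
#' entries propagate; the number of tests is the number of non-missing
#' p-values.
#'
#' @param p vector of p-values in `[0, 1]` (NA allowed)
#' @return vector of adjusted values, same length and order
#' @export
benjamini_hochberg <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pn <- p[ok]
  if (any(pn < 0 | pn > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pn)
  o <- order(pn, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * pn[o]))
  out[ok[o]] <- adj
  out
}

#' Build a full-rank design matrix from a sample sheet
#'
#' Assembles intercept + condition indicator + the requested covariates
#' (sheet columns, e.g. sex, age, immunosuppressant flags, batch labels)
#' and optional principal-component scores, then drops rank-deficient
#' columns deterministically: columns are tested left to right and a column
#' that does not increase the rank is dropped (so later-entered aliased
#' covariates lose — e.g. drug flags perfectly confounded with condition).
#'
#' @param sheet sample sheet with at least `sample_id` and `condition`
#' @param covariates character vector of sheet column names to include
#'   after the condition indicator
#' @param pcs optional samples x k matrix of PC scores (rows matched to
#'   `sheet$sample_id` by name when rownames are present)
#' @param case label of the case condition (default `"DCM"`)
#' @return numeric design matrix with a `conditionDCM`-style column named
#'   `condition`
#' @export
build_design <- function(sheet, covariates = character(), pcs = NULL,
                         case = "DCM") {
  stop_if_missing_cols(sheet, c("sample_id", "condition"), "sample sheet")
  df <- data.frame(condition = as.numeric(sheet$condition == case))
  for (cv in covariates) {
    if (!cv %in% colnames(sheet)) stop("covariate not in sample sheet: ", cv)
    v <- sheet[[cv]]
    if (is.character(v)) v <- factor(v)
    df[[cv]] <- if (is.logical(v)) as.numeric(v) else v
  }
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (!is.null(rownames(pcs))) pcs <- pcs[sheet$sample_id, , drop = FALSE]
    for (j in seq_len(ncol(pcs))) {
      df[[colnames(pcs)[j] %||% paste0("PC", j)]] <- pcs[, j]
    }
  }
  X <- model.matrix(~ ., data = df)
  # greedy left-to-right rank filter: keeps intercept and condition,
  # drops later aliased columns
  keep <- logical(ncol(X))
  Xk <- NULL
  r <- 0L
  for (j in seq_len(ncol(X))) {
    cand <- cbind(Xk, X[, j])
    if (qr(cand)$rank > r) {
      Xk <- cand
      r <- r + 1L
      keep[j] <- TRUE
    }
  }
  if (!all(keep)) {
    warning("dropping aliased design column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  rownames(X) <- sheet$sample_id
  X
}

glm_cov_unscaled <- function(fit) {
  p <- fit$rank
  chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
}

#' Differential gene expression: negative-binomial Wald test
#'
#' Per gene, a negative-binomial log-linear model of the counts with a
#' log size-factor offset. Dispersions are estimated by method of moments
#' on normalized counts (within-condition), shrunk toward a lowess
#' mean-dispersion trend on the log scale ([shrink_dispersion()]), and the
#' condition coefficient is tested with a Wald statistic at the shrunken
#' dispersion. Because plugging an estimated dispersion into the Wald
#' standard error is anti-conservative, a quasi-likelihood scale is layered
#' on top: per-gene Pearson dispersions relative to the fitted NB variance
#' are shrunk by empirical Bayes ([squeeze_var()]) and the statistic is
#' referred to a t distribution on `df_prior + df_residual` degrees of
#' freedom. Genes with all-zero counts get `NA` results. Adjustment by
#' [benjamini_hochberg()].
#'
#' @param gene_counts genes x samples integer matrix (bin inclusion counts
#'   summed per gene)
#' @param sheet sample sheet (columns matched to the count columns)
#' @param covariates extra sheet columns for the design (default none)
#' @param sf optional size factors; computed by [size_factors()] if `NULL`
#' @param prior_df optional fixed trend weight for dispersion
#'   shrinkage; `NULL` (default) estimates it by moment matching
#'   (see [shrink_dispersion()])
#' @return data.frame: `feature_id`, `effect` (log2 fold change), `se`,
#'   `stat`, `p`, `fdr`, `dispersion`
#' @export
test_dge <- function(gene_counts, sheet, covariates = character(),
                     sf = NULL, prior_df = NULL) {
  gene_counts <- as.matrix(gene_counts)
  gene_counts <- gene_counts[, sheet$sample_id, drop = FALSE]
  if (is.null(sf)) sf <- size_factors(gene_counts)
  X <- build_design(sheet, covariates)
  n <- ncol(gene_counts)
  nonzero <- rowSums(gene_counts) > 0

  norm <- sweep(gene_counts, 2, sf, "/")
  mu <- rowMeans(norm)
  grp <- sheet$condition
  # within-condition method-of-moments dispersion on normalized counts
  s2w <- rep(NA_real_, nrow(norm))
  for (g in unique(grp)) {
    cols <- grp == g
    if (sum(cols) < 2) next
    v <- apply(norm[, cols, drop = FALSE], 1, var) * (sum(cols) - 1)
    s2w <- ifelse(is.na(s2w), 0, s2w) + v
  }
  s2w <- s2w / (n - length(unique(grp)))
  shot <- mu * mean(1 / sf)
  alpha_raw <- (s2w - shot) / mu^2
  dfit <- shrink_dispersion(alpha_raw[nonzero], mu[nonzero],
                            df = n - length(unique(grp)),
                            prior_df = prior_df)
  # the GLM family carries the noise-free trend dispersion; per-gene
  # departures from it are absorbed by the quasi-likelihood scale below
  alpha <- rep(NA_real_, nrow(gene_counts))
  alpha[nonzero] <- dfit$trend

  res <- data.frame(feature_id = rownames(gene_counts),
                    effect = NA_real_, se = NA_real_, stat = NA_real_,
                    p = NA_real_, fdr = NA_real_, dispersion = alpha,
                    stringsAsFactors = FALSE)
  off <- log(sf)
  ci <- match("condition", colnames(X))
  dfr <- n - ncol(X)
  b_vec <- se_vec <- phi_vec <- rep(NA_real_, nrow(gene_counts))
  for (i in which(nonzero)) {
    a <- max(alpha[i], 1e-8)
    fam <- MASS::negative.binomial(theta = 1 / a, link = "log")
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, gene_counts[i, ], family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$rank < ncol(X)) next
    b_vec[i] <- fit$coefficients[ci]
    se_vec[i] <- sqrt(glm_cov_unscaled(fit)[ci, ci])
    mu_hat <- fit$fitted.values
    # quasi-likelihood scale: residual variation not captured by the
    # shrunken NB dispersion
    phi_vec[i] <- sum((fit$y - mu_hat)^2 / (mu_hat + a * mu_hat^2)) / dfr
  }
  okg <- which(!is.na(phi_vec))
  if (length(okg) >= 10) {
    sq <- squeeze_var(phi_vec[okg], dfr, covariate = log(mu[okg] + 1))
    phi_post <- sq$s2_post
    df_tot <- sq$df_prior + dfr
  } else {
    phi_post <- rep(1, length(okg))
    df_tot <- dfr
  }
  res$effect[okg] <- b_vec[okg] / log(2)
  res$se[okg] <- se_vec[okg] * sqrt(phi_post) / log(2)
  res$stat[okg] <- b_vec[okg] / (se_vec[okg] * sqrt(phi_post))
  res$p[okg] <- 2 * pt(-abs(res$stat[okg]), df = df_tot)
  res$fdr <- benjamini_hochberg(res$p)
  res
}

#' Differential exon usage: quasi-binomial test with dispersion shrinkage
#'
#' Per exon bin, the response is (bin inclusion count, rest-of-gene count)
#' per sample, modelled with a logit-link binomial GLM on condition plus
#' any configured covariates. Because biological usage variation makes the
#' per-sample variance grow with the squared total, a plain multiplicative
#' quasi-binomial dispersion is not enough when totals differ across
#' samples; a Williams-type intraclass correlation is therefore estimated
#' genome-wide from the first-pass Pearson dispersions and the binomial
#' weights are deflated to `w / (1 + rho * (w - 1))` before the second
#' pass. Residual per-bin overdispersions are then shrunk toward a lowess
#' mean-dispersion trend by empirical Bayes ([squeeze_var()]), and the
#' condition coefficient is tested with a moderated t at
#' `df_prior + df_residual` degrees of freedom. Bins of single-bin genes
#' (rest-of-gene count identically zero) get `NA` with a logged reason.
#'
#' @param counts inclusion-count matrix (rows named `gene:bin`) or a list
#'   with an `inclusion` element
#' @param sheet sample sheet
#' @param covariates extra sheet columns for the design (default none:
#'   condition only)
#' @param log_path optional log file
#' @return data.frame: `feature_id`, `effect` (usage log-odds ratio), `se`,
#'   `stat`, `p`, `fdr`, `dispersion`, `reason` for NA rows
#' @export
test_deu <- function(counts, sheet, covariates = character(),
                     log_path = NULL) {
  incl <- as.matrix(if (is.list(counts)) counts$inclusion else counts)
  incl <- incl[, sheet$sample_id, drop = FALSE]
  gene <- sub(":[^:]+$", "", rownames(incl))
  tot <- rowsum(incl, gene)[gene, , drop = FALSE]
  other <- tot - incl
  X <- build_design(sheet, covariates)
  ci <- match("condition", colnames(X))
  nb <- nrow(incl)
  res <- data.frame(feature_id = rownames(incl),
                    effect = NA_real_, se = NA_real_, stat = NA_real_,
                    p = NA_real_, fdr = NA_real_, dispersion = NA_real_,
                    reason = NA_character_, stringsAsFactors = FALSE)
  fit_bin <- function(i, rho) {
    w <- tot[i, ]
    use <- w > 0
    w_eff <- w / (1 + rho * pmax(w - 1, 0))
    y <- ifelse(use, incl[i, ] / pmax(w, 1), 0)
    fit <- tryCatch(
      suppressWarnings(glm.fit(X[use, , drop = FALSE], y[use],
                               weights = w_eff[use],
                               family = quasibinomial())),
      error = function(e) NULL)
    if (is.null(fit) || fit$rank < ncol(X)) return(NULL)
    mu <- fit$fitted.values
    pear <- (fit$y - mu) * sqrt(fit$prior.weights) /
      sqrt(pmax(mu * (1 - mu), 1e-12))
    dfr <- sum(use) - ncol(X)
    list(b = fit$coefficients[ci],
         se = sqrt(glm_cov_unscaled(fit)[ci, ci]),
         phi = sum(pear^2) / dfr, dfr = dfr, mt = mean(w))
  }
  testable <- logical(nb)
  for (i in seq_len(nb)) {
    if (all(other[i, ] == 0)) {
      res$reason[i] <- "single-bin gene"
    } else if (sum(tot[i, ] > 0) <= ncol(X)) {
      res$reason[i] <- "insufficient nonzero totals"
    } else testable[i] <- TRUE
  }
  # first pass at binomial weights: genome-wide Williams intraclass
  # correlation from the excess Pearson dispersion
  rho_num <- rho_den <- c()
  for (i in which(testable)) {
    f1 <- fit_bin(i, rho = 0)
    if (is.null(f1)) next
    rho_num <- c(rho_num, (f1$phi - 1) / pmax(f1$mt - 1, 1))
  }
  rho <- if (length(rho_num) >= 10) max(0, median(rho_num)) else 0
  b_vec <- se_vec <- phi_vec <- dfr_vec <- mt_vec <- rep(NA_real_, nb)
  for (i in which(testable)) {
    f2 <- fit_bin(i, rho = rho)
    if (is.null(f2)) {
      res$reason[i] <- "degenerate fit"
      next
    }
    b_vec[i] <- f2$b
    se_vec[i] <- f2$se
    phi_vec[i] <- f2$phi
    dfr_vec[i] <- f2$dfr
    mt_vec[i] <- f2$mt
  }
  okd <- which(!is.na(phi_vec))
  if (length(okd) >= 2) {
    sq <- squeeze_var(phi_vec[okd], dfr_vec[okd],
                      covariate = log(mt_vec[okd] + 1))
    phi_post <- sq$s2_post
    df_tot <- sq$df_prior + dfr_vec[okd]
  } else {
    phi_post <- phi_vec[okd]
    df_tot <- dfr_vec[okd]
  }
  res$effect[okd] <- b_vec[okd]
  res$se[okd] <- se_vec[okd] * sqrt(phi_post)
  res$stat[okd] <- res$effect[okd] / res$se[okd]
  res$p[okd] <- 2 * pt(-abs(res$stat[okd]), df = df_tot)
  res$dispersion[okd] <- phi_post
  res$fdr <- benjamini_hochberg(res$p)
  log_line(log_path, "test_deu", n_bins = nb, n_tested = length(okd),
           n_single_bin = sum(res$reason %in% "single-bin gene"),
           williams_rho = signif(rho, 4))
  attr(res, "williams_rho") <- rho
  res
}

#' Differential methylation: moderated t-test on M-values
#'
#' Per probe, ordinary least squares of the M-values on the design (by
#' default condition, sex, age, the five immunosuppressant flags and the
#' first two principal components of the methylation data). Residual
#' variances are shrunk by empirical Bayes ([squeeze_var()]): the prior
#' variance and prior df are estimated by moment-matching the scaled-F
#' distribution of the per-probe variances, and the moderated t uses
#' `df_prior + df_residual` degrees of freedom (normal reference in the
#' complete-pooling limit). Aliased design columns are dropped with a
#' warning by [build_design()]; a `NaN` prior-df estimate falls back to the
#' ordinary t with a warning.
#'
#' @param m probes x samples matrix of M-values
#' @param sheet sample sheet
#' @param covariates sheet columns entering after condition (default the
#'   five drug flags plus sex and age, where present)
#' @param pcs optional samples x k PC score matrix ([top_principal_components()])
#' @param df_prior optional fixed prior df (0 = ordinary t, Inf = complete
#'   pooling); estimated when `NULL`
#' @return data.frame: `feature_id`, `effect` (M difference), `se`, `stat`,
#'   `p`, `fdr`, `df_total`
#' @export
test_dmr <- function(m, sheet, covariates = NULL, pcs = NULL,
                     df_prior = NULL) {
  m <- as.matrix(m)
  m <- m[, sheet$sample_id, drop = FALSE]
  if (is.null(covariates)) {
    covariates <- intersect(c("sex", "age", "tacrolimus", "mycophenolate",
                              "steroid", "everolimus", "ciclosporin"),
                            colnames(sheet))
  }
  X <- build_design(sheet, covariates, pcs = pcs)
  # small cohorts: drop trailing covariates (never intercept/condition)
  # until at least one residual degree of freedom remains
  if (nrow(X) - ncol(X) < 1 && ncol(X) > 2) {
    keep <- max(2, nrow(X) - 1)
    warning("design over-parameterized for ", nrow(X),
            " samples; dropping trailing column(s): ",
            paste(colnames(X)[(keep + 1):ncol(X)], collapse = ", "))
    X <- X[, seq_len(keep), drop = FALSE]
  }
  n <- nrow(X)
  p <- ncol(X)
  d <- n - p
  if (d < 1) stop("not enough residual degrees of freedom")
  qx <- qr(X)
  B <- qr.coef(qx, t(m))
  resid <- qr.resid(qx, t(m))
  s2 <- colSums(resid^2) / d
  sq <- squeeze_var(s2, d, df_prior = df_prior)
  d0 <- sq$df_prior
  if (is.nan(d0)) {
    warning("prior df estimate is NaN; falling back to ordinary t")
    sq <- squeeze_var(s2, d, df_prior = 0)
    d0 <- 0
  }
  ci <- match("condition", colnames(X))
  v <- solve(crossprod(X))[ci, ci]
  eff <- B[ci, ]
  se <- sqrt(sq$s2_post * v)
  tstat <- eff / se
  pval <- 2 * pt(-abs(tstat), df = d0 + d)
  data.frame(feature_id = rownames(m), effect = eff, se = se, stat = tstat,
             p = pval, fdr = benjamini_hochberg(pval), df_total = d0 + d,
             row.names = NULL, stringsAsFactors = FALSE)
}
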