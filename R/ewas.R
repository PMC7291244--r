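# Per-gene methylation-PSI association scan (single-locus EWAS) and the
# genome-wide variance-explained ANOVA.

#' Enumerate same-gene probe/bin combinations
#'
#' The association scan is restricted to combinations of an intronic probe
#' and an exon bin of the very same gene (local and remote within-gene
#' regulation). The probe-to-gene assignment comes from intron
#' containment, i.e. the gene whose intron holds the probe.
#'
#' @param probes probe records (post-QC)
#' @param introns intron table from [derive_introns()]
#' @param bins exon bins from [flatten_gene_models()]
#' @return data.frame with columns `probe_id`, `gene_id`, `bin_id`
#' @export
gene_combinations <- function(probes, introns, bins) {
  if (!nrow(introns) || !nrow(probes)) {
    return(data.frame(probe_id = character(), gene_id = character(),
                      bin_id = character(), stringsAsFactors = FALSE))
  }
  pr_gr <- GenomicRanges::GRanges(probes$chrom,
                                  IRanges::IRanges(probes$pos, probes$pos))
  in_gr <- GenomicRanges::GRanges(introns$chrom,
                                  IRanges::IRanges(introns$start, introns$end))
  hits <- GenomicRanges::findOverlaps(pr_gr, in_gr, type = "within")
  pg <- unique(data.frame(
    probe_id = probes$probe_id[S4Vectors::queryHits(hits)],
    gene_id = introns$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  if (!nrow(pg)) {
    return(data.frame(probe_id = character(), gene_id = character(),
                      bin_id = character(), stringsAsFactors = FALSE))
  }
  merged <- merge(pg, bins[, c("gene_id", "bin_id")], by = "gene_id")
  res <- merged[order(merged$gene_id, merged$probe_id, merged$bin_id),
                c("probe_id", "gene_id", "bin_id")]
  rownames(res) <- NULL
  res
}

#' Single-locus methylation-PSI association scan
#'
#' Per (probe, bin) combination within one group: a quasi-binomial
#' logit-link regression of the per-sample PSI on the probe's beta value
#' plus the first two methylation principal components, recording the
#' methylation coefficient, the odds ratio per 0.01 beta increment
#' (`exp(0.01 * coefficient)`) with a Wald t confidence interval, the
#' t-based p-value, and the unadjusted within-group Pearson correlation
#' of (beta, PSI). Combinations with fewer than `min_n` complete samples
#' or a degenerate (constant) PSI or beta are skipped with a logged count.
#'
#' @param beta probes x samples beta matrix
#' @param psi bins x samples PSI matrix (rows named `gene:bin`)
#' @param gene_index combinations from [gene_combinations()]
#' @param pcs samples x >=2 PC score matrix from
#'   [top_principal_components()]; set `NULL` to omit the covariates
#' @param sheet sample sheet
#' @param group condition label selecting the samples
#' @param min_n minimum complete samples per combination (default 5)
#' @param level confidence level for the OR interval
#' @param log_path optional log file
#' @return data.frame: `probe_id`, `gene_id`, `bin_id`, `group`,
#'   `coefficient`, `or_per_0.01` with `or_lo`/`or_hi`, `p`, `r`, `n`
#' @export
ewas_scan <- function(beta, psi, gene_index, pcs = NULL, sheet = NULL,
                      group = NULL, min_n = 5, level = 0.95,
                      log_path = NULL) {
  beta <- as.matrix(beta)
  psi <- as.matrix(psi)
  samples <- colnames(psi)
  if (!is.null(sheet) && !is.null(group)) {
    samples <- intersect(samples, sheet$sample_id[sheet$condition == group])
  }
  if (!is.null(pcs)) pcs <- as.matrix(pcs)[samples, , drop = FALSE]
  bin_key <- paste(gene_index$gene_id, gene_index$bin_id, sep = ":")
  usable <- bin_key %in% rownames(psi) & gene_index$probe_id %in% rownames(beta)
  gi <- gene_index[usable, , drop = FALSE]
  bin_key <- bin_key[usable]
  n_comb <- nrow(gi)
  out <- data.frame(gi, group = group %||% NA_character_,
                    coefficient = NA_real_, or_per_0.01 = NA_real_,
                    or_lo = NA_real_, or_hi = NA_real_, p = NA_real_,
                    r = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  n_skip <- 0L
  bmat <- beta[gi$probe_id, samples, drop = FALSE]
  pmat <- psi[bin_key, samples, drop = FALSE]
  qa <- 1 - (1 - level) / 2
  for (i in seq_len(n_comb)) {
    b <- bmat[i, ]
    y <- pmat[i, ]
    ok <- is.finite(b) & is.finite(y)
    if (sum(ok) < min_n || sd(y[ok]) == 0 || sd(b[ok]) == 0) {
      n_skip <- n_skip + 1L
      next
    }
    X <- cbind(`(Intercept)` = 1, beta = b[ok])
    if (!is.null(pcs)) X <- cbind(X, pcs[ok, 1:2, drop = FALSE])
    if (nrow(X) <= ncol(X)) {
      n_skip <- n_skip + 1L
      next
    }
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y[ok], family = quasibinomial())),
      error = function(e) NULL)
    if (is.null(fit) || fit$rank < ncol(X)) {
      n_skip <- n_skip + 1L
      next
    }
    mu <- fit$fitted.values
    dfr <- nrow(X) - ncol(X)
    phi <- sum((fit$y - mu)^2 / pmax(mu * (1 - mu), 1e-12)) / dfr
    cf <- fit$coefficients["beta"]
    se <- sqrt(glm_cov_unscaled(fit)[2, 2] * phi)
    tt <- cf / se
    q <- qt(qa, df = dfr)
    out$coefficient[i] <- cf
    out$or_per_0.01[i] <- exp(0.01 * cf)
    out$or_lo[i] <- exp(0.01 * (cf - q * se))
    out$or_hi[i] <- exp(0.01 * (cf + q * se))
    out$p[i] <- 2 * pt(-abs(tt), df = dfr)
    out$r[i] <- cor(b[ok], y[ok])
    out$n[i] <- sum(ok)
  }
  log_line(log_path, "ewas_scan", group = group %||% "all",
           combinations = n_comb, skipped = n_skip)
  out[!is.na(out$n), , drop = FALSE]
}

#' Variance of PSI explained by intronic methylation
#'
#' Per same-gene (probe, bin) combination, the R-squared of the simple
#' linear regression of PSI on beta; summarized as the mean across tests
#' with a normal-approximation 95 percent confidence interval
#' (`mean +/- 1.96 sd / sqrt(n)`).
#'
#' @inheritParams ewas_scan
#' @param min_n minimum complete samples per combination (default 5)
#' @return list with `mean_r2`, `ci` (length 2), `n_tests`, and the
#'   per-combination `r2` vector
#' @export
variance_explained <- function(beta, psi, gene_index, min_n = 5) {
  beta <- as.matrix(beta)
  psi <- as.matrix(psi)
  bin_key <- paste(gene_index$gene_id, gene_index$bin_id, sep = ":")
  usable <- bin_key %in% rownames(psi) & gene_index$probe_id %in% rownames(beta)
  gi <- gene_index[usable, , drop = FALSE]
  bmat <- beta[gi$probe_id, , drop = FALSE]
  pmat <- psi[paste(gi$gene_id, gi$bin_id, sep = ":"), , drop = FALSE]
  r2 <- vapply(seq_len(nrow(gi)), function(i) {
    b <- bmat[i, ]; y <- pmat[i, ]
    ok <- is.finite(b) & is.finite(y)
    if (sum(ok) < min_n || sd(b[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
    cor(b[ok], y[ok])^2
  }, numeric(1))
  r2 <- r2[!is.na(r2)]
  n <- length(r2)
  m <- mean(r2)
  half <- 1.96 * sd(r2) / sqrt(n)
  list(mean_r2 = m, ci = c(m - half, m + half), n_tests = n, r2 = r2)
}
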