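# Sample / probe / bin filters, normalization, beta-M conversion, PCA.
#
# Filters are idempotent and order-insensitive among themselves; every
# decision can be logged with in/out counts.

#' Drop samples with too few assigned reads
#'
#' Samples with `assigned_reads < min_assigned` are removed from the sample
#' sheet and from all count matrices. The boundary is strict: exactly
#' `min_assigned` reads is kept.
#'
#' @param sheet sample sheet data.frame with `sample_id` and
#'   `assigned_reads` columns
#' @param counts named list of matrices whose columns are sample ids (e.g.
#'   `list(inclusion =, exclusion =)`), or a single matrix
#' @param min_assigned read-count threshold (default 1,000,000)
#' @param log_path optional log file
#' @return list with elements `sheet` and `counts` (same shape as input)
#' @export
filter_samples <- function(sheet, counts, min_assigned = 1e6, log_path = NULL) {
  stop_if_missing_cols(sheet, c("sample_id", "assigned_reads"), "sample sheet")
  keep <- sheet$assigned_reads >= min_assigned
  if (!any(keep)) stop("no samples survive the assigned-reads filter")
  log_line(log_path, "filter_samples", n_in = nrow(sheet), n_kept = sum(keep),
           dropped = paste(sheet$sample_id[!keep], collapse = ";"))
  sheet <- sheet[keep, , drop = FALSE]
  subset_cols <- function(m) m[, sheet$sample_id, drop = FALSE]
  counts <- if (is.list(counts)) lapply(counts, subset_cols) else subset_cols(counts)
  list(sheet = sheet, counts = counts)
}

#' Drop blocklisted and sex-chromosome probes
#'
#' Removes probes flagged as SNP-affected, cross-reactive, or located on the
#' X/Y chromosomes. Input order is preserved.
#'
#' @param probes probe records with the three flag columns
#' @param log_path optional log file
#' @return the filtered probe data.frame
#' @export
filter_probes <- function(probes, log_path = NULL) {
  stop_if_missing_cols(probes, c("probe_id", "flag_snp", "flag_cross_reactive",
                                 "flag_sex_chrom"), "probes")
  drop <- probes$flag_snp | probes$flag_cross_reactive | probes$flag_sex_chrom
  log_line(log_path, "filter_probes", n_in = nrow(probes),
           n_kept = sum(!drop), n_snp = sum(probes$flag_snp),
           n_cross_reactive = sum(probes$flag_cross_reactive),
           n_sex_chrom = sum(probes$flag_sex_chrom))
  probes[!drop, , drop = FALSE]
}

#' Remove low-count exon bins
#'
#' Bins whose inclusion-count row sum across all retained samples is below
#' `min_total` are removed (strict: a row sum of exactly `min_total` is
#' kept).
#'
#' @param counts inclusion-count matrix (bins x samples), or a list with an
#'   `inclusion` element (the `exclusion` matrix, if present, is subset to
#'   the same rows)
#' @param min_total total-read-count threshold (default 6)
#' @param log_path optional log file
#' @return filtered matrix or list, matching the input shape
#' @export
filter_low_count_bins <- function(counts, min_total = 6, log_path = NULL) {
  incl <- if (is.list(counts)) counts$inclusion else counts
  keep <- rowSums(incl) >= min_total
  log_line(log_path, "filter_low_count_bins",
           n_in = nrow(incl), n_kept = sum(keep))
  if (is.list(counts)) {
    lapply(counts, function(m) m[keep, , drop = FALSE])
  } else {
    incl[keep, , drop = FALSE]
  }
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median, over features with a
#' positive count in every sample, of the ratio between the sample's count
#' and the feature's geometric mean across samples. If no feature is
#' positive in all samples, falls back to total-count scaling (rescaled to
#' geometric mean 1) with a warning.
#'
#' @param counts features x samples count matrix
#' @return positive numeric vector of per-sample factors, named by sample
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  logs <- log(counts)
  all_pos <- rowSums(is.finite(logs)) == ncol(counts)
  if (!any(all_pos)) {
    warning("no feature positive in all samples; falling back to total-count scaling")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
    return(setNames(sf, colnames(counts)))
  }
  log_gm <- rowMeans(logs[all_pos, , drop = FALSE])
  sf <- apply(logs[all_pos, , drop = FALSE], 2,
              function(x) exp(median(x - log_gm)))
  setNames(sf, colnames(counts))
}

M_EPS <- 1e-6

#' Convert methylation beta values to M-values
#'
#' `M = log2(beta / (1 - beta))` with beta clipped to
#' `[1e-6, 1 - 1e-6]` first so M is always finite.
#'
#' @param beta matrix (or vector) of beta values in `[0, 1]`
#' @return M-values with the same shape
#' @export
beta_to_m <- function(beta) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, M_EPS), 1 - M_EPS)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' Inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`.
#'
#' @param m matrix (or vector) of M-values
#' @return beta values with the same shape
#' @export
m_to_beta <- function(m) {
  plogis(m * log(2))
}

#' Top principal components of a features x samples matrix
#'
#' PCA over samples after centering each feature (row); returns the sample
#' scores of the first `k` components. The sign of each component is fixed
#' deterministically by requiring the largest-magnitude loading to be
#' positive.
#'
#' @param m complete (no NA) features x samples matrix
#' @param k number of components (default 2); must be `< ncol(m)`
#' @return `ncol(m) x k` score matrix with columns `PC1..PCk`
#' @export
top_principal_components <- function(m, k = 2) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix must be complete (no missing values)")
  if (k >= ncol(m)) stop("k must be smaller than the number of samples")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- colnames(m)
  scores
}
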