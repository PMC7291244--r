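# Fisher's z comparison of two independent correlations, the genome-wide
# differential-correlation scan between disease and control, and the
# cross-cohort directional replication filter.

#' Fisher's z test for the difference of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value. Vectorized over its arguments.
#'
#' @param r1,r2 sample correlations with `|r| < 1`
#' @param n1,n2 sample sizes (>= 4)
#' @return list with elements `z` and `p`
#' @export
fisher_z_diffcor <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) {
    stop("|r| must be < 1 (atanh transform is infinite at |r| = 1)")
  }
  if (any(c(n1, n2) < 4)) stop("group sizes must be at least 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Differential-correlation scan between disease and control
#'
#' Joins the two groups' association records on (probe, gene, bin), applies
#' [fisher_z_diffcor()] to the within-group Pearson correlations, adjusts
#' across all matched combinations by [benjamini_hochberg()], and flags
#' `screened = (FDR < fdr_threshold)`. Unmatched combinations are skipped
#' with a logged count.
#'
#' @param assoc_dcm,assoc_control association records from [ewas_scan()]
#'   for the disease and control group of one cohort
#' @param fdr_threshold screening threshold (default 0.05)
#' @param log_path optional log file
#' @return data.frame: `probe_id`, `gene_id`, `bin_id`, `r_dcm`,
#'   `r_control`, `n_dcm`, `n_control`, `z`, `p`, `fdr`, `screened`
#' @export
diffcor_scan <- function(assoc_dcm, assoc_control, fdr_threshold = 0.05,
                         log_path = NULL) {
  key <- c("probe_id", "gene_id", "bin_id")
  a <- assoc_dcm[, c(key, "r", "n")]
  b <- assoc_control[, c(key, "r", "n")]
  names(a)[4:5] <- c("r_dcm", "n_dcm")
  names(b)[4:5] <- c("r_control", "n_control")
  mg <- merge(a, b, by = key)
  log_line(log_path, "diffcor_scan",
           n_dcm_records = nrow(a), n_control_records = nrow(b),
           n_matched = nrow(mg),
           n_unmatched = nrow(a) + nrow(b) - 2 * nrow(mg))
  ok <- abs(mg$r_dcm) < 1 & abs(mg$r_control) < 1 &
    mg$n_dcm >= 4 & mg$n_control >= 4
  mg <- mg[ok, , drop = FALSE]
  fz <- fisher_z_diffcor(mg$r_dcm, mg$n_dcm, mg$r_control, mg$n_control)
  mg$z <- fz$z
  mg$p <- fz$p
  mg$fdr <- benjamini_hochberg(mg$p)
  mg$screened <- mg$fdr < fdr_threshold
  mg <- mg[order(mg$p), , drop = FALSE]
  rownames(mg) <- NULL
  mg
}

#' Directional replication across cohorts
#'
#' A screening-cohort candidate is `replicated` when it was screened
#' (FDR-significant) there and reaches a raw `p < p_threshold` in the
#' replication cohort, and `directionally_replicated` when in addition the
#' sign of the disease-group correlation agrees across cohorts, the sign
#' of the control-group correlation agrees across cohorts, and the two
#' groups' correlations have opposite signs (the group-reversed pattern).
#' Candidates absent from the replication records are not replicated and
#' are counted in the log.
#'
#' @param screen differential-correlation records of the screening cohort
#'   ([diffcor_scan()] output)
#' @param repl differential-correlation records of the replication cohort
#' @param p_threshold raw replication p threshold (default 0.05)
#' @param log_path optional log file
#' @return the screening records with replication columns
#'   (`p_replication`, `r_dcm_replication`, `r_control_replication`,
#'   `replicated`, `directionally_replicated`) appended
#' @export
directional_replication <- function(screen, repl, p_threshold = 0.05,
                                    log_path = NULL) {
  key <- c("probe_id", "gene_id", "bin_id")
  rp <- repl[, c(key, "r_dcm", "r_control", "p")]
  names(rp)[4:6] <- c("r_dcm_replication", "r_control_replication",
                      "p_replication")
  out <- merge(screen, rp, by = key, all.x = TRUE)
  absent <- is.na(out$p_replication)
  log_line(log_path, "directional_replication",
           candidates = sum(out$screened),
           absent_from_replication = sum(absent & out$screened))
  out$replicated <- out$screened & !absent & out$p_replication < p_threshold
  same_dcm <- sign(out$r_dcm) == sign(out$r_dcm_replication)
  same_ctrl <- sign(out$r_control) == sign(out$r_control_replication)
  reversed <- sign(out$r_dcm) != sign(out$r_control)
  out$directionally_replicated <- out$replicated &
    !is.na(same_dcm) & same_dcm & !is.na(same_ctrl) & same_ctrl & reversed
  out[order(out$p), , drop = FALSE]
}
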