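# Percent-spliced-in quantification from bin-level inclusion and
# skip-junction (exclusion) read counts.

#' Compute percent-spliced-in (PSI) per bin and sample
#'
#' Length-normalized inclusion fraction:
#' `PSI = (I / L_b) / (I / L_b + E / L_J)` where `I` is the bin's inclusion
#' read count, `E` its skip-junction read count, `L_b` the bin width and
#' `L_J` the effective junction length (`read_length - 1` by default).
#' Entries with no evidence (`I + E = 0`) are `NA`. Bins of single-bin
#' genes, which can accumulate no exclusion reads, therefore have PSI 1
#' wherever the gene is expressed.
#'
#' @param inclusion bins x samples inclusion count matrix
#' @param exclusion bins x samples exclusion (skip-junction) count matrix,
#'   same dimnames
#' @param bin_width numeric vector of bin widths, named by the inclusion
#'   matrix rownames (or in matching order)
#' @param read_length read length used to form the effective junction
#'   length `L_J = read_length - 1` (default 100)
#' @return bins x samples matrix of PSI values in `[0, 1]` with `NA` where
#'   there is no evidence
#' @export
compute_psi <- function(inclusion, exclusion, bin_width, read_length = 100) {
  inclusion <- as.matrix(inclusion)
  exclusion <- as.matrix(exclusion)
  if (!identical(dim(inclusion), dim(exclusion))) {
    stop("inclusion and exclusion matrices must have identical shape")
  }
  if (any(inclusion < 0) || any(exclusion < 0)) {
    stop("counts must be non-negative")
  }
  if (!is.null(names(bin_width)) && !is.null(rownames(inclusion))) {
    bin_width <- bin_width[rownames(inclusion)]
  }
  if (length(bin_width) != nrow(inclusion)) {
    stop("bin_width must match the count matrix rows")
  }
  lj <- read_length - 1
  di <- inclusion / bin_width
  de <- exclusion / lj
  psi <- di / (di + de)
  psi[inclusion + exclusion == 0] <- NA_real_
  dimnames(psi) <- dimnames(inclusion)
  psi
}
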