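# Brute-force oracles and random-instance generators used by the unit and
# acceptance tests. Every oracle is deliberately naive (base-wise scans,
# explicit enumeration) and independent of the package's implementation.

# base-wise exon-bin flattening: walk every base of the gene span, start a
# new bin wherever coverage begins or any transcript boundary is crossed
oracle_flatten_gene <- function(starts, ends) {
  lo <- min(starts)
  hi <- max(ends)
  covered <- rep(FALSE, hi - lo + 1)
  for (i in seq_along(starts)) covered[(starts[i]:ends[i]) - lo + 1] <- TRUE
  is_start <- rep(FALSE, hi - lo + 1)
  is_end <- rep(FALSE, hi - lo + 1)
  is_start[starts - lo + 1] <- TRUE
  is_end[ends - lo + 1] <- TRUE
  bins <- list()
  cur <- NA
  for (b in seq_along(covered)) {
    if (!covered[b]) {
      if (!is.na(cur)) {
        bins[[length(bins) + 1]] <- c(cur, b - 1)
        cur <- NA
      }
      next
    }
    if (is.na(cur)) {
      cur <- b
    } else if (is_start[b] || is_end[b - 1]) {
      bins[[length(bins) + 1]] <- c(cur, b - 1)
      cur <- b
    }
  }
  if (!is.na(cur)) bins[[length(bins) + 1]] <- c(cur, length(covered))
  m <- do.call(rbind, bins)
  data.frame(start = m[, 1] + lo - 1, end = m[, 2] + lo - 1)
}

# gap enumeration between sorted disjoint bins
oracle_introns_gene <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  out <- list()
  for (i in seq_len(length(starts) - 1)) {
    s <- ends[i] + 1
    e <- starts[i + 1] - 1
    if (e >= s) out[[length(out) + 1]] <- c(s, e)
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# explicit step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(p[o[i:m]] * m / seq(i, m)))
  }
  adj
}

# per-entry PSI
oracle_psi <- function(I, E, L, LJ) {
  out <- matrix(NA_real_, nrow(I), ncol(I))
  for (i in seq_len(nrow(I))) for (j in seq_len(ncol(I))) {
    if (I[i, j] + E[i, j] == 0) next
    di <- I[i, j] / L[i]
    de <- E[i, j] / LJ
    out[i, j] <- di / (di + de)
  }
  dimnames(out) <- dimnames(I)
  out
}

# enumeration oracle for flank pairing on one gene: scan introns for
# containment, take the immediately adjacent bins, count distances base by
# base
oracle_pairs_gene <- function(pos, bin_start, bin_end) {
  o <- order(bin_start)
  bin_start <- bin_start[o]
  bin_end <- bin_end[o]
  out <- list()
  for (i in seq_len(length(bin_start) - 1)) {
    s <- bin_end[i] + 1
    e <- bin_start[i + 1] - 1
    if (e < s) next
    for (p in pos[pos >= s & pos <= e]) {
      d_dn <- sum(seq(p + 1, bin_start[i + 1]) > 0)   # base count to next bin
      d_up <- sum(seq(bin_end[i], p - 1) > 0)          # base count from prev bin
      out[[length(out) + 1]] <- data.frame(
        kind = c("intron-exon", "exon-intron"),
        bin = c(o[i + 1], o[i]), pos = p, distance = c(d_dn, d_up))
    }
  }
  if (!length(out)) {
    return(data.frame(kind = character(), bin = integer(), pos = integer(),
                      distance = integer()))
  }
  do.call(rbind, out)
}

# random multi-transcript gene models (non-overlapping exons per transcript)
random_gene_models <- function(n_genes = 3, span = 300, max_tx = 3,
                               max_exons = 4) {
  out <- list()
  for (g in seq_len(n_genes)) {
    offset <- (g - 1) * (span + 50)
    n_tx <- sample(max_tx, 1)
    for (t in seq_len(n_tx)) {
      k <- sample(max_exons, 1)
      cuts <- sort(sample(seq_len(span), 2 * k))
      out[[length(out) + 1]] <- data.frame(
        gene_id = sprintf("g%02d", g),
        transcript_id = sprintf("g%02d.t%d", g, t),
        chrom = "chr1", strand = "+",
        start = offset + cuts[seq(1, 2 * k, 2)],
        end = offset + cuts[seq(2, 2 * k, 2)],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# tiny deterministic two-bin scaffold used by several pairing tests
two_bin_scaffold <- function() {
  models <- data.frame(
    gene_id = "g1", transcript_id = "g1.t1", chrom = "chr1", strand = "+",
    start = c(100L, 300L), end = c(200L, 400L), stringsAsFactors = FALSE)
  bins <- flatten_gene_models(models)
  list(models = models, bins = bins, introns = derive_introns(bins))
}

make_probe <- function(probe_id, chrom, pos) {
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
             flag_snp = FALSE, flag_cross_reactive = FALSE,
             flag_sex_chrom = FALSE, stringsAsFactors = FALSE)
}

# minimal sample sheet for the differential tests
make_sheet <- function(n_dcm, n_ctrl, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_dcm + n_ctrl
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    condition = c(rep("DCM", n_dcm), rep("control", n_ctrl)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = round(rnorm(n, 55, 8)),
    assigned_reads = rep(2e6, n),
    stringsAsFactors = FALSE)
}
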