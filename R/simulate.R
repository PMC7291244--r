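# Ground-truth-labelled synthetic datasets with the statistical structure
# the pipeline assumes: flattened gene models on synthetic chromosomes,
# 450K-style intronic/exonic probe placement with blocklist flags,
# logit-normal beta values with planted differential methylation,
# negative-binomial exon counts with gene-level expression effects and
# planted usage coupling to flanking-intron methylation, group-reversed
# correlation loci, batch effects, and immunosuppressant flags confined to
# controls (covariate-condition confounding). Identical config implies
# byte-identical output.

#' Build a simulation configuration
#'
#' Defaults mirror the study conditions the pipeline targets: a screening
#' cohort of 34 cases / 21 controls and a replication cohort of 11 / 5,
#' one intronic probe per intron on average, genome-wide positive
#' methylation-usage coupling, and 20 group-reversed loci planted at
#' within-group correlations of -0.75 (cases) / +0.75 (controls) (a level
#' chosen by an a priori power analysis of the Fisher-z screening step;
#' see the methods vignette), alongside 10 same-sign differential-
#' magnitude confound loci for the directionality filter.
#'
#' @param seed integer RNG seed; identical config gives identical data
#' @param n_genes number of genes
#' @param bins_per_gene integer range (min, max) of exon bins per gene
#' @param bin_width range (min, max) of bin widths in bp (log-uniform)
#' @param intron_width_meanlog,intron_width_sdlog lognormal intron widths
#' @param probes_per_intron Poisson mean of intronic probes per intron
#' @param n_dcm,n_control named per-cohort sample counts
#'   (`c(screening =, replication =)`)
#' @param expr_meanlog,expr_sdlog lognormal gene expression means
#' @param nb_dispersion gene-sample negative-binomial dispersion
#' @param read_length read length (effective junction length is
#'   `read_length - 1`)
#' @param psi0_meanlogit,psi0_sdlogit baseline bin PSI on the logit scale
#' @param psi_logit_sd per-bin-sample biological PSI noise (logit scale)
#' @param coupling methylation-usage coupling on the PSI logit per unit
#'   beta; `coupled_fraction` of probe-adjacent bins are affected
#' @param coupled_fraction fraction of flank pairs carrying the coupling
#' @param deu_effect,deu_fraction planted usage logit shift in cases and
#'   affected-bin fraction
#' @param dge_lfc,dge_fraction planted expression log2 fold change and
#'   affected-gene fraction
#' @param dmr_effect,dmr_fraction planted M-value shift in cases and
#'   affected-probe fraction
#' @param m_mean,m_sd_probe,m_sd_noise M-value location, across-probe sd,
#'   within-probe across-sample sd
#' @param n_reversed_loci,reversed_r group-reversed loci count and their
#'   target within-group correlations `c(dcm =, control =)`
#' @param n_samesign_loci,samesign_r same-sign differential-magnitude
#'   confound loci (should be rejected by the directionality filter)
#' @param reversed_latent_sd PSI-scale spread (sd around 0.5, truncated to
#'   `[0.05, 0.95]`) of the correlated latent at planted loci
#' @param n_batches,batch_sd batch count and multiplicative batch effect
#'   sd (log scale; also used as the M-value batch shift sd)
#' @param sample_depth_sd per-sample lognormal depth variation
#' @param frac_probe_snp,frac_probe_cross_reactive fractions of probes
#'   carrying blocklist flags
#' @param frac_probe_exonic,frac_probe_sex_chrom fractions of additional
#'   exonic / sex-chromosome probes relative to the intronic probe count
#' @param n_low_read_samples screening samples planted below the
#'   1,000,000 assigned-read threshold
#' @param antisense_pair place the last two genes as an overlapping
#'   sense/antisense pair?
#' @return a validated `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 500L,
                       bins_per_gene = c(6L, 20L),
                       bin_width = c(50L, 400L),
                       intron_width_meanlog = log(1500),
                       intron_width_sdlog = 0.8,
                       probes_per_intron = 1.0,
                       n_dcm = c(screening = 34L, replication = 11L),
                       n_control = c(screening = 21L, replication = 5L),
                       expr_meanlog = log(300),
                       expr_sdlog = 0.7,
                       nb_dispersion = 0.1,
                       read_length = 100L,
                       psi0_meanlogit = 1.0,
                       psi0_sdlogit = 0.8,
                       psi_logit_sd = 0.5,
                       coupling = 1.2,
                       coupled_fraction = 1.0,
                       deu_effect = 1.0,
                       deu_fraction = 0.1,
                       dge_lfc = 1.0,
                       dge_fraction = 0.1,
                       dmr_effect = 1.0,
                       dmr_fraction = 0.05,
                       m_mean = 0,
                       m_sd_probe = 1.5,
                       m_sd_noise = 0.5,
                       n_reversed_loci = 20L,
                       reversed_r = c(dcm = -0.75, control = 0.75),
                       n_samesign_loci = 10L,
                       samesign_r = c(dcm = 0.8, control = 0.45),
                       reversed_latent_sd = 0.28,
                       n_batches = 2L,
                       batch_sd = 0.1,
                       sample_depth_sd = 0.15,
                       frac_probe_snp = 0.02,
                       frac_probe_cross_reactive = 0.02,
                       frac_probe_exonic = 0.05,
                       frac_probe_sex_chrom = 0.02,
                       n_low_read_samples = 0L,
                       antisense_pair = TRUE) {
  cfg <- as.list(environment())
  fr <- c(coupled_fraction, deu_fraction, dge_fraction, dmr_fraction,
          frac_probe_snp, frac_probe_cross_reactive, frac_probe_exonic,
          frac_probe_sex_chrom)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (any(c(n_dcm, n_control) < 4)) stop("at least 4 samples per group")
  if (!all(c("screening", "replication") %in% names(n_dcm)) ||
      !all(c("screening", "replication") %in% names(n_control))) {
    stop("n_dcm and n_control need 'screening' and 'replication' entries")
  }
  if (any(abs(c(reversed_r, samesign_r)) >= 1)) {
    stop("target correlations must lie strictly inside (-1, 1)")
  }
  if (n_genes < 1 || bins_per_gene[1] < 1) stop("need at least one gene and bin")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("methsplice simulation config\n")
  cat(sprintf("  genes: %d  bins/gene: %d-%d  probes/intron (mean): %.2f\n",
              x$n_genes, x$bins_per_gene[1], x$bins_per_gene[2],
              x$probes_per_intron))
  cat(sprintf("  screening %d DCM / %d control; replication %d / %d\n",
              x$n_dcm["screening"], x$n_control["screening"],
              x$n_dcm["replication"], x$n_control["replication"]))
  cat(sprintf("  coupling %.2f (fraction %.2f)  deu %.2f/%.2f  dmr %.2f/%.2f  dge %.2f/%.2f\n",
              x$coupling, x$coupled_fraction, x$deu_effect, x$deu_fraction,
              x$dmr_effect, x$dmr_fraction, x$dge_lfc, x$dge_fraction))
  cat(sprintf("  reversed loci: %d at r = (%.2f, %.2f); same-sign confounds: %d\n",
              x$n_reversed_loci, x$reversed_r["dcm"], x$reversed_r["control"],
              x$n_samesign_loci))
  invisible(x)
}

# -- internal layout helpers -------------------------------------------------

sim_layout <- function(cfg) {
  nb <- sample(seq(cfg$bins_per_gene[1], cfg$bins_per_gene[2]),
               cfg$n_genes, replace = TRUE)
  gene_id <- sprintf("G%04d", seq_len(cfg$n_genes))
  chroms <- paste0("chr", 1:4)
  chrom <- chroms[((seq_len(cfg$n_genes) - 1) %% length(chroms)) + 1]
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  cursor <- setNames(rep(1L, length(chroms)), chroms)
  bins <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    n <- nb[g]
    widths <- round(exp(runif(n, log(cfg$bin_width[1]), log(cfg$bin_width[2]))))
    gaps <- pmax(2L, round(rlnorm(n - 1, cfg$intron_width_meanlog,
                                  cfg$intron_width_sdlog)))
    start0 <- cursor[chrom[g]] + 10000L
    starts <- start0 + cumsum(c(0L, widths[-n] + gaps))
    ends <- starts + widths - 1L
    bins[[g]] <- data.frame(gene_id = gene_id[g],
                            bin_id = sprintf("E%03d", seq_len(n)),
                            chrom = chrom[g], strand = strand[g],
                            start = as.integer(starts), end = as.integer(ends),
                            width = as.integer(widths),
                            stringsAsFactors = FALSE)
    cursor[chrom[g]] <- as.integer(ends[n])
  }
  if (cfg$antisense_pair && cfg$n_genes >= 2) {
    # overlap the last gene with the one before it on the opposite strand
    a <- cfg$n_genes - 1L
    b <- cfg$n_genes
    shift <- bins[[a]]$start[1] + 137L - bins[[b]]$start[1]
    bins[[b]]$start <- bins[[b]]$start + shift
    bins[[b]]$end <- bins[[b]]$end + shift
    bins[[b]]$chrom <- bins[[a]]$chrom[1]
    bins[[b]]$strand <- if (bins[[a]]$strand[1] == "+") "-" else "+"
  }
  do.call(rbind, bins)
}

sim_transcripts <- function(bins) {
  # transcript 1 carries every bin; transcript 2 (genes with >= 4 bins)
  # skips one interior bin, so the GTF exercises multi-transcript parsing
  # while flattening still recovers exactly the planted bins
  out <- lapply(split(bins, bins$gene_id), function(b) {
    t1 <- data.frame(gene_id = b$gene_id, transcript_id = paste0(b$gene_id[1], ".T1"),
                     chrom = b$chrom, strand = b$strand,
                     start = b$start, end = b$end, stringsAsFactors = FALSE)
    if (nrow(b) >= 4) {
      drop <- sample(2:(nrow(b) - 1), 1)
      b2 <- b[-drop, , drop = FALSE]
      t2 <- data.frame(gene_id = b2$gene_id, transcript_id = paste0(b2$gene_id[1], ".T2"),
                       chrom = b2$chrom, strand = b2$strand,
                       start = b2$start, end = b2$end, stringsAsFactors = FALSE)
      rbind(t1, t2)
    } else t1
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

sim_probes <- function(cfg, bins, introns) {
  k <- rpois(nrow(introns), cfg$probes_per_intron)
  idx <- rep(seq_len(nrow(introns)), k)
  pos <- introns$start[idx] +
    floor(runif(length(idx)) * (introns$end[idx] - introns$start[idx] + 1))
  pr <- data.frame(
    probe_id = sprintf("cg%08d", seq_along(idx)),
    chrom = introns$chrom[idx],
    pos = as.integer(pos),
    intron_gene = introns$gene_id[idx],
    upstream_bin = introns$upstream_bin[idx],
    downstream_bin = introns$downstream_bin[idx],
    stringsAsFactors = FALSE)
  n_in <- nrow(pr)
  n_ex <- round(cfg$frac_probe_exonic * n_in)
  if (n_ex > 0) {
    bi <- sample(nrow(bins), n_ex, replace = TRUE)
    pos_ex <- bins$start[bi] +
      floor(runif(n_ex) * (bins$end[bi] - bins$start[bi] + 1))
    pr <- rbind(pr, data.frame(
      probe_id = sprintf("cg%08d", n_in + seq_len(n_ex)),
      chrom = bins$chrom[bi], pos = as.integer(pos_ex),
      intron_gene = NA_character_, upstream_bin = NA_character_,
      downstream_bin = NA_character_, stringsAsFactors = FALSE))
  }
  n_sex <- round(cfg$frac_probe_sex_chrom * n_in)
  if (n_sex > 0) {
    pr <- rbind(pr, data.frame(
      probe_id = sprintf("cg%08d", n_in + n_ex + seq_len(n_sex)),
      chrom = "chrX", pos = as.integer(sample(1e6, n_sex, replace = TRUE)),
      intron_gene = NA_character_, upstream_bin = NA_character_,
      downstream_bin = NA_character_, stringsAsFactors = FALSE))
  }
  pr$flag_snp <- runif(nrow(pr)) < cfg$frac_probe_snp
  pr$flag_cross_reactive <- runif(nrow(pr)) < cfg$frac_probe_cross_reactive
  pr$flag_sex_chrom <- pr$chrom %in% c("chrX", "chrY")
  pr
}

sim_sheet <- function(cfg, cohort) {
  n_d <- cfg$n_dcm[[cohort]]
  n_c <- cfg$n_control[[cohort]]
  n <- n_d + n_c
  pre <- if (cohort == "screening") "SCR" else "REP"
  condition <- c(rep("DCM", n_d), rep("control", n_c))
  drugs <- c("tacrolimus", "mycophenolate", "steroid", "everolimus",
             "ciclosporin")
  p_drug <- c(0.8, 0.7, 0.5, 0.2, 0.3)
  sheet <- data.frame(
    sample_id = sprintf("%s%02d", pre, seq_len(n)),
    condition = condition,
    cohort = cohort,
    sex = sample(c("M", "F"), n, replace = TRUE),
    age = as.integer(round(rnorm(n, 55, 10))),
    stringsAsFactors = FALSE)
  for (j in seq_along(drugs)) {
    # immunosuppressants only in controls (transplant recipients):
    # deliberate covariate-condition confounding
    sheet[[drugs[j]]] <- condition == "control" & runif(n) < p_drug[j]
  }
  # batch composition imbalanced with respect to condition
  p_b1 <- ifelse(condition == "DCM", 0.7, 0.3)
  other <- if (cfg$n_batches > 1) {
    sample(2:cfg$n_batches, n, replace = TRUE)
  } else rep(1L, n)
  sheet$batch_date <- paste0("batch", ifelse(runif(n) < p_b1, 1L, other))
  sheet$flowcell <- paste0("FC", sample(2, n, replace = TRUE))
  sheet$assigned_reads <- as.integer(round(rlnorm(n, log(1e7), 0.3)))
  if (cohort == "screening" && cfg$n_low_read_samples > 0) {
    low <- seq_len(min(cfg$n_low_read_samples, n))
    sheet$assigned_reads[low] <- as.integer(sample(1e5:9e5, length(low)))
  }
  sheet
}

# -- main generator ----------------------------------------------------------

#' Simulate a full two-cohort dataset with ground-truth labels
#'
#' Generates annotation, probe manifest with blocklist flags, beta-value
#' and exon-count matrices for screening and replication cohorts, sample
#' sheets, and a truth table of every planted effect. See [sim_config()]
#' for the generative model's parameters and the methods vignette for its
#' assumptions.
#'
#' @param cfg a [sim_config()] object
#' @return an object of class `methsplice_sim`: list with `annotation`
#'   (exon records), `bins`, `introns`, `probes`, `cohorts` (per cohort:
#'   `sheet`, `beta`, `inclusion`, `exclusion`, `psi_true`), `truth`, and
#'   `config`
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  bins <- sim_layout(cfg)
  annotation <- sim_transcripts(bins)
  introns <- derive_introns(bins)
  probes <- sim_probes(cfg, bins, introns)

  # gene-level expression, shared across cohorts
  mu_g <- rlnorm(cfg$n_genes, cfg$expr_meanlog, cfg$expr_sdlog)
  names(mu_g) <- sprintf("G%04d", seq_len(cfg$n_genes))
  dge_genes <- names(mu_g)[runif(cfg$n_genes) < cfg$dge_fraction]

  intronic <- !is.na(probes$intron_gene)
  bin_width_of <- setNames(bins$width, paste(bins$gene_id, bins$bin_id,
                                             sep = ":"))
  # planted correlation loci live in adequately expressed genes (top half
  # of the expression distribution) with partner bins wide enough for
  # read coverage, so that their PSI, and hence the planted within-group
  # correlation, is estimable from the counts
  estimable <- intronic &
    mu_g[probes$intron_gene] >= median(mu_g) &
    bin_width_of[paste(probes$intron_gene, probes$downstream_bin,
                       sep = ":")] >= 100
  estimable[is.na(estimable)] <- FALSE
  eligible <- which(intronic & estimable & !probes$flag_snp &
                      !probes$flag_cross_reactive & !probes$flag_sex_chrom)
  n_planted <- cfg$n_reversed_loci + cfg$n_samesign_loci
  # one planted locus per partner bin: a shared bin would overwrite an
  # earlier planted construction
  cand <- if (length(eligible)) sample(eligible) else integer()
  cand <- cand[!duplicated(paste(probes$intron_gene[cand],
                                 probes$downstream_bin[cand]))]
  if (n_planted > length(cand)) {
    stop(sprintf(
      "config inconsistency: %d planted loci requested but only %d eligible intronic probes",
      n_planted, length(cand)))
  }
  planted_idx <- if (n_planted > 0) cand[seq_len(n_planted)] else integer()
  rev_idx <- utils::head(planted_idx, cfg$n_reversed_loci)
  ss_idx <- utils::tail(planted_idx, cfg$n_samesign_loci)

  bin_key <- paste(bins$gene_id, bins$bin_id, sep = ":")
  planted_bin_key <- paste(probes$intron_gene[planted_idx],
                           probes$downstream_bin[planted_idx], sep = ":")

  # bin-level baselines; planted-locus partner bins are centred at
  # PSI 0.5 (alternative exons) so the planted correlation has room
  psi0 <- plogis(rnorm(nrow(bins), cfg$psi0_meanlogit, cfg$psi0_sdlogit))
  names(psi0) <- bin_key
  psi0[planted_bin_key] <- 0.5
  deu_eligible <- setdiff(bin_key, planted_bin_key)
  deu_bins <- deu_eligible[runif(length(deu_eligible)) < cfg$deu_fraction]

  # probe-level methylation baselines
  m0 <- rnorm(nrow(probes), cfg$m_mean, cfg$m_sd_probe)
  dmr_eligible <- setdiff(which(intronic), planted_idx)
  dmr_idx <- dmr_eligible[runif(length(dmr_eligible)) < cfg$dmr_fraction]

  # coupled flank pairs: every probe-adjacent bin, both orientations,
  # thinned by coupled_fraction; planted loci bins are handled separately
  adj <- rbind(
    data.frame(probe = which(intronic), gene = probes$intron_gene[intronic],
               bin = probes$downstream_bin[intronic], kind = "intron-exon",
               stringsAsFactors = FALSE),
    data.frame(probe = which(intronic), gene = probes$intron_gene[intronic],
               bin = probes$upstream_bin[intronic], kind = "exon-intron",
               stringsAsFactors = FALSE))
  adj$bin_key <- paste(adj$gene, adj$bin, sep = ":")
  adj <- adj[!(adj$bin_key %in% planted_bin_key), , drop = FALSE]
  adj <- adj[runif(nrow(adj)) < cfg$coupled_fraction, , drop = FALSE]

  gene_of_bin <- match(bins$gene_id, names(mu_g))
  w_b <- bins$width / 1000
  w_j <- (cfg$read_length - 1) / 1000

  cohorts <- list()
  for (cohort in c("screening", "replication")) {
    sheet <- sim_sheet(cfg, cohort)
    n <- nrow(sheet)
    is_dcm <- sheet$condition == "DCM"
    batches <- sort(unique(sheet$batch_date))
    batch_shift_m <- setNames(rnorm(length(batches), 0, cfg$batch_sd), batches)
    batch_fac <- setNames(exp(rnorm(length(batches), 0, cfg$batch_sd)), batches)
    depth <- exp(rnorm(n, 0, cfg$sample_depth_sd))

    # methylation: M-values, then beta
    M <- matrix(m0, nrow(probes), n) +
      matrix(rnorm(nrow(probes) * n, 0, cfg$m_sd_noise), nrow(probes), n)
    M <- sweep(M, 2, batch_shift_m[sheet$batch_date], "+")
    if (length(dmr_idx)) {
      M[dmr_idx, is_dcm] <- M[dmr_idx, is_dcm] + cfg$dmr_effect
    }
    rownames(M) <- probes$probe_id
    colnames(M) <- sheet$sample_id
    beta <- m_to_beta(M)

    # usage logits
    eta <- matrix(qlogis(psi0), nrow(bins), n)
    rownames(eta) <- bin_key
    colnames(eta) <- sheet$sample_id
    if (length(deu_bins)) {
      eta[deu_bins, is_dcm] <- eta[deu_bins, is_dcm] + cfg$deu_effect
    }
    if (nrow(adj)) {
      contrib <- cfg$coupling * (beta[adj$probe, , drop = FALSE] - 0.5)
      agg <- rowsum(contrib, group = adj$bin_key)
      eta[rownames(agg), ] <- eta[rownames(agg), ] + agg
    }
    eta <- eta + matrix(rnorm(length(eta), 0, cfg$psi_logit_sd), nrow(eta))
    psi_true <- plogis(eta)

    # planted loci: construct the partner bin's PSI linearly in a latent
    # that carries the target within-group correlation to the probe's
    # methylation; the linear (PSI-scale) construction keeps the Pearson
    # correlation from being compressed by the logistic transform
    plant_one <- function(pidx, r_targets) {
      bkey <- paste(probes$intron_gene[pidx], probes$downstream_bin[pidx],
                    sep = ":")
      for (grp in c(TRUE, FALSE)) {   # TRUE = DCM
        cols <- which(is_dcm == grp)
        rho <- if (grp) r_targets[["dcm"]] else r_targets[["control"]]
        zb <- scale(M[pidx, cols])[, 1]
        lat <- rho * zb + sqrt(1 - rho^2) * rnorm(length(cols))
        psi_true[bkey, cols] <<- pmin(0.95, pmax(0.05,
          0.5 + cfg$reversed_latent_sd * lat))
      }
      bkey
    }
    rev_keys <- vapply(rev_idx, plant_one, character(1),
                       r_targets = as.list(cfg$reversed_r))
    ss_keys <- vapply(ss_idx, plant_one, character(1),
                      r_targets = as.list(cfg$samesign_r))

    # counts
    mu_gs <- outer(mu_g, depth * batch_fac[sheet$batch_date])
    if (length(dge_genes)) {
      mu_gs[dge_genes, is_dcm] <- mu_gs[dge_genes, is_dcm] * 2^cfg$dge_lfc
    }
    u <- matrix(rgamma(length(mu_gs), shape = 1 / cfg$nb_dispersion,
                       scale = cfg$nb_dispersion), nrow(mu_gs))
    mu_gs <- mu_gs * u
    mu_bin <- mu_gs[gene_of_bin, , drop = FALSE] * w_b
    inclusion <- matrix(rpois(length(mu_bin), mu_bin * psi_true),
                        nrow(bins), n)
    mu_ex <- mu_gs[gene_of_bin, , drop = FALSE] * w_j
    exclusion <- matrix(rpois(length(mu_ex), mu_ex * (1 - psi_true)),
                        nrow(bins), n)
    dimnames(inclusion) <- dimnames(exclusion) <- list(bin_key, sheet$sample_id)

    cohorts[[cohort]] <- list(sheet = sheet, beta = beta,
                              inclusion = inclusion, exclusion = exclusion,
                              psi_true = psi_true)
  }

  truth <- list(
    genes = data.frame(gene_id = names(mu_g), mu = mu_g,
                       is_dge = names(mu_g) %in% dge_genes,
                       lfc = ifelse(names(mu_g) %in% dge_genes, cfg$dge_lfc, 0),
                       row.names = NULL, stringsAsFactors = FALSE),
    bins = data.frame(feature_id = bin_key, psi0 = psi0,
                      is_deu = bin_key %in% deu_bins,
                      deu_effect = ifelse(bin_key %in% deu_bins,
                                          cfg$deu_effect, 0),
                      row.names = NULL, stringsAsFactors = FALSE),
    probes = data.frame(probe_id = probes$probe_id,
                        is_intronic = intronic,
                        is_dmr = seq_len(nrow(probes)) %in% dmr_idx,
                        dmr_effect = ifelse(seq_len(nrow(probes)) %in% dmr_idx,
                                            cfg$dmr_effect, 0),
                        row.names = NULL, stringsAsFactors = FALSE),
    coupled_pairs = data.frame(probe_id = probes$probe_id[adj$probe],
                               gene_id = adj$gene, bin_id = adj$bin,
                               kind = adj$kind, coupling = cfg$coupling,
                               row.names = NULL, stringsAsFactors = FALSE),
    reversed = data.frame(probe_id = probes$probe_id[rev_idx],
                          gene_id = probes$intron_gene[rev_idx],
                          bin_id = probes$downstream_bin[rev_idx],
                          r_dcm = rep(cfg$reversed_r[["dcm"]], length(rev_idx)),
                          r_control = rep(cfg$reversed_r[["control"]],
                                          length(rev_idx)),
                          row.names = NULL, stringsAsFactors = FALSE),
    samesign = data.frame(probe_id = probes$probe_id[ss_idx],
                          gene_id = probes$intron_gene[ss_idx],
                          bin_id = probes$downstream_bin[ss_idx],
                          r_dcm = rep(cfg$samesign_r[["dcm"]], length(ss_idx)),
                          r_control = rep(cfg$samesign_r[["control"]],
                                          length(ss_idx)),
                          row.names = NULL, stringsAsFactors = FALSE)
  )

  structure(list(annotation = annotation, bins = bins, introns = introns,
                 probes = probes[, c("probe_id", "chrom", "pos", "flag_snp",
                                     "flag_cross_reactive", "flag_sex_chrom")],
                 cohorts = cohorts, truth = truth, config = cfg),
            class = "methsplice_sim")
}

#' @export
print.methsplice_sim <- function(x, ...) {
  cat("methsplice synthetic dataset\n")
  cat(sprintf("  genes: %d  bins: %d  probes: %d (%d intronic)\n",
              nrow(x$truth$genes), nrow(x$bins), nrow(x$probes),
              sum(x$truth$probes$is_intronic)))
  for (ch in names(x$cohorts)) {
    sh <- x$cohorts[[ch]]$sheet
    cat(sprintf("  %s: %d DCM / %d control\n", ch,
                sum(sh$condition == "DCM"), sum(sh$condition == "control")))
  }
  invisible(x)
}

#' Simulate pair-level flank-regression data with a planted coefficient
#'
#' Draws flank pairs directly at the level the pooled regression sees: a
#' methylation value per pair, a gene-total offset, and an inclusion count
#' with mean `total * exp(intercept + beta_star * beta +
#' distance_coef * log10(distance))` and quasi-Poisson noise
#' (`Var = phi * mean`, via an NB1 draw). Used for parameter-recovery,
#' coverage and null-calibration studies of [fit_flank_glm()].
#'
#' @param n number of pairs
#' @param beta_star planted methylation coefficient (log scale)
#' @param phi dispersion (>= 1; 1 gives plain Poisson)
#' @param intercept baseline log usage fraction (default `log(0.05)`)
#' @param distance_coef planted coefficient of `log10(distance)`
#' @param seed optional RNG seed
#' @return data.frame with `y`, `total`, `beta`, `distance`;
#'   `attr(, "beta_star")` records the planted value
#' @export
simulate_flank_pairs <- function(n, beta_star = 0.33, phi = 2,
                                 intercept = log(0.05), distance_coef = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- rbeta(n, 2, 2)
  total <- round(rlnorm(n, log(2000), 0.8)) + 1
  distance <- pmax(1, round(rlnorm(n, log(1741), 1)))
  mu <- total * exp(intercept + beta_star * x + distance_coef * log10(distance))
  y <- if (phi <= 1) rpois(n, mu) else rnbinom(n, mu = mu, size = mu / (phi - 1))
  structure(data.frame(y = y, total = total, beta = x, distance = distance),
            beta_star = beta_star, phi = phi)
}

#' Generate a standard-size fixture dataset
#'
#' `tiny` (5 genes, 4+4 samples per cohort) for end-to-end unit tests,
#' `small` (500 genes at the default cohort sizes) for statistical power
#' and calibration tests, `paper_scale` (3,400 genes, about 40,000
#' analyzable intron-exon pairs) for the headline flank regression.
#'
#' @param size `"tiny"`, `"small"` or `"paper_scale"`
#' @param seed RNG seed
#' @param dir optional directory; when given the dataset is also written
#'   to disk via [write_dataset()]
#' @return a `methsplice_sim` object (invisibly when written to disk)
#' @export
make_fixture <- function(size = c("tiny", "small", "paper_scale"), seed = 1L,
                         dir = NULL) {
  size <- match.arg(size)
  cfg <- switch(size,
    tiny = sim_config(seed = seed, n_genes = 5L, bins_per_gene = c(4L, 8L),
                      n_dcm = c(screening = 4L, replication = 4L),
                      n_control = c(screening = 4L, replication = 4L),
                      n_reversed_loci = 1L, n_samesign_loci = 1L),
    small = sim_config(seed = seed),
    paper_scale = sim_config(seed = seed, n_genes = 3400L,
                             n_reversed_loci = 0L, n_samesign_loci = 0L)
  )
  sim <- simulate_dataset(cfg)
  if (!is.null(dir)) {
    write_dataset(sim, dir)
    return(invisible(sim))
  }
  sim
}

#' Write a simulated dataset to disk in standard formats
#'
#' GTF annotation, probe manifest TSV with one-probe-per-line blocklists,
#' per-cohort sample sheet CSV and beta / inclusion / exclusion TSV
#' matrices, truth tables, and a `manifest.json` recording the
#' configuration and an md5 hash per file (fixed seed implies identical
#' hashes).
#'
#' @param sim a `methsplice_sim` object
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest path
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gtf <- file.path(dir, "annotation.gtf")
  ex <- sim$annotation
  gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end),
                               strand = ex$strand)
  gr$type <- "exon"
  gr$gene_id <- ex$gene_id
  gr$transcript_id <- ex$transcript_id
  gr$source <- "methsplice"
  rtracklayer::export(gr, gtf, format = "gtf")

  write.table(sim$probes, file.path(dir, "probes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sim$probes$probe_id[sim$probes$flag_snp],
             file.path(dir, "blocklist_snp.txt"))
  writeLines(sim$probes$probe_id[sim$probes$flag_cross_reactive],
             file.path(dir, "blocklist_cross_reactive.txt"))

  write_mat <- function(m, path, id_col) {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- id_col
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (ch in names(sim$cohorts)) {
    co <- sim$cohorts[[ch]]
    cd <- file.path(dir, ch)
    dir.create(cd, showWarnings = FALSE)
    write.csv(co$sheet, file.path(cd, "samples.csv"), row.names = FALSE)
    write_mat(round(co$beta, 6), file.path(cd, "beta.tsv"), "probe_id")
    write_mat(co$inclusion, file.path(cd, "inclusion.tsv"), "feature_id")
    write_mat(co$exclusion, file.path(cd, "exclusion.tsv"), "feature_id")
  }
  for (nm in names(sim$truth)) {
    write.table(sim$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(dir, files)))
  names(hashes) <- files
  cfg <- sim$config
  class(cfg) <- NULL
  manifest <- list(config = cfg, files = hashes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}
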