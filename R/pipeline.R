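# Stage-wise pipeline orchestration over the on-disk dataset layout
# written by write_dataset(): each stage reads its upstream artifacts,
# writes TSV outputs under the output directory ({cohort}/{stage}.tsv for
# per-cohort results) plus a line-delimited log, and fails with an
# actionable message naming the missing upstream stage. The replication
# join is the only cross-cohort step; cohorts are otherwise processed
# fully independently (own QC, size factors, principal components).

PIPELINE_STAGES <- c("simulate", "pair", "qc", "dge", "deu", "dmr", "psi",
                     "flank", "ewas", "diffcor", "replicate", "intersect",
                     "report")

#' Build a pipeline configuration
#'
#' @param data_dir dataset directory (layout of [write_dataset()])
#' @param out_dir output directory for stage artifacts
#' @param min_assigned sample read-count threshold (default 1,000,000)
#' @param min_bin_total bin total-count threshold (default 6)
#' @param alpha raw p threshold for the DEU/DMR intersection
#' @param screening_fdr FDR threshold in the screening cohort
#' @param replication_p raw p threshold in the replication cohort
#' @param read_length read length for the PSI junction normalization
#' @param deu_covariates sheet columns entering the DEU design (default
#'   none: condition only)
#' @param dge_covariates sheet columns entering the DGE design
#' @param max_combinations optional cap on the number of (probe, bin)
#'   combinations entering the association scan (planted-locus studies
#'   subsample nulls; `NULL` = all)
#' @param sim_size fixture size for the `simulate` stage
#' @param seed seed controlling the `simulate` stage and combination
#'   subsampling
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(data_dir, out_dir,
                            min_assigned = 1e6, min_bin_total = 6,
                            alpha = 0.05, screening_fdr = 0.05,
                            replication_p = 0.05, read_length = 100,
                            deu_covariates = character(),
                            dge_covariates = character(),
                            max_combinations = NULL,
                            sim_size = "tiny", seed = 1L) {
  stopifnot(min_assigned > 0, min_bin_total > 0, alpha > 0,
            screening_fdr > 0, replication_p > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

pl_log <- function(config) file.path(config$out_dir, "pipeline.log")

req_artifact <- function(path, needed_stage) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s'; run stage '%s' first",
                 path, needed_stage), call. = FALSE)
  }
  path
}

read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run one pipeline stage (or the whole pipeline)
#'
#' Stages: `simulate`, `pair`, `qc`, `dge`, `deu`, `dmr`, `psi`, `flank`,
#' `ewas`, `diffcor`, `replicate`, `intersect`, `report`, or `all` to run
#' the full flow (per-cohort stages for both cohorts, then the replication
#' join). Re-running a stage with unchanged inputs and seed reproduces its
#' outputs.
#'
#' @param stage stage name
#' @param config a [pipeline_config()]
#' @return invisibly, the paths of the artifacts the stage wrote
#' @export
run_pipeline <- function(stage, config) {
  stage <- match.arg(stage, c(PIPELINE_STAGES, "all"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    out <- unlist(lapply(PIPELINE_STAGES, run_pipeline, config = config))
    return(invisible(out))
  }
  fun <- get(paste0("stage_", sub("-", "_", stage)), mode = "function")
  paths <- fun(config)
  log_line(pl_log(config), stage, artifacts = length(paths))
  invisible(paths)
}

stage_simulate <- function(config) {
  sim <- make_fixture(config$sim_size, seed = config$seed,
                      dir = config$data_dir)
  file.path(config$data_dir, "manifest.json")
}

stage_pair <- function(config) {
  gtf <- req_artifact(file.path(config$data_dir, "annotation.gtf"), "simulate")
  models <- read_gtf(gtf)
  bins <- flatten_gene_models(models)
  introns <- derive_introns(bins)
  probes <- read_probe_manifest(
    req_artifact(file.path(config$data_dir, "probes.tsv"), "simulate"),
    snp_blocklist = file.path(config$data_dir, "blocklist_snp.txt"),
    cross_reactive_blocklist = file.path(config$data_dir,
                                         "blocklist_cross_reactive.txt"))
  probes <- filter_probes(probes, log_path = pl_log(config))
  pairs <- build_flank_pairs(probes, introns, bins, log_path = pl_log(config))
  o <- config$out_dir
  write.table(bins, file.path(o, "bins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bins_bed(bins, file.path(o, "bins.bed"))
  write.table(introns, file.path(o, "introns.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(probes, file.path(o, "probes_qc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_pairs_tsv(pairs, file.path(o, "pairs.tsv"))
  file.path(o, c("bins.tsv", "bins.bed", "introns.tsv", "probes_qc.tsv",
                 "pairs.tsv"))
}

pl_cohorts <- function(config) {
  chs <- c("screening", "replication")
  found <- chs[file.exists(file.path(config$data_dir, chs, "samples.csv"))]
  if (!length(found)) {
    stop("no cohort sample sheets under '", config$data_dir,
         "'; run stage 'simulate' first (or point data_dir at a dataset)",
         call. = FALSE)
  }
  found
}

stage_qc <- function(config) {
  out <- character()
  for (ch in pl_cohorts(config)) {
    dd <- file.path(config$data_dir, ch)
    sheet <- read.csv(req_artifact(file.path(dd, "samples.csv"), "simulate"),
                      stringsAsFactors = FALSE)
    incl <- read_matrix(file.path(dd, "inclusion.tsv"))
    excl <- read_matrix(file.path(dd, "exclusion.tsv"))
    beta <- read_matrix(file.path(dd, "beta.tsv"))
    fs <- filter_samples(sheet, list(inclusion = incl, exclusion = excl,
                                     beta = beta),
                         min_assigned = config$min_assigned,
                         log_path = pl_log(config))
    cc <- filter_low_count_bins(fs$counts[c("inclusion", "exclusion")],
                                min_total = config$min_bin_total,
                                log_path = pl_log(config))
    beta <- fs$counts$beta
    m <- beta_to_m(beta)
    sf <- size_factors(rowsum(cc$inclusion,
                              sub(":[^:]+$", "", rownames(cc$inclusion))))
    pcs <- top_principal_components(m, k = 2)
    od <- file.path(config$out_dir, ch)
    dir.create(od, showWarnings = FALSE)
    write.csv(fs$sheet, file.path(od, "samples_qc.csv"), row.names = FALSE)
    wm <- function(x, f, id) {
      df <- data.frame(rownames(x), x, check.names = FALSE)
      colnames(df)[1] <- id
      write.table(df, file.path(od, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    wm(cc$inclusion, "inclusion_qc.tsv", "feature_id")
    wm(cc$exclusion, "exclusion_qc.tsv", "feature_id")
    wm(beta, "beta_qc.tsv", "probe_id")
    wm(m, "m_values.tsv", "probe_id")
    wm(pcs, "pcs.tsv", "sample_id")
    write.table(data.frame(sample_id = names(sf), size_factor = sf),
                file.path(od, "size_factors.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out <- c(out, file.path(od, c("samples_qc.csv", "inclusion_qc.tsv",
                                  "exclusion_qc.tsv", "beta_qc.tsv",
                                  "m_values.tsv", "pcs.tsv",
                                  "size_factors.tsv")))
  }
  out
}

pl_read_qc <- function(config, ch) {
  od <- file.path(config$out_dir, ch)
  req_artifact(file.path(od, "inclusion_qc.tsv"), "qc")
  list(sheet = read.csv(file.path(od, "samples_qc.csv"),
                        stringsAsFactors = FALSE),
       inclusion = read_matrix(file.path(od, "inclusion_qc.tsv")),
       exclusion = read_matrix(file.path(od, "exclusion_qc.tsv")),
       beta = read_matrix(file.path(od, "beta_qc.tsv")),
       m = read_matrix(file.path(od, "m_values.tsv")),
       pcs = read_matrix(file.path(od, "pcs.tsv")))
}

write_results <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage_dge <- function(config) {
  vapply(pl_cohorts(config), function(ch) {
    q <- pl_read_qc(config, ch)
    genes <- rowsum(q$inclusion, sub(":[^:]+$", "", rownames(q$inclusion)))
    res <- test_dge(genes, q$sheet, covariates = config$dge_covariates)
    write_results(res, file.path(config$out_dir, ch, "dge.tsv"))
  }, character(1))
}

stage_deu <- function(config) {
  vapply(pl_cohorts(config), function(ch) {
    q <- pl_read_qc(config, ch)
    res <- test_deu(q$inclusion, q$sheet,
                    covariates = config$deu_covariates,
                    log_path = pl_log(config))
    write_results(res, file.path(config$out_dir, ch, "deu.tsv"))
  }, character(1))
}

stage_dmr <- function(config) {
  vapply(pl_cohorts(config), function(ch) {
    q <- pl_read_qc(config, ch)
    res <- test_dmr(q$m, q$sheet, pcs = q$pcs)
    write_results(res, file.path(config$out_dir, ch, "dmr.tsv"))
  }, character(1))
}

stage_psi <- function(config) {
  bins <- read.delim(req_artifact(file.path(config$out_dir, "bins.tsv"),
                                  "pair"), stringsAsFactors = FALSE)
  widths <- setNames(bins$width, paste(bins$gene_id, bins$bin_id, sep = ":"))
  vapply(pl_cohorts(config), function(ch) {
    q <- pl_read_qc(config, ch)
    psi <- compute_psi(q$inclusion, q$exclusion,
                       widths[rownames(q$inclusion)],
                       read_length = config$read_length)
    df <- data.frame(feature_id = rownames(psi), psi, check.names = FALSE)
    write_results(df, file.path(config$out_dir, ch, "psi.tsv"))
  }, character(1))
}

stage_flank <- function(config) {
  pairs <- read.delim(req_artifact(file.path(config$out_dir, "pairs.tsv"),
                                   "pair"), stringsAsFactors = FALSE)
  vapply(pl_cohorts(config), function(ch) {
    q <- pl_read_qc(config, ch)
    tab <- flank_regression_table(pairs, q$inclusion, q$beta, q$sheet,
                                  log_path = pl_log(config))
    write_results(tab, file.path(config$out_dir, ch, "flank.tsv"))
  }, character(1))
}

pl_combinations <- function(config, probes, introns, bins) {
  gi <- gene_combinations(probes, introns, bins)
  if (!is.null(config$max_combinations) &&
      nrow(gi) > config$max_combinations) {
    set.seed(substream_seed(config$seed, "combinations"))
    gi <- gi[sort(sample(nrow(gi), config$max_combinations)), , drop = FALSE]
  }
  gi
}

stage_ewas <- function(config) {
  o <- config$out_dir
  probes <- read.delim(req_artifact(file.path(o, "probes_qc.tsv"), "pair"),
                       stringsAsFactors = FALSE)
  introns <- read.delim(file.path(o, "introns.tsv"), stringsAsFactors = FALSE)
  bins <- read.delim(file.path(o, "bins.tsv"), stringsAsFactors = FALSE)
  gi <- pl_combinations(config, probes, introns, bins)
  out <- character()
  for (ch in pl_cohorts(config)) {
    req_artifact(file.path(o, ch, "psi.tsv"), "psi")
    q <- pl_read_qc(config, ch)
    psi_df <- read.delim(file.path(o, ch, "psi.tsv"), check.names = FALSE,
                         stringsAsFactors = FALSE)
    psi <- as.matrix(psi_df[, -1, drop = FALSE])
    rownames(psi) <- psi_df$feature_id
    for (g in c("DCM", "control")) {
      res <- ewas_scan(q$beta, psi, gi, pcs = q$pcs, sheet = q$sheet,
                       group = g, log_path = pl_log(config))
      p <- write_results(res, file.path(o, ch, paste0("ewas_", g, ".tsv")))
      out <- c(out, p)
    }
    ve <- variance_explained(q$beta, psi, gi)
    write_results(data.frame(mean_r2 = ve$mean_r2, ci_lo = ve$ci[1],
                             ci_hi = ve$ci[2], n_tests = ve$n_tests),
                  file.path(o, ch, "variance_explained.tsv"))
    out <- c(out, file.path(o, ch, "variance_explained.tsv"))
  }
  out
}

stage_diffcor <- function(config) {
  vapply(pl_cohorts(config), function(ch) {
    od <- file.path(config$out_dir, ch)
    a <- read.delim(req_artifact(file.path(od, "ewas_DCM.tsv"), "ewas"),
                    stringsAsFactors = FALSE)
    b <- read.delim(file.path(od, "ewas_control.tsv"),
                    stringsAsFactors = FALSE)
    res <- diffcor_scan(a, b, fdr_threshold = config$screening_fdr,
                        log_path = pl_log(config))
    write_results(res, file.path(od, "diffcor.tsv"))
  }, character(1))
}

stage_replicate <- function(config) {
  o <- config$out_dir
  scr <- read.delim(req_artifact(file.path(o, "screening", "diffcor.tsv"),
                                 "diffcor"), stringsAsFactors = FALSE)
  rep_path <- file.path(o, "replication", "diffcor.tsv")
  if (!file.exists(rep_path)) {
    stop("missing artifact '", rep_path, "'; run stage 'diffcor' first",
         call. = FALSE)
  }
  rp <- read.delim(rep_path, stringsAsFactors = FALSE)
  res <- directional_replication(scr, rp, p_threshold = config$replication_p,
                                 log_path = pl_log(config))
  write_results(res, file.path(o, "replication.tsv"))
}

stage_intersect <- function(config) {
  o <- config$out_dir
  deu <- read.delim(req_artifact(file.path(o, "screening", "deu.tsv"), "deu"),
                    stringsAsFactors = FALSE)
  dmr <- read.delim(req_artifact(file.path(o, "screening", "dmr.tsv"), "dmr"),
                    stringsAsFactors = FALSE)
  pairs <- read.delim(req_artifact(file.path(o, "pairs.tsv"), "pair"),
                      stringsAsFactors = FALSE)
  bins <- read.delim(file.path(o, "bins.tsv"), stringsAsFactors = FALSE)
  ix <- intersect_deu_dmr(deu, dmr, pairs, alpha = config$alpha, bins = bins)
  write_results(ix$summary, file.path(o, "intersect_summary.tsv"))
  write_results(ix$hits, file.path(o, "intersect_hits.tsv"))
  if (!is.null(ix$bed)) {
    write.table(ix$bed, file.path(o, "intersect_hits.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  file.path(o, c("intersect_summary.tsv", "intersect_hits.tsv"))
}

stage_report <- function(config) {
  o <- config$out_dir
  lines <- c("methsplice pipeline report", "")
  flank_p <- file.path(o, "screening", "flank.tsv")
  if (file.exists(flank_p)) {
    tab <- read.delim(flank_p, stringsAsFactors = FALSE)
    lines <- c(lines, "Flank regression (screening cohort):",
               utils::capture.output(print(tab)), "")
  }
  for (ch in pl_cohorts(config)) {
    for (what in c("dge", "deu", "dmr")) {
      f <- file.path(o, ch, paste0(what, ".tsv"))
      if (!file.exists(f)) next
      res <- read.delim(f, stringsAsFactors = FALSE)
      lines <- c(lines, sprintf("%s %s: %d features, %d with raw p < %.2f, %d with FDR < %.2f",
                                ch, toupper(what), nrow(res),
                                sum(res$p < config$alpha, na.rm = TRUE),
                                config$alpha,
                                sum(res$fdr < config$screening_fdr, na.rm = TRUE),
                                config$screening_fdr))
    }
  }
  ix <- file.path(o, "intersect_summary.tsv")
  if (file.exists(ix)) {
    lines <- c(lines, "", "DEU/DMR co-occurrence:",
               utils::capture.output(print(read.delim(ix))))
  }
  rp <- file.path(o, "replication.tsv")
  if (file.exists(rp)) {
    r <- read.delim(rp, stringsAsFactors = FALSE)
    lines <- c(lines, "",
               sprintf("Differential correlation: %d screened, %d replicated, %d directionally replicated",
                       sum(r$screened), sum(r$replicated),
                       sum(r$directionally_replicated)))
    cand <- r[r$replicated, c("probe_id", "gene_id", "bin_id", "r_dcm",
                              "r_control", "p", "fdr", "p_replication",
                              "directionally_replicated")]
    if (nrow(cand)) {
      lines <- c(lines, "", "Replicated candidates:",
                 utils::capture.output(print(cand, row.names = FALSE)))
    }
  }
  writeLines(lines, file.path(o, "report.txt"))
  file.path(o, "report.txt")
}
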