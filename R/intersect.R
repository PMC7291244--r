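# Overlay of differential exon usage and differential methylation hits on
# the flank-pair table.

#' Intersect DEU and DMR hits over flank pairs
#'
#' A flank pair is a co-occurrence hit iff its exon bin has a raw DEU
#' p-value below `alpha` and its intronic probe a raw DMR p-value below
#' `alpha`. Reports hit pairs and distinct gene counts per pair kind.
#'
#' @param deu differential-exon-usage results ([test_deu()] output; rows
#'   identified by `feature_id = gene:bin`)
#' @param dmr differential-methylation results ([test_dmr()] output; rows
#'   identified by probe id)
#' @param pairs flank-pair table
#' @param alpha raw p-value threshold applied to both tests (default 0.05)
#' @param bins optional bin table; when given, hit regions are also
#'   returned as a BED data.frame (0-based half-open)
#' @return list with `hits` (the hit pairs), `summary` (per-kind pair and
#'   gene counts), and optionally `bed`
#' @export
intersect_deu_dmr <- function(deu, dmr, pairs, alpha = 0.05, bins = NULL) {
  deu_p <- setNames(deu$p, deu$feature_id)
  dmr_p <- setNames(dmr$p, dmr$feature_id)
  bin_key <- paste(pairs$gene_id, pairs$bin_id, sep = ":")
  pb <- deu_p[bin_key]
  pp <- dmr_p[pairs$probe_id]
  hit <- !is.na(pb) & !is.na(pp) & pb < alpha & pp < alpha
  hits <- pairs[hit, , drop = FALSE]
  hits$deu_p <- pb[hit]
  hits$dmr_p <- pp[hit]
  rownames(hits) <- NULL
  summary <- do.call(rbind, lapply(c("intron-exon", "exon-intron"), function(k) {
    h <- hits[hits$kind == k, , drop = FALSE]
    data.frame(kind = k, n_pairs = nrow(h),
               n_genes = length(unique(h$gene_id)),
               stringsAsFactors = FALSE)
  }))
  out <- list(hits = hits, summary = summary)
  if (!is.null(bins) && nrow(hits)) {
    key <- paste(bins$gene_id, bins$bin_id, sep = ":")
    idx <- match(paste(hits$gene_id, hits$bin_id, sep = ":"), key)
    out$bed <- data.frame(chrom = bins$chrom[idx],
                          start = bins$start[idx] - 1L,
                          end = bins$end[idx],
                          name = paste(hits$gene_id, hits$bin_id, sep = ":"),
                          stringsAsFactors = FALSE)
  }
  out
}
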