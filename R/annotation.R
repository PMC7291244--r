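# Genomic scaffold: exon-bin flattening, intron derivation, flank pairing.
#
# Coordinates are 1-based inclusive throughout (GTF convention); the only
# 0-based half-open conversion happens in the BED writers. Strand is recorded
# but deliberately ignored for pairing and distances: the probe manifest is
# strandless, so "upstream"/"downstream" are genomic orientation. Overlapping
# genes (e.g. a sense/antisense pair such as TTN / TTN-AS1) are flattened
# independently per gene_id, and a probe pairs only within the gene whose
# intron contains it.

#' Read exon records from a GTF file into a gene-model table
#'
#' Keeps `feature == "exon"` rows and extracts `gene_id` / `transcript_id`
#' from the attribute column. Parsing is delegated to
#' [rtracklayer::import()].
#'
#' @param path path to a GTF file
#' @return a data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive), one row per exon
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon records found in GTF: ", path)
  data.frame(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read a methylation probe manifest
#'
#' @param path TSV with columns `probe_id`, `chrom`, `pos` and the flag
#'   columns `flag_snp`, `flag_cross_reactive`, `flag_sex_chrom` (0/1 or
#'   logical). Missing flag columns are filled from blocklist files if given.
#' @param snp_blocklist,cross_reactive_blocklist optional paths to
#'   one-probe-id-per-line text files; probes listed there get the
#'   corresponding flag set.
#' @return data.frame of probe records
#' @export
read_probe_manifest <- function(path, snp_blocklist = NULL,
                                cross_reactive_blocklist = NULL) {
  pr <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(pr, c("probe_id", "chrom", "pos"), "probe manifest")
  for (fl in c("flag_snp", "flag_cross_reactive", "flag_sex_chrom")) {
    if (!fl %in% colnames(pr)) pr[[fl]] <- FALSE
    pr[[fl]] <- as.logical(pr[[fl]])
  }
  if (!is.null(snp_blocklist)) {
    ids <- readLines(snp_blocklist)
    pr$flag_snp <- pr$flag_snp | pr$probe_id %in% ids
  }
  if (!is.null(cross_reactive_blocklist)) {
    ids <- readLines(cross_reactive_blocklist)
    pr$flag_cross_reactive <- pr$flag_cross_reactive | pr$probe_id %in% ids
  }
  pr$flag_sex_chrom <- pr$flag_sex_chrom | pr$chrom %in% c("chrX", "chrY", "X", "Y")
  if (any(pr$pos < 1)) stop("probe manifest contains pos < 1")
  pr
}

validate_gene_models <- function(models) {
  stop_if_missing_cols(models, c("gene_id", "transcript_id", "chrom",
                                 "strand", "start", "end"), "gene models")
  bad <- which(models$start > models$end)
  if (length(bad)) {
    stop(sprintf("malformed exon interval (start > end) in gene %s transcript %s [%d, %d]",
                 models$gene_id[bad[1]], models$transcript_id[bad[1]],
                 models$start[bad[1]], models$end[bad[1]]), call. = FALSE)
  }
  chrom_per_gene <- tapply(models$chrom, models$gene_id,
                           function(x) length(unique(x)))
  if (any(chrom_per_gene > 1)) {
    stop("all exons of a gene must share one chromosome: ",
         names(chrom_per_gene)[chrom_per_gene > 1][1], call. = FALSE)
  }
  invisible(models)
}

#' Flatten transcript exons into disjoint exonic counting bins
#'
#' Per gene, the union of all transcript exons is partitioned into maximal
#' disjoint bins split at every distinct exon boundary observed across the
#' gene's transcripts (the counting-bin construction used for differential
#' exon usage). Bins are labelled `E001`, `E002`, ... in genomic order.
#' Overlapping genes are flattened independently; no cross-gene merging.
#'
#' @param models gene-model data.frame as from [read_gtf()]
#' @return data.frame with columns `gene_id`, `bin_id`, `chrom`, `strand`,
#'   `start`, `end`, `width`, ordered by gene then genomic start
#' @export
flatten_gene_models <- function(models) {
  validate_gene_models(models)
  out <- lapply(split(models, models$gene_id), function(gm) {
    ir <- IRanges::IRanges(start = gm$start, end = gm$end)
    bins <- IRanges::disjoin(ir)          # split at every observed boundary
    bins <- bins[order(IRanges::start(bins))]
    n <- length(bins)
    data.frame(
      gene_id = gm$gene_id[1],
      bin_id = sprintf("E%03d", seq_len(n)),
      chrom = gm$chrom[1],
      strand = gm$strand[1],
      start = IRanges::start(bins),
      end = IRanges::end(bins),
      width = IRanges::width(bins),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Derive intron intervals between consecutive exon bins
#'
#' One interval per gap between consecutive bins of a gene:
#' `[prev.end + 1, next.start - 1]`. Abutting bins (zero-width gap) produce
#' no interval.
#'
#' @param bins exon bins as returned by [flatten_gene_models()]
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`, plus
#'   `upstream_bin` / `downstream_bin` giving the ids of the bordering bins
#'   in genomic coordinates
#' @export
derive_introns <- function(bins) {
  stop_if_missing_cols(bins, c("gene_id", "bin_id", "chrom", "start", "end"),
                       "exon bins")
  out <- lapply(split(bins, bins$gene_id), function(b) {
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) < 2) return(NULL)
    gap_start <- b$end[-nrow(b)] + 1
    gap_end <- b$start[-1] - 1
    keep <- gap_end >= gap_start
    if (!any(keep)) return(NULL)
    data.frame(
      gene_id = b$gene_id[1],
      chrom = b$chrom[1],
      start = gap_start[keep],
      end = gap_end[keep],
      upstream_bin = b$bin_id[-nrow(b)][keep],
      downstream_bin = b$bin_id[-1][keep],
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      upstream_bin = character(), downstream_bin = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Pair intronic probes with their bordering exon bins
#'
#' Every probe falling strictly inside an intron of a gene yields up to two
#' flank pairs within that gene: an `intron-exon` pair with the bin
#' immediately downstream in genomic coordinates (distance
#' `bin.start - pos`) and an `exon-intron` pair with the bin immediately
#' upstream (distance `pos - bin.end`). A probe sitting exactly on a bin
#' boundary is exonic (bins are closed intervals) and yields no pair.
#' Probes on chromosomes absent from the annotation are skipped and counted
#' in the log.
#'
#' @param probes probe records (already blocklist-filtered; see
#'   [filter_probes()])
#' @param introns intron table from [derive_introns()]
#' @param bins exon bins from [flatten_gene_models()]
#' @param log_path optional log file for skipped-probe accounting
#' @return data.frame with columns `kind` (`intron-exon` / `exon-intron`),
#'   `probe_id`, `gene_id`, `bin_id`, `distance`
#' @export
build_flank_pairs <- function(probes, introns, bins, log_path = NULL) {
  stop_if_missing_cols(probes, c("probe_id", "chrom", "pos"), "probes")
  empty <- data.frame(kind = character(), probe_id = character(),
                      gene_id = character(), bin_id = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (!nrow(introns) || !nrow(probes)) return(empty)

  known_chrom <- unique(bins$chrom)
  off <- !(probes$chrom %in% known_chrom)
  log_line(log_path, "build_flank_pairs",
           probes_in = nrow(probes), probes_off_annotation = sum(off))
  probes <- probes[!off, , drop = FALSE]
  if (!nrow(probes)) return(empty)

  pr_gr <- GenomicRanges::GRanges(probes$chrom,
                                  IRanges::IRanges(probes$pos, probes$pos))
  in_gr <- GenomicRanges::GRanges(introns$chrom,
                                  IRanges::IRanges(introns$start, introns$end))
  hits <- GenomicRanges::findOverlaps(pr_gr, in_gr, type = "within")
  if (!length(hits)) return(empty)

  pi <- S4Vectors::queryHits(hits)
  ii <- S4Vectors::subjectHits(hits)
  bin_key <- paste(bins$gene_id, bins$bin_id)
  bin_start <- setNames(bins$start, bin_key)
  bin_end <- setNames(bins$end, bin_key)

  up_key <- paste(introns$gene_id[ii], introns$upstream_bin[ii])
  dn_key <- paste(introns$gene_id[ii], introns$downstream_bin[ii])

  ie <- data.frame(  # probe's intron precedes the downstream bin
    kind = "intron-exon",
    probe_id = probes$probe_id[pi],
    gene_id = introns$gene_id[ii],
    bin_id = introns$downstream_bin[ii],
    distance = as.integer(bin_start[dn_key] - probes$pos[pi]),
    stringsAsFactors = FALSE
  )
  ei <- data.frame(  # probe's intron follows the upstream bin
    kind = "exon-intron",
    probe_id = probes$probe_id[pi],
    gene_id = introns$gene_id[ii],
    bin_id = introns$upstream_bin[ii],
    distance = as.integer(probes$pos[pi] - bin_end[up_key]),
    stringsAsFactors = FALSE
  )
  res <- rbind(ie, ei)
  res <- res[!is.na(res$bin_id) & !is.na(res$distance), , drop = FALSE]
  stopifnot(all(res$distance >= 1))
  res <- res[order(res$kind, res$gene_id, res$bin_id, res$probe_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  log_line(log_path, "build_flank_pairs",
           intron_exon_pairs = sum(res$kind == "intron-exon"),
           exon_intron_pairs = sum(res$kind == "exon-intron"))
  res
}

#' Median flank-pair distance
#'
#' Reporting helper for the pair table (the regression's distance covariate
#' summary).
#'
#' @param pairs pair table from [build_flank_pairs()]
#' @return median of `distance`
#' @export
median_pair_distance <- function(pairs) {
  median(pairs$distance)
}

#' Write exon bins as BED (0-based half-open)
#'
#' @param bins bin table
#' @param path output path
#' @export
write_bins_bed <- function(bins, path) {
  bed <- data.frame(bins$chrom, bins$start - 1L, bins$end,
                    paste(bins$gene_id, bins$bin_id, sep = ":"),
                    0L, bins$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the flank-pair table as TSV
#'
#' @param pairs pair table
#' @param path output path
#' @export
write_pairs_tsv <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
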