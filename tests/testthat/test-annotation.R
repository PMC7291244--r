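# Exon-bin flattening, intron derivation, flank pairing.

test_that("flattening splits at observed transcript boundaries", {
  m1 <- data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
                   strand = "+", start = c(100L, 300L), end = c(200L, 400L))
  b1 <- flatten_gene_models(m1)
  expect_equal(b1$bin_id, c("E001", "E002"))
  expect_equal(b1$start, c(100L, 300L))
  expect_equal(b1$end, c(200L, 400L))
  expect_equal(b1$width, c(101L, 101L))

  m2 <- data.frame(gene_id = "g1", transcript_id = c("t1", "t2"),
                   chrom = "chr1", strand = "+",
                   start = c(100L, 150L), end = c(200L, 200L))
  b2 <- flatten_gene_models(m2)
  expect_equal(b2$start, c(100L, 150L))
  expect_equal(b2$end, c(149L, 200L))

  m3 <- data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
                   strand = "+", start = 10L, end = 10L)
  b3 <- flatten_gene_models(m3)
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$width, 1L)
})

test_that("malformed intervals are rejected with the offending record named", {
  m <- data.frame(gene_id = "gX", transcript_id = "tY", chrom = "chr1",
                  strand = "+", start = 50L, end = 40L)
  expect_error(flatten_gene_models(m), "gX.*tY")
})

test_that("overlapping genes are flattened independently", {
  m <- data.frame(gene_id = c("gA", "gB"), transcript_id = c("tA", "tB"),
                  chrom = "chr1", strand = c("+", "-"),
                  start = c(100L, 150L), end = c(300L, 250L))
  b <- flatten_gene_models(m)
  expect_equal(b$start[b$gene_id == "gA"], 100L)
  expect_equal(b$end[b$gene_id == "gA"], 300L)
  expect_equal(b$start[b$gene_id == "gB"], 150L)
})

test_that("intron derivation enumerates gaps and skips abutting bins", {
  sc <- two_bin_scaffold()
  expect_equal(sc$introns$start, 201L)
  expect_equal(sc$introns$end, 299L)

  abut <- data.frame(gene_id = "g1", bin_id = c("E001", "E002"),
                     chrom = "chr1", start = c(100L, 201L),
                     end = c(200L, 300L))
  expect_equal(nrow(derive_introns(abut)), 0L)

  three <- data.frame(gene_id = "g1", bin_id = c("E001", "E002", "E003"),
                      chrom = "chr1", start = c(1L, 20L, 40L),
                      end = c(10L, 30L, 50L))
  intr <- derive_introns(three)
  expect_equal(intr$start, c(11L, 31L))
  expect_equal(intr$end, c(19L, 39L))
})

test_that("an intronic probe pairs with both bordering bins at base-exact distances", {
  sc <- two_bin_scaffold()
  pairs <- build_flank_pairs(make_probe("cg1", "chr1", 250L),
                             sc$introns, sc$bins)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(pairs$kind, c("intron-exon", "exon-intron"))
  expect_equal(pairs$distance[pairs$kind == "intron-exon"], 50L)  # 300 - 250
  expect_equal(pairs$distance[pairs$kind == "exon-intron"], 50L)  # 250 - 200
  expect_equal(unique(pairs$bin_id[pairs$kind == "intron-exon"]), "E002")
  expect_equal(unique(pairs$bin_id[pairs$kind == "exon-intron"]), "E001")
})

test_that("exonic, boundary, intergenic and off-chromosome probes yield no pairs", {
  sc <- two_bin_scaffold()
  probes <- rbind(make_probe("cg_exonic", "chr1", 150L),
                  make_probe("cg_boundary", "chr1", 300L),  # on bin start: exonic
                  make_probe("cg_outside", "chr1", 5000L),
                  make_probe("cg_offchrom", "chr9", 250L))
  pairs <- build_flank_pairs(probes, sc$introns, sc$bins)
  expect_equal(nrow(pairs), 0L)
})

test_that("pairing is stable under reordering of input records", {
  set.seed(41)
  models <- random_gene_models(n_genes = 4)
  bins <- flatten_gene_models(models)
  introns <- derive_introns(bins)
  probes <- make_probe(sprintf("cg%03d", 1:60), "chr1",
                       sample(1500L, 60))
  p1 <- build_flank_pairs(probes, introns, bins)
  shuffle <- function(df) df[sample(nrow(df)), , drop = FALSE]
  p2 <- build_flank_pairs(shuffle(probes), shuffle(introns), shuffle(bins))
  expect_equal(p1, p2)
  b2 <- flatten_gene_models(shuffle(models))
  expect_equal(bins[order(bins$gene_id), ], b2[order(b2$gene_id), ],
               ignore_attr = TRUE)
})

test_that("median pair distance equals a sort-based oracle", {
  set.seed(42)
  models <- random_gene_models(n_genes = 5)
  bins <- flatten_gene_models(models)
  introns <- derive_introns(bins)
  probes <- make_probe(sprintf("cg%03d", 1:80), "chr1", sample(1800L, 80))
  pairs <- build_flank_pairs(probes, introns, bins)
  d <- sort(pairs$distance)
  n <- length(d)
  med_oracle <- if (n %% 2 == 1) d[(n + 1) / 2] else (d[n / 2] + d[n / 2 + 1]) / 2
  expect_equal(median_pair_distance(pairs), med_oracle)
})

test_that("flattened bins partition the exon union on random gene models", {
  set.seed(43)
  for (rep in 1:40) {
    models <- random_gene_models(n_genes = 2)
    bins <- flatten_gene_models(models)
    for (g in unique(models$gene_id)) {
      gm <- models[models$gene_id == g, ]
      bg <- bins[bins$gene_id == g, ]
      want <- oracle_flatten_gene(gm$start, gm$end)
      expect_equal(bg$start, want$start)
      expect_equal(bg$end, want$end)
      # pairwise disjoint, ordered, consecutively labelled
      expect_true(all(diff(bg$start) > 0))
      expect_true(all(bg$start[-1] > bg$end[-nrow(bg)]))
      expect_equal(bg$bin_id, sprintf("E%03d", seq_len(nrow(bg))))
      # base-wise union equality
      cov_bins <- unlist(Map(seq, bg$start, bg$end))
      cov_exons <- sort(unique(unlist(Map(seq, gm$start, gm$end))))
      expect_equal(sort(cov_bins), cov_exons)
    }
  }
})
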