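# Synthetic-data generator: determinism, validation, truth consistency.

test_that("identical config yields byte-identical datasets", {
  s1 <- make_fixture("tiny", seed = 61)
  s2 <- make_fixture("tiny", seed = 61)
  expect_identical(s1$cohorts$screening$inclusion,
                   s2$cohorts$screening$inclusion)
  expect_identical(s1$cohorts$replication$beta, s2$cohorts$replication$beta)
  expect_identical(s1$truth, s2$truth)

  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_dataset(s1, d1)
  write_dataset(s2, d2)
  files <- list.files(d1, recursive = TRUE)
  h1 <- tools::md5sum(file.path(d1, files))
  h2 <- tools::md5sum(file.path(d2, files))
  expect_equal(unname(h1), unname(h2))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("inconsistent configs are rejected before generation", {
  expect_error(sim_config(deu_fraction = 1.5), "fractions")
  expect_error(sim_config(n_control = c(screening = 3L, replication = 5L)),
               "at least 4")
  expect_error(sim_config(reversed_r = c(dcm = -1, control = 1)),
               "strictly inside")
  cfg <- sim_config(n_genes = 3L, bins_per_gene = c(3L, 4L),
                    probes_per_intron = 0.2, n_reversed_loci = 50L)
  expect_error(simulate_dataset(cfg), "eligible")
})

test_that("emitted matrices are clean and PSI truth is recovered from counts", {
  sim <- make_fixture("tiny", seed = 62)
  for (ch in names(sim$cohorts)) {
    co <- sim$cohorts[[ch]]
    expect_false(anyNA(co$inclusion) || anyNA(co$exclusion) || anyNA(co$beta))
    expect_true(all(co$inclusion >= 0) && all(co$exclusion >= 0))
    expect_true(all(co$beta > 0 & co$beta < 1))
    expect_true(all(co$psi_true > 0 & co$psi_true < 1))
  }
  co <- sim$cohorts$screening
  w <- setNames(sim$bins$width, paste(sim$bins$gene_id, sim$bins$bin_id,
                                      sep = ":"))
  psi <- compute_psi(co$inclusion, co$exclusion, w)
  expect_gt(cor(as.vector(psi), as.vector(co$psi_true),
                use = "complete.obs"), 0.8)
})

test_that("sample sheets carry the designed confounding structure", {
  sim <- make_fixture("small", seed = 63)
  for (ch in names(sim$cohorts)) {
    sh <- sim$cohorts[[ch]]$sheet
    drugs <- c("tacrolimus", "mycophenolate", "steroid", "everolimus",
               "ciclosporin")
    # immunosuppressants only in controls
    expect_true(all(!sh[sh$condition == "DCM", drugs]))
    expect_true(any(unlist(sh[sh$condition == "control", drugs])))
  }
  sh <- sim$cohorts$screening$sheet
  expect_equal(sum(sh$condition == "DCM"), 34L)
  expect_equal(sum(sh$condition == "control"), 21L)
  rp <- sim$cohorts$replication$sheet
  expect_equal(sum(rp$condition == "DCM"), 11L)
  expect_equal(sum(rp$condition == "control"), 5L)

  low <- simulate_dataset(sim_config(seed = 64, n_genes = 10L,
                                     n_reversed_loci = 2L,
                                     n_samesign_loci = 1L,
                                     n_low_read_samples = 2L))
  expect_equal(sum(low$cohorts$screening$sheet$assigned_reads < 1e6), 2L)
})

test_that("planted reversed loci show the group-reversed correlation in truth", {
  sim <- make_fixture("small", seed = 65)
  co <- sim$cohorts$screening
  dcm <- co$sheet$sample_id[co$sheet$condition == "DCM"]
  ctl <- co$sheet$sample_id[co$sheet$condition == "control"]
  rv <- sim$truth$reversed
  r_dcm <- r_ctl <- numeric(nrow(rv))
  for (i in seq_len(nrow(rv))) {
    bkey <- paste(rv$gene_id[i], rv$bin_id[i], sep = ":")
    r_dcm[i] <- cor(co$beta[rv$probe_id[i], dcm], co$psi_true[bkey, dcm])
    r_ctl[i] <- cor(co$beta[rv$probe_id[i], ctl], co$psi_true[bkey, ctl])
  }
  expect_gt(mean(r_dcm < 0), 0.9)
  expect_gt(mean(r_ctl > 0), 0.9)
  expect_lt(abs(mean(r_dcm) - (-0.75)), 0.15)
  expect_lt(abs(mean(r_ctl) - 0.75), 0.15)
})

test_that("variance explained rises monotonically with coupling strength", {
  grid <- c(0, 0.6, 1.2, 1.8, 2.4)
  mean_r2 <- vapply(seq_along(grid), function(i) {
    cfg <- sim_config(seed = 66, n_genes = 60L, coupling = grid[i],
                      n_reversed_loci = 0L, n_samesign_loci = 0L,
                      deu_fraction = 0, dmr_fraction = 0)
    sim <- simulate_dataset(cfg)
    co <- sim$cohorts$screening
    w <- setNames(sim$bins$width, paste(sim$bins$gene_id, sim$bins$bin_id,
                                        sep = ":"))
    psi <- compute_psi(co$inclusion, co$exclusion, w)
    pr <- filter_probes(sim$probes)
    gi <- gene_combinations(pr, sim$introns, sim$bins)
    variance_explained(co$beta, psi, gi)$mean_r2
  }, numeric(1))
  expect_gt(cor(grid, mean_r2, method = "spearman"), 0.9)
})
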