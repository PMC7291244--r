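# Association scan, odds-ratio convention, Fisher's z differential
# correlation, directional replication, DEU/DMR intersection.

make_assoc <- function(keys, r, n, p = NULL) {
  data.frame(probe_id = keys, gene_id = "g", bin_id = "E001",
             r = r, n = n, p = p %||% rep(NA_real_, length(keys)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("association scan records the OR-per-0.01-beta convention exactly", {
  set.seed(51)
  n <- 30
  beta <- matrix(runif(n, 0.2, 0.8), 1, n,
                 dimnames = list("cg1", sprintf("s%02d", 1:n)))
  eta <- qlogis(0.3) + 16 * (beta[1, ] - 0.5)
  psi <- matrix(plogis(eta + rnorm(n, 0, 0.2)), 1, n,
                dimnames = list("g:E001", colnames(beta)))
  gi <- data.frame(probe_id = "cg1", gene_id = "g", bin_id = "E001")
  sheet <- data.frame(sample_id = colnames(beta), condition = "DCM")
  res <- ewas_scan(beta, psi, gi, sheet = sheet, group = "DCM")
  expect_equal(res$or_per_0.01, exp(0.01 * res$coefficient))
  expect_true(res$or_lo < res$or_per_0.01 & res$or_per_0.01 < res$or_hi)
  expect_gt(res$coefficient, 0)
  expect_gt(res$r, 0.5)
  expect_equal(res$n, n)
  # OR antisymmetry: flipped coupling gives the reciprocal odds ratio scale
  expect_equal(exp(0.01 * -res$coefficient), 1 / res$or_per_0.01)
  # closed form: a logit coefficient of ln(1.18)/0.01 is OR 1.18
  expect_equal(exp(0.01 * (log(1.18) / 0.01)), 1.18)
})

test_that("degenerate and under-sampled combinations are skipped", {
  beta <- matrix(runif(8), 2, 4, dimnames = list(c("cg1", "cg2"),
                                                 paste0("s", 1:4)))
  psi <- matrix(c(rep(0.5, 4), NA, 0.2, 0.3, 0.4), 2, 4, byrow = TRUE,
                dimnames = list(c("g:E001", "g:E002"), paste0("s", 1:4)))
  gi <- data.frame(probe_id = c("cg1", "cg2"), gene_id = "g",
                   bin_id = c("E001", "E002"))
  res <- ewas_scan(beta, psi, gi, min_n = 4)
  expect_equal(nrow(res), 0L)  # constant PSI and too few complete samples
})

test_that("variance explained matches simple-regression R-squared", {
  set.seed(52)
  n <- 20
  b <- matrix(runif(3 * n), 3, n,
              dimnames = list(c("cg1", "cg2", "cg3"), paste0("s", 1:n)))
  psi <- rbind(2 * b[1, ] - 0.3,                  # perfectly linear
               plogis(b[2, ] + rnorm(n)),
               runif(n))
  rownames(psi) <- c("g:E001", "g:E002", "g:E003")
  colnames(psi) <- colnames(b)
  psi[1, ] <- pmin(pmax(psi[1, ], 0), 1)
  gi <- data.frame(probe_id = c("cg1", "cg2", "cg3"), gene_id = "g",
                   bin_id = c("E001", "E002", "E003"))
  ve <- variance_explained(b, psi, gi)
  expect_equal(ve$n_tests, 3L)
  r2_manual <- vapply(1:3, function(i)
    summary(lm(psi[i, ] ~ b[i, ]))$r.squared, numeric(1))
  expect_equal(sort(ve$r2), sort(r2_manual), tolerance = 1e-8)
  expect_equal(ve$mean_r2, mean(r2_manual))
  expect_equal(ve$ci[2] - ve$mean_r2, 1.96 * sd(r2_manual) / sqrt(3))
})

test_that("null R-squared has the known 1/(n-1) expectation", {
  set.seed(53)
  n <- 20
  reps <- 2000
  b <- matrix(runif(reps * n), reps, n,
              dimnames = list(sprintf("cg%04d", 1:reps), paste0("s", 1:n)))
  psi <- matrix(runif(reps * n), reps, n,
                dimnames = list(sprintf("g%04d:E001", 1:reps), colnames(b)))
  gi <- data.frame(probe_id = rownames(b),
                   gene_id = sprintf("g%04d", 1:reps), bin_id = "E001")
  ve <- variance_explained(b, psi, gi)
  expect_lt(abs(ve$mean_r2 - 1 / (n - 1)), 0.2 / (n - 1))
})

test_that("Fisher z matches its closed form and symmetries", {
  fz <- fisher_z_diffcor(0.5, 50, 0, 50)
  expect_equal(fz$z, atanh(0.5) / sqrt(2 / 47), tolerance = 1e-12)
  expect_equal(fz$z, 2.6629, tolerance = 1e-4)
  expect_equal(fz$p, 0.00775, tolerance = 1e-3)

  same <- fisher_z_diffcor(0.3, 30, 0.3, 20)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)

  sw <- fisher_z_diffcor(0, 50, 0.5, 50)
  expect_equal(sw$z, -fz$z)
  expect_equal(sw$p, fz$p)

  expect_error(fisher_z_diffcor(1, 30, 0.2, 30), "atanh")
  expect_error(fisher_z_diffcor(0.5, 3, 0.2, 30), "at least 4")
})

test_that("diffcor scan joins groups, adjusts, and flags screening hits", {
  one <- diffcor_scan(make_assoc("cg1", 0.7, 30), make_assoc("cg1", -0.2, 20))
  expect_equal(one$fdr, one$p)  # single combination

  keys <- sprintf("cg%03d", 1:30)
  a <- make_assoc(keys, c(rep(0.9, 3), runif(27, -0.2, 0.2)), 40)
  b <- make_assoc(c(keys, "extra"), c(rep(-0.9, 3), runif(27, -0.2, 0.2), 0), 40)
  res <- diffcor_scan(a, b)
  expect_equal(nrow(res), 30L)  # unmatched 'extra' skipped
  expect_true(all(res$screened[match(keys[1:3], res$probe_id)]))
  expect_equal(res$fdr, benjamini_hochberg(res$p), tolerance = 1e-12)
})

test_that("directional replication applies sign and threshold logic", {
  scr <- data.frame(probe_id = c("a", "b", "c", "d"), gene_id = "g",
                    bin_id = "E001",
                    r_dcm = c(-0.7, 0.6, -0.7, -0.7),
                    r_control = c(0.7, 0.2, 0.7, 0.7),
                    n_dcm = 30, n_control = 20,
                    z = -5, p = c(1e-6, 1e-6, 1e-6, 1e-6),
                    fdr = c(1e-4, 1e-4, 1e-4, 1e-4),
                    screened = TRUE, stringsAsFactors = FALSE)
  rp <- data.frame(probe_id = c("a", "b", "c"), gene_id = "g",
                   bin_id = "E001",
                   r_dcm = c(-0.8, 0.5, -0.6),
                   r_control = c(0.6, 0.1, 0.5),
                   p = c(0.01, 0.02, 0.06), stringsAsFactors = FALSE)
  out <- directional_replication(scr, rp)
  get <- function(id, col) out[[col]][out$probe_id == id]
  # reversed signs, consistent across cohorts, p < 0.05: directional
  expect_true(get("a", "replicated"))
  expect_true(get("a", "directionally_replicated"))
  # same-sign groups: replicated but not directional
  expect_true(get("b", "replicated"))
  expect_false(get("b", "directionally_replicated"))
  # replication p = 0.06: not replicated
  expect_false(get("c", "replicated"))
  # absent from replication: not replicated
  expect_false(get("d", "replicated"))
})

test_that("DEU/DMR intersection enumerates the conjunction", {
  pairs <- data.frame(kind = c("intron-exon", "intron-exon", "exon-intron"),
                      probe_id = c("p1", "p2", "p3"),
                      gene_id = c("gA", "gA", "gB"),
                      bin_id = c("E001", "E002", "E001"),
                      distance = c(10L, 20L, 30L), stringsAsFactors = FALSE)
  deu <- data.frame(feature_id = c("gA:E001", "gA:E002", "gB:E001"),
                    p = c(0.01, 0.2, 0.01))
  dmr <- data.frame(feature_id = c("p1", "p2", "p3"),
                    p = c(0.04, 0.01, 0.2))
  ix <- intersect_deu_dmr(deu, dmr, pairs)
  expect_equal(nrow(ix$hits), 1L)
  expect_equal(ix$hits$probe_id, "p1")
  expect_equal(ix$summary$n_pairs, c(1L, 0L))

  no_deu <- intersect_deu_dmr(transform(deu, p = 0.9), dmr, pairs)
  expect_equal(nrow(no_deu$hits), 0L)

  all_in <- intersect_deu_dmr(deu, dmr, pairs, alpha = 1)
  expect_equal(nrow(all_in$hits), 3L)
})

test_that("screening power at planted r of 0.6 matches the analytic expectation", {
  # per-locus detection at |r1 - r2| = 1.2, n = 30/20, among 5,000 nulls is
  # moderate (analytic approximation: BH threshold near |z| = 3.75, mean z
  # = 4.48, detection ~0.77); the scan should find most but not
  # necessarily all planted loci
  set.seed(55)
  n1 <- 30; n2 <- 20
  r_pair <- function(rho, n) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cor(x, y)
  }
  keys <- sprintf("k%04d", 1:5020)
  planted <- keys[1:20]
  r1 <- c(vapply(1:20, function(i) r_pair(-0.6, n1), numeric(1)),
          vapply(1:5000, function(i) r_pair(0, n1), numeric(1)))
  r2 <- c(vapply(1:20, function(i) r_pair(0.6, n2), numeric(1)),
          vapply(1:5000, function(i) r_pair(0, n2), numeric(1)))
  res <- diffcor_scan(make_assoc(keys, r1, n1), make_assoc(keys, r2, n2))
  hits <- res$probe_id[res$screened]
  n_found <- sum(planted %in% hits)
  expect_gte(n_found, 12)           # well above chance, below full recovery
  expect_lte(sum(!(hits %in% planted)), 3)  # FDR control holds
})
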