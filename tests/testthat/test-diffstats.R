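# BH adjustment, design construction, moderated t, NB Wald DGE,
# quasi-binomial DEU.

test_that("BH step-up matches hand-evaluated and reference values", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  p <- c(0.04, NA, 0.001)
  out <- benjamini_hochberg(p)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], p.adjust(p[c(1, 3)], "BH"))
  expect_error(benjamini_hochberg(c(0.5, 1.5)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force step-up and p.adjust on random vectors", {
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    got <- benjamini_hochberg(p)
    expect_equal(got, oracle_bh(p))
    expect_equal(got, p.adjust(p, "BH"))
  }
})

test_that("aliased covariates are dropped deterministically, condition kept", {
  sheet <- make_sheet(6, 6, seed = 1)
  sheet$tacrolimus <- sheet$condition == "control"  # perfect alias
  expect_warning(X <- build_design(sheet, c("sex", "tacrolimus")),
                 "tacrolimus")
  expect_true("condition" %in% colnames(X))
  expect_false("tacrolimus" %in% colnames(X))
  expect_equal(qr(X)$rank, ncol(X))
})

test_that("variance shrinkage interpolates between raw and prior", {
  set.seed(8)
  s2 <- rchisq(300, df = 10) / 10
  sq <- squeeze_var(s2, df = 10)
  expect_true(all(sq$s2_post >= pmin(s2, sq$s2_prior) - 1e-12))
  expect_true(all(sq$s2_post <= pmax(s2, sq$s2_prior) + 1e-12))
  expect_equal(squeeze_var(s2, 10, df_prior = 0)$s2_post, s2)
  pooled <- squeeze_var(s2, 10, df_prior = Inf)$s2_post
  expect_equal(length(unique(round(pooled, 12))), 1L)
})

test_that("count dispersion shrinkage stays between raw and trend", {
  set.seed(9)
  mu <- rlnorm(200, log(100), 1)
  raw <- rlnorm(200, log(0.1), 0.6)
  fit <- shrink_dispersion(raw, mu, df = 30)
  expect_true(all(fit$shrunk >= pmin(fit$raw, fit$trend) - 1e-12))
  expect_true(all(fit$shrunk <= pmax(fit$raw, fit$trend) + 1e-12))
})

test_that("moderated t reduces to ordinary t at d0 = 0 and pools at d0 = Inf", {
  set.seed(12)
  sheet <- make_sheet(8, 7)
  m <- matrix(rnorm(100 * 15), 100, 15,
              dimnames = list(sprintf("p%03d", 1:100), sheet$sample_id))
  raw <- test_dmr(m, sheet, covariates = character(), df_prior = 0)
  X <- build_design(sheet, character())
  ord_t <- apply(m, 1, function(y) summary(lm(y ~ X - 1))$coefficients[2, 3])
  expect_equal(raw$stat, unname(ord_t), tolerance = 1e-8)

  pooled <- test_dmr(m, sheet, covariates = character(), df_prior = Inf)
  s2_pool <- rep(exp(mean(log(apply(qr.resid(qr(X), t(m)), 2,
                                    function(r) sum(r^2) / (15 - 2))))), 100)
  v <- solve(crossprod(X))["condition", "condition"]
  expect_equal(pooled$se, sqrt(s2_pool * v), tolerance = 1e-8)
})

test_that("moderated t agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(13)
  sheet <- make_sheet(15, 12)
  m <- matrix(rnorm(400 * 27, sd = rep(sqrt(rchisq(400, 8) / 8), 27)),
              400, 27, dimnames = list(sprintf("p%03d", 1:400),
                                       sheet$sample_id))
  m[1:20, sheet$condition == "DCM"] <- m[1:20, sheet$condition == "DCM"] + 1
  got <- test_dmr(m, sheet, covariates = c("sex", "age"))
  X <- build_design(sheet, c("sex", "age"))
  fit <- limma::eBayes(limma::lmFit(m, X))
  expect_equal(got$stat, fit$t[, "condition"], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(got$p, fit$p.value[, "condition"], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("planted methylation differences are recovered with uniform null p", {
  set.seed(14)
  sheet <- make_sheet(30, 20)
  n_probe <- 1000
  truth <- seq_len(n_probe) <= 50
  m <- matrix(rnorm(n_probe * 50, sd = 0.6), n_probe, 50,
              dimnames = list(sprintf("p%04d", 1:n_probe), sheet$sample_id))
  m[truth, sheet$condition == "DCM"] <- m[truth, sheet$condition == "DCM"] + 1
  res <- test_dmr(m, sheet, covariates = character())
  sens <- mean(res$fdr[truth] < 0.05)
  fpr <- mean(res$p[!truth] < 0.05)
  expect_gt(sens, 0.9)
  expect_lt(abs(fpr - 0.05), 0.03)
  expect_gt(ks.test(res$p[!truth], "punif")$p.value, 0.01)
})

test_that("NB Wald DGE recovers a planted four-fold change and is calm at null", {
  set.seed(15)
  sheet <- make_sheet(20, 20)
  n_gene <- 200
  mu <- rep(100, n_gene)
  truth <- seq_len(n_gene) <= 20
  counts <- t(vapply(seq_len(n_gene), function(g) {
    m <- ifelse(sheet$condition == "DCM" & truth[g], mu[g] * 4, mu[g])
    rnbinom(40, mu = m, size = 10)
  }, numeric(40)))
  dimnames(counts) <- list(sprintf("g%03d", 1:n_gene), sheet$sample_id)
  res <- test_dge(counts, sheet)
  # planted genes: effect near log2(4) and overwhelmingly significant
  expect_lt(abs(median(res$effect[truth]) - 2), 0.25)
  expect_gt(mean(res$fdr[truth] < 0.05), 0.9)
  # condition permuted at random: null fraction near the nominal level
  perm <- sheet
  perm$condition <- sample(perm$condition)
  res_perm <- test_dge(counts, perm)
  expect_lt(abs(mean(res_perm$p < 0.05) - 0.05), 0.05)

  flat <- matrix(50, 5, 40, dimnames = list(paste0("f", 1:5), sheet$sample_id))
  res_flat <- test_dge(flat, sheet)
  expect_true(all(abs(res_flat$effect) < 1e-6))
  expect_true(all(res_flat$p > 0.99))

  zero <- rbind(counts[1:3, ], allzero = 0)
  res_zero <- test_dge(zero, sheet)
  expect_true(is.na(res_zero$p[4]))
})

test_that("quasi-binomial DEU ranks planted usage shifts highly", {
  set.seed(16)
  sheet <- make_sheet(20, 20)
  n_gene <- 80
  bins_per_gene <- 5
  rows <- character(0)
  counts <- NULL
  truth <- logical(0)
  for (g in seq_len(n_gene)) {
    tot <- rnbinom(40, mu = 500, size = 5) + 50
    base_logit <- rnorm(bins_per_gene, -1.4, 0.3)
    planted <- c(g <= 8, rep(FALSE, bins_per_gene - 1))
    pmat <- vapply(seq_len(bins_per_gene), function(b) {
      eta <- base_logit[b] + ifelse(planted[b] & sheet$condition == "DCM", 1, 0)
      plogis(eta)
    }, numeric(40))
    inc <- vapply(seq_len(bins_per_gene), function(b)
      rbinom(40, tot, pmat[, b]), numeric(40))
    counts <- rbind(counts, t(inc))
    rows <- c(rows, sprintf("g%03d:E%03d", g, seq_len(bins_per_gene)))
    truth <- c(truth, planted)
  }
  dimnames(counts) <- list(rows, sheet$sample_id)
  res <- test_deu(counts, sheet)
  ranks <- rank(res$p)
  auc <- (sum(ranks[!truth]) - sum(!truth) * (sum(!truth) + 1) / 2) /
    (sum(truth) * sum(!truth))
  expect_gt(auc, 0.9)

  # identical proportions in both groups: near-zero effect estimates
  flat_tot <- rep(400L, 40)
  flat <- rbind("gf:E001" = round(flat_tot * 0.25),
                "gf:E002" = flat_tot - round(flat_tot * 0.25))
  colnames(flat) <- sheet$sample_id
  res_flat <- test_deu(flat, sheet)
  expect_true(all(abs(res_flat$effect) < 1e-6))

  # single-bin genes are excluded with a reason
  single <- rbind("gs:E001" = rep(30L, 40))
  colnames(single) <- sheet$sample_id
  res_single <- test_deu(single, sheet)
  expect_true(is.na(res_single$p))
  expect_match(res_single$reason, "single-bin")
})
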