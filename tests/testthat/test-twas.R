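test_that("candidate-variant selection applies the window, p and score filters", {
  v <- tibble::tibble(chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
                      pos = c(2e6 - 999999L, 2e6 + 1000001L, 2e6, 2e6, 2e6),
                      pvalue = c(0.005, 0.005, 0.011, 0.005, 0.005))
  score <- tibble::tibble(score = c(2L, 2L, 2L, 0L, 2L))
  gene <- list(gene = "g", chrom = "chr1", tss = 2e6)
  kept <- select_model_variants(v, score, gene)
  expect_equal(kept, 1L) # others fail window, p, score or chromosome
})

test_that("elastic-net training recovers a noiseless signal and is deterministic", {
  panel <- simulate_expression_panel(n_samples = 200, n_variants = 10,
                                     weights = c(2, rep(0, 9)), h2 = 1,
                                     n_covariates = 0, seed = 31)
  m <- train_prediction_model(panel, "gene1", colnames(panel$dosage), seed = 1)
  expect_gt(m$cv_r2, 0.95)
  w_full <- setNames(numeric(10), colnames(panel$dosage))
  w_full[names(m$weights)] <- m$weights
  expect_equal(names(which.max(abs(w_full))), colnames(panel$dosage)[1])

  m2 <- train_prediction_model(panel, "gene1", colnames(panel$dosage), seed = 1)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$cv_r2, m2$cv_r2)
})

test_that("null expression gives near-zero CV R2", {
  r2 <- vapply(1:5, function(s) {
    panel <- simulate_expression_panel(n_samples = 200, n_variants = 20,
                                       h2 = 0, n_covariates = 0,
                                       seed = 100 + s)
    train_prediction_model(panel, "gene1", colnames(panel$dosage),
                           seed = s)$cv_r2
  }, numeric(1))
  expect_gte(sum(r2 < 0.05), 4) # >= 4 of 5 seeds essentially null
})

test_that("covariate residualization removes confounder signal", {
  panel <- simulate_expression_panel(n_samples = 300, n_variants = 15,
                                     h2 = 0.5, n_covariates = 2, seed = 55)
  m <- train_prediction_model(panel, "gene1", colnames(panel$dosage), seed = 2)
  expect_gt(m$cv_r2, 0.2)
  # sigma_g^2 equals w' Sigma w on the training covariance
  w_full <- setNames(numeric(15), colnames(panel$dosage))
  w_full[names(m$weights)] <- m$weights
  expect_equal(m$sigma_g^2,
               drop(t(w_full) %*% stats::cov(panel$dosage) %*% w_full),
               tolerance = 1e-8)
})

test_that("summary-level Z collapses to the variant z for a single-weight model", {
  gwas <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                         beta = 0.5, se = 0.1)
  model <- structure(list(gene = "g", weights = c("chr1:100:A:G" = 1),
                          sigma_l = c("chr1:100:A:G" = 0.7), sigma_g = 0.7,
                          null_model = FALSE), class = "tf_prediction_model")
  res <- metaxcan_z(model, gwas)
  expect_equal(res$zscore, 0.5 / 0.1)

  # allele flip: swapped ref/alt with flipped weight leaves Z unchanged
  model_fl <- model
  names(model_fl$weights) <- names(model_fl$sigma_l) <- "chr1:100:G:A"
  model_fl$weights[] <- -1
  expect_equal(metaxcan_z(model_fl, gwas)$zscore, res$zscore)

  # absent variant is dropped with a warning; all-absent is an error
  model2 <- model
  names(model2$weights) <- names(model2$sigma_l) <- "chr1:999:A:G"
  expect_error(suppressWarnings(metaxcan_z(model2, gwas)), "harmonized|absent")

  null_model <- structure(list(gene = "g", weights = numeric(0), sigma_g = 0,
                               null_model = TRUE),
                          class = "tf_prediction_model")
  expect_error(metaxcan_z(null_model, gwas), "sigma_g")
})

test_that("strand-ambiguous mismatches are dropped with a warning", {
  gwas <- tibble::tibble(chrom = "chr1", pos = c(100L, 200L),
                         ref = c("A", "A"), alt = c("T", "G"),
                         beta = c(0.5, 0.3), se = c(0.1, 0.1))
  model <- structure(list(
    gene = "g", weights = c("chr1:100:T:A" = 1, "chr1:200:A:G" = 1),
    sigma_l = c("chr1:100:T:A" = 1, "chr1:200:A:G" = 1), sigma_g = 1,
    null_model = FALSE), class = "tf_prediction_model")
  expect_warning(res <- metaxcan_z(model, gwas), "unharmonizable")
  expect_equal(res$n_used, 1L) # only the unambiguous variant survives
  expect_equal(res$zscore, 3)
})

test_that("gene-level aggregation enforces the two-dataset R2 and min-p rule", {
  mk <- function(r2, p) tibble::tibble(
    gene = "g", dataset = c("gtex", "tcga", "metabric"),
    cv_r2 = r2, zscore = 1, p_value = p)
  agg <- aggregate_gene_significance(mk(c(0.02, 0.015, 0.003), c(3e-6, 0.5, 0.5)))
  expect_true(agg$significant)
  agg2 <- aggregate_gene_significance(mk(c(0.02, 0.003, 0.004), c(1e-9, 1, 1)))
  expect_false(agg2$significant)
  agg3 <- aggregate_gene_significance(mk(c(0.02, 0.015, 0.003), c(2e-5, 1, 1)))
  expect_false(agg3$significant)
})

test_that("novelty classification measures distance to known loci", {
  loci <- tibble::tibble(chrom = "chr1", start = c(0, 5e6), end = c(1e4, 5.1e6))
  expect_equal(classify_novelty(list(gene = "a", chrom = "chr1", tss = 2.6e6),
                                loci), "far") # 1.5 Mb from nearest locus end
  expect_equal(classify_novelty(list(gene = "b", chrom = "chr1", tss = 5e3),
                                loci), "within")
  expect_equal(classify_novelty(list(gene = "c", chrom = "chr9", tss = 1e6),
                                loci), "far") # no loci on the chromosome
  expect_equal(classify_novelty(list(gene = "d", chrom = "chr1", tss = 5e3),
                                loci, reported_genes = "d"), "reported")
})

test_that("phenotype permutation drives summary-level Z to null calibration", {
  set.seed(61)
  panel <- simulate_expression_panel(n_samples = 200, n_variants = 15,
                                     h2 = 0.4, n_covariates = 0, seed = 61)
  model <- train_prediction_model(panel, "gene1", colnames(panel$dosage),
                                  seed = 1)
  zs <- vapply(1:40, function(s) {
    cohort <- simulate_expression_panel(n_samples = 1000, n_variants = 15,
                                        weights = panel$truth$weights,
                                        h2 = 0.4, n_covariates = 0,
                                        seed = 1000 + s)
    # permuted phenotype: genetic value shuffled before the GWAS
    g_perm <- sample(cohort$truth$genetic_value)
    sim <- simulate_phenotype_gwas(cohort$dosage, g_perm, alpha = 0.5,
                                   seed = 2000 + s)
    m <- model
    m$sigma_l <- apply(cohort$dosage, 2, sd)
    S <- stats::cov(cohort$dosage)
    wf <- setNames(numeric(15), colnames(cohort$dosage))
    wf[names(model$weights)] <- model$weights
    m$sigma_g <- sqrt(drop(t(wf) %*% S %*% wf))
    metaxcan_z(m, sim$gwas)$zscore
  }, numeric(1))
  expect_lte(mean(abs(zs) > 1.96), 0.05 + 0.08) # small-m binomial slack
})
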