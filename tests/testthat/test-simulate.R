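test_that("peak simulation hits coverage and co-occupancy targets deterministically", {
  genome <- tibble::tibble(chrom = "chr1", length = 1e7)
  pk <- simulate_peaks(genome, n_tfs = 3, coverage = 0.05, seed = 4)
  bp <- vapply(pk, function(p) sum(p$end - p$start), numeric(1))
  expect_true(all(abs(bp - 5e5) / 5e5 < 0.1)) # within 10% of 500 kb

  # designed zero co-occupancy means zero shared interval bases
  des0 <- tibble::tibble(tf1 = "tf1", tf2 = "tf2", frac = 0)
  pk0 <- simulate_peaks(genome, n_tfs = 2, co_occupancy = des0, seed = 4)
  ov <- GenomicRanges::intersect(
    GenomicRanges::GRanges(pk0$tf1$chrom,
                           IRanges::IRanges(pk0$tf1$start + 1, pk0$tf1$end)),
    GenomicRanges::GRanges(pk0$tf2$chrom,
                           IRanges::IRanges(pk0$tf2$start + 1, pk0$tf2$end)))
  expect_equal(length(ov), 0L)

  # designed half co-occupancy is achieved exactly at the slot level
  des <- tibble::tibble(tf1 = "tf1", tf2 = "tf2", frac = 0.5)
  pkh <- simulate_peaks(genome, n_tfs = 2, co_occupancy = des, seed = 4)
  ovh <- GenomicRanges::intersect(
    GenomicRanges::GRanges(pkh$tf1$chrom,
                           IRanges::IRanges(pkh$tf1$start + 1, pkh$tf1$end)),
    GenomicRanges::GRanges(pkh$tf2$chrom,
                           IRanges::IRanges(pkh$tf2$start + 1, pkh$tf2$end)))
  expect_equal(sum(IRanges::width(ovh)), 0.5 * 5e5, tolerance = 0.01)

  expect_identical(simulate_peaks(genome, seed = 9),
                   simulate_peaks(genome, seed = 9))
})

test_that("GWAS z-score generator matches its closed-form moments", {
  # null: mean chi2 ~ 1
  v0 <- simulate_gwas_summary(n_blocks = 1000, variants_per_block = 20,
                              rho = 0.2, seed = 6)
  expect_equal(mean(v0$chi2), 1, tolerance = 0.05)

  # lambda = 1 on one TF: sample delta-chi2 ~ 1 at 1e5 variants
  anno <- tibble::tibble(tf1 = as.integer(runif(1e5) < 0.1))
  v1 <- simulate_gwas_summary(n_blocks = 5000, variants_per_block = 20,
                              annotation = anno, lambda = c(tf1 = 1),
                              rho = 0.2, seed = 6)
  d <- mean(v1$chi2[anno$tf1 == 1]) - mean(v1$chi2[anno$tf1 == 0])
  expect_equal(d, 1, tolerance = 0.1)

  # within-block z-correlation ~ rho, recovered by the intercept-only fit
  v9 <- simulate_gwas_summary(n_blocks = 2000, variants_per_block = 10,
                              rho = 0.9, seed = 7)
  z <- v9$beta # z-scale response
  fit <- fit_block_lmm(z, matrix(1, length(z), 1,
                                 dimnames = list(NULL, "(Intercept)")),
                       v9$block_id)
  icc <- fit$var_block / (fit$var_block + fit$var_resid)
  expect_equal(icc, 0.9, tolerance = 0.03)

  # beta/se and p columns are mutually consistent
  expect_equal(v0$chi2, (v0$beta / v0$se)^2, tolerance = 1e-12)
  expect_equal(v0$pvalue, p_from_chi2(v0$chi2), tolerance = 1e-12)
})

test_that("study bundles align, round-trip through the readers, and are reproducible", {
  st <- simulate_study("smoke", seed = 12)
  expect_equal(nrow(st$variants), nrow(st$annotation))
  expect_equal(nrow(st$variants), 500 * 20)
  st2 <- simulate_study("smoke", seed = 12)
  expect_identical(st$variants, st2$variants)
  expect_identical(st$annotation, st2$annotation)

  # file round trip: gwas table and peaks survive write + read
  dir <- withr::local_tempdir()
  gpath <- file.path(dir, "gwas.tsv")
  write_gwas_table(st$variants, gpath)
  back <- readr::read_tsv(gpath, show_col_types = FALSE)
  expect_equal(back$chi2, st$variants$chi2, tolerance = 1e-12)
  ppath <- file.path(dir, "tf1.bed")
  readr::write_tsv(as.data.frame(st$peaks$tf1), ppath, col_names = FALSE,
                   progress = FALSE)
  pk <- read_peaks(ppath, tf_name = "tf1")
  expect_equal(pk$start, st$peaks$tf1$start)
  expect_equal(pk$end, st$peaks$tf1$end)
})

test_that("expression panel: heritability limits and LD knob behave", {
  # h2 = 1: training R2 -> 1
  p1 <- simulate_expression_panel(n_samples = 300, n_variants = 10, h2 = 1,
                                  n_covariates = 0, seed = 21)
  r2 <- suppressWarnings(summary(lm(p1$expression[, 1] ~ p1$dosage))$r.squared)
  expect_gt(r2, 0.99)

  # neighbor-copy 0: near-zero inter-variant dosage correlation
  p0 <- simulate_expression_panel(n_samples = 2000, n_variants = 10,
                                  neighbor_copy = 0, n_covariates = 0,
                                  seed = 22)
  cors <- stats::cor(p0$dosage)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.1)

  # neighbor-copy high: adjacent dosages strongly correlated
  pl <- simulate_expression_panel(n_samples = 2000, n_variants = 10,
                                  neighbor_copy = 0.8, n_covariates = 0,
                                  seed = 23)
  adj <- diag(stats::cor(pl$dosage)[-1, -nrow(stats::cor(pl$dosage))])
  expect_gt(mean(adj), 0.4)
})

test_that("cohort GWAS: effect direction and sqrt(n) scaling of Z", {
  panel <- simulate_expression_panel(n_samples = 2000, n_variants = 10,
                                     weights = c(1, rep(0, 9)), h2 = 0.5,
                                     n_covariates = 0, seed = 31)
  sim <- simulate_phenotype_gwas(panel$dosage, panel$truth$genetic_value,
                                 alpha = 1, seed = 31)
  causal <- names(panel$truth$weights)[panel$truth$weights != 0]
  expect_gt(sim$gwas$beta[sim$gwas$pos == 1e6], 0) # sign matches alpha > 0

  # alpha = 0: chi2 behaves as a null 1-df chi-square
  sim0 <- simulate_phenotype_gwas(panel$dosage, panel$truth$genetic_value,
                                  alpha = 0, seed = 32)
  expect_equal(mean(sim0$gwas$chi2), 1, tolerance = 0.6)

  # doubling the cohort scales the causal |z| by ~sqrt(2)
  zs <- vapply(c(1000L, 4000L), function(n) {
    mean(vapply(1:8, function(s) {
      pp <- simulate_expression_panel(n_samples = n, n_variants = 10,
                                      weights = c(1, rep(0, 9)), h2 = 0.5,
                                      n_covariates = 0, seed = 40 + s)
      sm <- simulate_phenotype_gwas(pp$dosage, pp$truth$genetic_value,
                                    alpha = 0.2, seed = 50 + s)
      abs(sm$gwas$beta[1] / sm$gwas$se[1])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(zs[2] / zs[1], 2, tolerance = 0.35) # 4x samples ~ 2x |z|
})

test_that("gene-effect tables separate essential from neutral genes", {
  sim <- simulate_gene_effects(n_genes = 100, n_cells = 34, seed = 9)
  med <- apply(sim$effects, 1, median)
  expect_true(all(med[sim$essential] < -0.5))
  expect_true(all(med[!sim$essential] > -0.5))
  expect_identical(simulate_gene_effects(seed = 3)$effects,
                   simulate_gene_effects(seed = 3)$effects)
})
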