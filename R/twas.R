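#' Select candidate variants for a gene's expression model
#'
#' The TF-restricted TWAS trains each gene's model only on putative regulatory
#' variants: within +/- `window` of the gene's TSS, with a GWAS p-value below
#' `p_cut`, and occupied by at least `min_score` of the risk-associated TFs.
#'
#' @param variants Variant tibble with `chrom`, `pos`, `pvalue`.
#' @param score Tibble from [compute_tf_score()] aligned to `variants` (or an
#'   integer score vector).
#' @param gene One-row tibble/list with `chrom` and `tss`.
#' @param window Flank in bp around the TSS (default 1 Mb).
#' @param p_cut GWAS p-value ceiling (default 0.01).
#' @param min_score Minimum TF-occupancy score (default 1).
#' @return Integer row indices into `variants` of the retained candidates.
#' @export
select_model_variants <- function(variants, score, gene, window = 1e6,
                                  p_cut = 0.01, min_score = 1) {
  s <- if (is.data.frame(score)) score$score else as.integer(score)
  stopifnot(length(s) == nrow(variants))
  which(variants$chrom == gene$chrom &
          abs(variants$pos - gene$tss) <= window &
          variants$pvalue < p_cut &
          s >= min_score)
}

#' Train a per-gene elastic-net expression model
#'
#' Covariates are regressed out of the expression vector first
#' (residualization), then an elastic net (mixing parameter `alpha`, default
#' 0.5) is fit on the dosages with `folds`-fold cross-validation; the penalty
#' is chosen at the CV minimum and `cv_r2` is the squared correlation between
#' out-of-fold predictions and the residualized expression. Reference SDs
#' (`sigma_l` per variant, `sigma_g` of the predicted expression) are computed
#' from the training panel's genotype covariance, the default LD reference for
#' the summary-level association.
#'
#' @param panel List with `dosage` (samples x variants matrix with variant-key
#'   column names), `expression` (samples x genes matrix or a named numeric
#'   vector), optional `covariates` (samples x k matrix/data frame).
#' @param gene Gene name (column of `expression`), ignored when `expression`
#'   is a vector.
#' @param variant_keys Column names of `dosage` to use as candidates.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @return A `tf_prediction_model` list: `gene`, `variant_keys`, `weights`
#'   (named, only retained variants), `cv_r2`, `alpha`, `lambda`, `sigma_l`
#'   (named SDs of all candidate dosages), `sigma_g`, `null_model` (TRUE when
#'   every weight is zero), `n_samples`.
#' @export
train_prediction_model <- function(panel, gene, variant_keys, folds = 10,
                                   seed = 1, alpha = 0.5) {
  X <- as.matrix(panel$dosage[, variant_keys, drop = FALSE])
  expr <- panel$expression
  y <- if (is.matrix(expr) || is.data.frame(expr)) {
    as.numeric(as.matrix(expr)[, gene])
  } else as.numeric(expr)
  n <- length(y)
  if (ncol(X) < 2) abort("Need at least 2 candidate variants.")
  if (n < folds) abort("Fewer samples than CV folds.")
  keep <- apply(X, 2, function(v) sd(v) > 0)
  if (!all(keep)) {
    warn(sprintf("Dropped %d constant-dosage variant(s).", sum(!keep)))
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) < 2) abort("Fewer than 2 variable candidate variants.")
  if (!is.null(panel$covariates)) {
    C <- as.matrix(as.data.frame(panel$covariates))
    y <- residuals(lm(y ~ C))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))
  cv <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid, keep = TRUE,
                          standardize = TRUE)
  i_min <- which(cv$lambda == cv$lambda.min)
  oof <- cv$fit.preval[, i_min]
  # squared out-of-fold correlation, counted only when positive: under the
  # null, out-of-fold predictions anti-correlate with y and squaring that
  # would masquerade as predictive ability
  cv_r2 <- if (sd(oof) > 0) max(0, cor(oof, y))^2 else 0
  w_all <- as.numeric(coef(cv, s = "lambda.min"))[-1]
  names(w_all) <- colnames(X)
  nz <- w_all != 0
  sigma_l <- apply(X, 2, sd)
  Sigma <- stats::cov(X)
  sigma_g <- sqrt(max(0, drop(crossprod(w_all, Sigma %*% w_all))))
  structure(list(gene = gene, variant_keys = colnames(X),
                 weights = w_all[nz], cv_r2 = cv_r2, alpha = alpha,
                 lambda = cv$lambda.min, sigma_l = sigma_l, sigma_g = sigma_g,
                 null_model = !any(nz), n_samples = n),
            class = "tf_prediction_model")
}

#' @export
#' @method print tf_prediction_model
print.tf_prediction_model <- function(x, ...) {
  cat(sprintf("Expression model for %s: %d/%d nonzero weights, CV R2 = %.3f\n",
              x$gene, length(x$weights), length(x$variant_keys), x$cv_r2))
  invisible(x)
}

ambiguous_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Summary-level gene-trait association Z-score
#'
#' Combines the gene's expression-model weights with per-variant GWAS
#' statistics, without individual-level data:
#' \deqn{Z_g = \sum_{l \in \mathrm{Model}_g} w_{lg}\,
#'   \frac{\hat\sigma_l}{\hat\sigma_g}\,
#'   \frac{\hat\beta_l}{\mathrm{se}(\hat\beta_l)}.}
#' Variants are matched on (chrom, pos); when the GWAS effect allele is the
#' model's reference allele the z-score is sign-flipped, strand-ambiguous
#' A/T and C/G variants whose alleles do not match are dropped with a warning,
#' as are model variants absent from the GWAS.
#'
#' @param model A `tf_prediction_model`; variant keys must be
#'   `"chrom:pos:ref:alt"`.
#' @param gwas Variant tibble with `chrom`, `pos`, `ref`, `alt`, `beta`, `se`.
#' @return One-row tibble: `gene`, `zscore`, `p_value`, `n_model_variants`,
#'   `n_used`.
#' @export
metaxcan_z <- function(model, gwas) {
  if (model$null_model || model$sigma_g <= 0) {
    abort("Association undefined: the model has no nonzero weights (sigma_g = 0).")
  }
  keys <- names(model$weights)
  parts <- strsplit(keys, ":", fixed = TRUE)
  mk <- tibble(key = keys,
               chrom = purrr::map_chr(parts, 1),
               pos = as.integer(purrr::map_chr(parts, 2)),
               ref = purrr::map_chr(parts, 3),
               alt = purrr::map_chr(parts, 4),
               w = unname(model$weights),
               sigma_l = unname(model$sigma_l[keys]))
  m <- left_join(mk, gwas[, c("chrom", "pos", "ref", "alt", "beta", "se")],
                 by = c("chrom", "pos"), suffix = c("", ".gwas"))
  absent <- is.na(m$beta)
  if (any(absent)) {
    warn(sprintf("%d model variant(s) absent from the GWAS; dropped.", sum(absent)))
    m <- m[!absent, , drop = FALSE]
  }
  same <- m$ref == m$ref.gwas & m$alt == m$alt.gwas
  flipped <- m$ref == m$alt.gwas & m$alt == m$ref.gwas & !ambiguous_pair(m$ref, m$alt)
  bad <- !same & !flipped
  if (any(bad)) {
    warn(sprintf("%d variant(s) dropped for unharmonizable alleles.", sum(bad)))
    m <- m[!bad, , drop = FALSE]
    same <- same[!bad]; flipped <- flipped[!bad]
  }
  if (!nrow(m)) abort("No model variant could be harmonized with the GWAS.")
  z_l <- (m$beta / m$se) * ifelse(flipped, -1, 1)
  z <- sum(m$w * (m$sigma_l / model$sigma_g) * z_l)
  tibble(gene = model$gene, zscore = z, p_value = 2 * pnorm(-abs(z)),
         n_model_variants = length(keys), n_used = nrow(m))
}

#' Aggregate per-dataset TWAS results into gene-level significance
#'
#' A gene is called significant when its model reaches `cv_r2 >
#' r2_threshold` in at least two datasets and its smallest association
#' p-value across datasets is below `p_threshold`.
#'
#' @param assocs Tibble with one row per (gene, dataset): columns `gene`,
#'   `dataset`, `cv_r2`, `zscore`, `p_value`.
#' @param r2_threshold CV R2 floor (default 0.01).
#' @param p_threshold Minimum-p ceiling (default 1e-5).
#' @return Tibble with one row per gene: `gene`, `n_datasets`,
#'   `n_r2_pass`, `min_p`, `best_dataset`, `significant`.
#' @export
aggregate_gene_significance <- function(assocs, r2_threshold = 0.01,
                                        p_threshold = 1e-5) {
  assocs %>%
    group_by(.data$gene) %>%
    summarise(n_datasets = dplyr::n(),
              n_r2_pass = sum(.data$cv_r2 > r2_threshold),
              min_p = min(.data$p_value),
              best_dataset = .data$dataset[which.min(.data$p_value)],
              .groups = "drop") %>%
    mutate(significant = .data$n_r2_pass >= 2 & .data$min_p < p_threshold)
}

#' Classify a TWAS gene's novelty relative to known GWAS loci
#'
#' @param gene One-row tibble/list with `gene`, `chrom`, `tss`.
#' @param gwas_loci Tibble of known loci (`chrom`, `start`, `end`; BED
#'   convention); may be empty.
#' @param distance Distance defining "within" a locus (default 1 Mb).
#' @param reported_genes Optional character vector of previously reported
#'   genes; membership overrides the distance classes.
#' @return One of `"reported"`, `"within"`, `"far"`.
#' @export
classify_novelty <- function(gene, gwas_loci, distance = 1e6,
                             reported_genes = NULL) {
  if (!is.null(reported_genes) && gene$gene %in% reported_genes) {
    return("reported")
  }
  loci <- gwas_loci[gwas_loci$chrom == gene$chrom, , drop = FALSE]
  if (!nrow(loci)) return("far")
  # distance from TSS to the nearest locus interval (0 when inside)
  d <- pmax(0, pmax(loci$start + 1 - gene$tss, gene$tss - loci$end))
  if (min(d) < distance) "within" else "far"
}
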