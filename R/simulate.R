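#' Simulate TF peak sets with controlled co-occupancy
#'
#' The genome is partitioned into `peak_width` slots; each TF occupies a
#' random subset of slots so its marginal coverage is exact by construction.
#' Pairwise co-occupancy is controlled through a design table: a designed pair
#' shares exactly `round(frac * n_slots)` slots and overlaps nowhere else, so
#' `frac = 0` yields fully disjoint interval sets.
#'
#' @param genome Tibble with `chrom` and `length` (bp); default one 10 Mb
#'   chromosome.
#' @param n_tfs Number of TFs (default 5), named `tf1..tfn`.
#' @param coverage Fraction of the genome each TF covers (default 0.05;
#'   recycled per TF).
#' @param peak_width Peak width in bp (default 1000).
#' @param co_occupancy Optional tibble with `tf1`, `tf2`, `frac`: the fraction
#'   of each TF's slots shared by the pair.
#' @param seed Integer seed.
#' @return Named list of `tf_peaks` objects.
#' @export
simulate_peaks <- function(genome = tibble(chrom = "chr1", length = 1e7),
                           n_tfs = 5, coverage = 0.05, peak_width = 1000,
                           co_occupancy = NULL, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  coverage <- rep_len(coverage, n_tfs)
  slots_per_chrom <- floor(genome$length / peak_width)
  total_slots <- sum(slots_per_chrom)
  chrom_of <- rep(genome$chrom, slots_per_chrom)
  offset_of <- unlist(purrr::map(slots_per_chrom, seq_len)) - 1
  tf_names <- paste0("tf", seq_len(n_tfs))
  slot_sets <- setNames(vector("list", n_tfs), tf_names)
  for (k in seq_len(n_tfs)) {
    n_slots <- round(coverage[k] * total_slots)
    shared <- integer()
    forbidden <- integer()
    if (!is.null(co_occupancy)) {
      des <- co_occupancy[co_occupancy$tf2 == tf_names[k] &
                            co_occupancy$tf1 %in% tf_names[seq_len(k - 1)], ,
                          drop = FALSE]
      for (i in seq_len(nrow(des))) {
        partner <- slot_sets[[des$tf1[i]]]
        n_share <- round(des$frac[i] * n_slots)
        pool <- setdiff(partner, c(shared, forbidden))
        if (n_share > length(pool)) {
          abort(sprintf("Cannot share %d slots between %s and %s.",
                        n_share, des$tf1[i], des$tf2[i]))
        }
        shared <- c(shared, sample(pool, n_share))
        forbidden <- union(forbidden, partner)
      }
    }
    free <- setdiff(seq_len(total_slots), union(shared, forbidden))
    extra <- sample(free, n_slots - length(shared))
    slot_sets[[k]] <- sort(c(shared, extra))
  }
  purrr::imap(slot_sets, function(slots, nm) {
    peak_set(chrom_of[slots], offset_of[slots] * peak_width,
             (offset_of[slots] + 1) * peak_width, tf_name = nm,
             cell_line = "synthetic")
  })
}

#' Simulate a ChromHMM-style segmentation
#'
#' Tiles each chromosome with fixed-width segments and draws a state mnemonic
#' per segment.
#'
#' @param genome Tibble with `chrom` and `length`.
#' @param states Character vector of state mnemonics.
#' @param probs State probabilities (default uniform).
#' @param segment_width Segment width in bp (default 10 kb).
#' @param seed Integer seed.
#' @return Tibble with `chrom`, `start`, `end`, `state` (BED convention).
#' @export
simulate_chromhmm <- function(genome = tibble(chrom = "chr1", length = 1e7),
                              states = c("TssA", "Enh", "Tx", "Het", "Quies"),
                              probs = NULL, segment_width = 1e4, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  purrr::pmap_dfr(genome, function(chrom, length) {
    n_seg <- ceiling(length / segment_width)
    start <- (seq_len(n_seg) - 1) * segment_width
    tibble(chrom = chrom, start = start,
           end = pmin(start + segment_width, length),
           state = sample(states, n_seg, replace = TRUE, prob = probs))
  })
}

#' Simulate GWAS summary statistics with block correlation and annotation shifts
#'
#' Per-variant z-scores follow the factor model
#' \deqn{z_{ij} = \sqrt{\rho}\, u_i + \sqrt{1-\rho}\, e_{ij} + s_{ij},}
#' with a shared standard-normal block factor \eqn{u_i}, independent noise
#' \eqn{e_{ij}}, and a deterministic annotation shift
#' \eqn{s_{ij} = \sum_f \lambda_f A_{ijf}} plus any pairwise co-binding
#' shifts. The chi-square is \eqn{z^2} and the p-value its 1-df upper tail, so
#' the expected chi-square difference between variants bound by a single TF
#' and unbound variants is exactly \eqn{\lambda^2}. `beta` is set to `z` and
#' `se` to 1, making `(beta/se)^2` consistent with `chi2`.
#'
#' @param n_blocks,variants_per_block Block grid (defaults 500 x 20).
#' @param block_size Block width in bp (default 100 kb).
#' @param annotation Optional binary tibble/matrix (n variants x features)
#'   aligned to the generated variant order.
#' @param lambda Named numeric vector of per-feature shifts (names must be
#'   `annotation` columns); NULL for none.
#' @param interactions Optional tibble `tf1`, `tf2`, `shift`: extra shift
#'   added where both columns are 1 (super-additive co-binding).
#' @param rho Within-block z correlation in \[0, 1) (default 0.2).
#' @param chrom Chromosome label (default "chr1"; blocks laid consecutively).
#' @param seed Integer seed.
#' @return A variant tibble (`chrom`, `pos`, `ref`, `alt`, `beta`, `se`,
#'   `pvalue`, `chi2`, `block_id`).
#' @export
simulate_gwas_summary <- function(n_blocks = 500, variants_per_block = 20,
                                  block_size = 1e5, annotation = NULL,
                                  lambda = NULL, interactions = NULL,
                                  rho = 0.2, chrom = "chr1", seed = 1) {
  stopifnot(rho >= 0, rho < 1)
  n <- n_blocks * variants_per_block
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  block <- rep(seq_len(n_blocks) - 1L, each = variants_per_block)
  within <- as.integer(unlist(purrr::map(
    seq_len(n_blocks), ~ sort(sample.int(block_size, variants_per_block)))))
  pos <- block * block_size + within
  shift <- numeric(n)
  if (!is.null(lambda)) {
    stopifnot(!is.null(annotation), all(names(lambda) %in% colnames(annotation)))
    A <- as.matrix(as.data.frame(annotation)[, names(lambda), drop = FALSE])
    shift <- shift + drop(A %*% lambda)
  }
  if (!is.null(interactions)) {
    for (i in seq_len(nrow(interactions))) {
      shift <- shift + interactions$shift[i] *
        annotation[[interactions$tf1[i]]] * annotation[[interactions$tf2[i]]]
    }
  }
  u <- rnorm(n_blocks)
  z <- sqrt(rho) * u[block + 1L] + sqrt(1 - rho) * rnorm(n) + shift
  chi2 <- z^2
  tibble(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
         beta = z, se = 1, pvalue = p_from_chi2(chi2), chi2 = chi2,
         block_id = block)
}

#' Simulate a complete annotated study
#'
#' Bundles peaks, chromatin segmentation, GWAS summary statistics, the binary
#' annotation matrix and the ground truth for one of three profiles:
#' `"smoke"` (500 blocks x 20 variants, 5 TFs), `"calibration"` (5,000 x 50)
#' or `"twas"` (smoke-sized genome with denser small-p enrichment for model
#' training). Defaults plant an enrichment of `lambda = 1` on `tf1` (so the
#' true mean chi-square difference is 1) with within-block correlation 0.2
#' (smoke) or 0.3 (calibration); pass `lambda = 0` for a null study.
#'
#' @param profile One of `"smoke"`, `"calibration"`, `"twas"`.
#' @param seed Integer seed (streams for peaks, segmentation and z-scores are
#'   derived from it).
#' @param lambda Per-TF shift vector recycled/named over the TFs, or a single
#'   number applied to `tf1` only (default 1).
#' @param rho Within-block z correlation (profile default when NULL).
#' @param n_tfs Number of TFs (default 5).
#' @param interactions Optional co-binding shift design (see
#'   [simulate_gwas_summary()]).
#' @param co_occupancy Optional peak co-occupancy design (see
#'   [simulate_peaks()]).
#' @return List with `variants`, `peaks`, `annotation`, `chromhmm`,
#'   `chromatin`, `score`, `truth`.
#' @export
simulate_study <- function(profile = c("smoke", "calibration", "twas"),
                           seed = 1, lambda = 1, rho = NULL, n_tfs = 5,
                           interactions = NULL, co_occupancy = NULL) {
  profile <- match.arg(profile)
  dims <- switch(profile,
                 smoke = list(n_blocks = 500L, vpb = 20L, rho = 0.2),
                 calibration = list(n_blocks = 5000L, vpb = 50L, rho = 0.3),
                 twas = list(n_blocks = 500L, vpb = 20L, rho = 0.2))
  rho <- rho %||% dims$rho
  block_size <- 1e5
  genome <- tibble(chrom = "chr1", length = dims$n_blocks * block_size)
  tf_names <- paste0("tf", seq_len(n_tfs))
  if (length(lambda) == 1 && is.null(names(lambda))) {
    lambda <- setNames(c(lambda, rep(0, n_tfs - 1)), tf_names)
  } else {
    lambda <- setNames(rep_len(lambda, n_tfs), tf_names)
  }
  peaks <- simulate_peaks(genome, n_tfs = n_tfs, coverage = 0.05,
                          co_occupancy = co_occupancy, seed = seed + 1000L)
  chromhmm <- simulate_chromhmm(genome, seed = seed + 2000L)
  # positions first (annotation must align to them), then z-scores with shifts
  skeleton <- simulate_gwas_summary(dims$n_blocks, dims$vpb, block_size,
                                    rho = rho, seed = seed)
  annotation <- annotate_tf_binding(skeleton, peaks)
  variants <- simulate_gwas_summary(dims$n_blocks, dims$vpb, block_size,
                                    annotation = annotation, lambda = lambda,
                                    interactions = interactions, rho = rho,
                                    seed = seed)
  chromatin <- suppressWarnings(annotate_chromatin(variants, chromhmm))
  score <- compute_tf_score(annotation)
  truth <- list(profile = profile, lambda = lambda, rho = rho,
                interactions = interactions, co_occupancy = co_occupancy,
                n_blocks = dims$n_blocks, variants_per_block = dims$vpb,
                block_size = block_size, seed = seed)
  list(variants = variants, peaks = peaks, annotation = annotation,
       chromhmm = chromhmm, chromatin = chromatin, score = score, truth = truth)
}

#' Simulate a genotype/expression training panel
#'
#' Dosages come from two haplotypes per sample; along each haplotype a variant
#' copies its left neighbour's allele with probability `neighbor_copy`
#' (a simple exponential-decay LD surrogate) and is otherwise drawn fresh at
#' its allele frequency. Expression is the dosage-weighted genetic value plus
#' covariate effects and Gaussian noise scaled so the genetic value explains a
#' fraction `h2` of the (covariate-free) variance.
#'
#' @param n_samples,n_variants Panel dimensions (defaults 300 x 30).
#' @param freq Allele frequencies (default drawn Uniform(0.1, 0.5)).
#' @param neighbor_copy LD neighbour-copy probability (default 0.3).
#' @param weights True variant weights: a numeric vector of length
#'   `n_variants`, or NULL to draw `n_causal` nonzero weights of size
#'   `effect_size`.
#' @param n_causal,effect_size Sparse-truth defaults (3 causal variants,
#'   weight 1).
#' @param h2 Fraction of expression variance explained by the genetic value
#'   in \[0, 1\] (default 0.3; 0 forces all-zero weights' signal).
#' @param n_covariates Number of standard-normal covariates with effects
#'   (default 2).
#' @param chrom,pos_start,pos_step Variant coordinates (1 kb spacing on chr1
#'   by default).
#' @param gene Gene name for the expression column (default "gene1").
#' @param seed Integer seed.
#' @return List: `dosage` (matrix, columns keyed `chrom:pos:ref:alt`),
#'   `expression` (n x 1 matrix), `covariates` (data frame), `variants`
#'   (metadata tibble), `truth` (weights, h2, genetic values).
#' @export
simulate_expression_panel <- function(n_samples = 300, n_variants = 30,
                                      freq = NULL, neighbor_copy = 0.3,
                                      weights = NULL, n_causal = 3,
                                      effect_size = 1, h2 = 0.3,
                                      n_covariates = 2, chrom = "chr1",
                                      pos_start = 1e6, pos_step = 1000,
                                      gene = "gene1", seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  freq <- freq %||% runif(n_variants, 0.1, 0.5)
  freq <- rep_len(freq, n_variants)
  hap <- function() {
    h <- matrix(0L, n_samples, n_variants)
    h[, 1] <- rbinom(n_samples, 1, freq[1])
    for (l in seq_len(n_variants)[-1]) {
      copy <- runif(n_samples) < neighbor_copy
      h[, l] <- ifelse(copy, h[, l - 1], rbinom(n_samples, 1, freq[l]))
    }
    h
  }
  X <- hap() + hap()
  pos <- pos_start + (seq_len(n_variants) - 1) * pos_step
  keys <- paste(chrom, pos, "A", "G", sep = ":")
  colnames(X) <- keys
  if (is.null(weights)) {
    weights <- numeric(n_variants)
    if (h2 > 0 && n_causal > 0) {
      weights[sample.int(n_variants, n_causal)] <-
        effect_size * sample(c(-1, 1), n_causal, replace = TRUE)
    }
  }
  g <- drop(X %*% weights)
  vg <- var(g)
  noise_sd <- if (h2 >= 1) 0
  else if (h2 <= 0 || vg == 0) 1
  else sqrt(vg * (1 - h2) / h2)
  covariates <- NULL
  cov_effect <- 0
  y <- g + rnorm(n_samples, sd = noise_sd)
  if (n_covariates > 0) {
    C <- matrix(rnorm(n_samples * n_covariates), n_samples)
    colnames(C) <- paste0("cov", seq_len(n_covariates))
    cov_effect <- rep_len(c(0.5, -0.5), n_covariates)
    y <- y + drop(C %*% cov_effect)
    covariates <- as.data.frame(C)
  }
  expression <- matrix(y, ncol = 1, dimnames = list(NULL, gene))
  variants <- tibble(chrom = chrom, pos = as.integer(pos), ref = "A",
                     alt = "G", key = keys)
  list(dosage = X, expression = expression, covariates = covariates,
       variants = variants,
       truth = list(weights = setNames(weights, keys), h2 = h2,
                    genetic_value = g, freq = freq,
                    cov_effect = cov_effect, seed = seed))
}

#' Simulate a GWAS cohort and its per-variant summary statistics
#'
#' Draws a phenotype from a genetic value (e.g. a gene's true or predicted
#' expression) plus noise, then computes marginal per-variant regressions of
#' the phenotype on each dosage — the individual-level oracle feeding the
#' summary-level association check.
#'
#' @param dosage Cohort dosage matrix (samples x variants, columns keyed
#'   `chrom:pos:ref:alt`).
#' @param genetic_value Numeric per-sample genetic value.
#' @param alpha Effect of the genetic value on the phenotype (default 0.5).
#' @param noise_sd Phenotype noise SD (default 1).
#' @param block_size LD-block width for the output table (default 100 kb).
#' @param seed Integer seed.
#' @return List: `gwas` (variant tibble with `beta`, `se`, `pvalue`, `chi2`,
#'   `block_id`), `phenotype`.
#' @export
simulate_phenotype_gwas <- function(dosage, genetic_value, alpha = 0.5,
                                    noise_sd = 1, block_size = 1e5, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(dosage)
  y <- alpha * genetic_value + rnorm(n, sd = noise_sd)
  xc <- scale(dosage, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  if (any(sxx == 0)) abort("Constant-dosage variant in the cohort.")
  sxy <- drop(crossprod(xc, yc))
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  se <- sqrt(rss / (n - 2) / sxx)
  parts <- strsplit(colnames(dosage), ":", fixed = TRUE)
  gwas <- tibble(chrom = purrr::map_chr(parts, 1),
                 pos = as.integer(purrr::map_chr(parts, 2)),
                 ref = purrr::map_chr(parts, 3),
                 alt = purrr::map_chr(parts, 4),
                 beta = beta, se = se,
                 pvalue = p_from_chi2((beta / se)^2),
                 chi2 = (beta / se)^2)
  gwas <- assign_ld_blocks(gwas, block_size = block_size)
  list(gwas = gwas, phenotype = y)
}

#' Simulate a CERES-like gene-effect table
#'
#' Essential genes are drawn with mean effect `essential_mean` (well below
#' the -0.5 dependency cutoff); the rest centre at 0.
#'
#' @param n_genes Number of genes (default 50).
#' @param n_cells Number of cell lines (default 34).
#' @param essential_fraction Fraction of essential genes (default 0.2).
#' @param essential_mean,sd Effect distribution parameters.
#' @param seed Integer seed.
#' @return List: `effects` (genes x cells matrix), `essential` (logical).
#' @export
simulate_gene_effects <- function(n_genes = 50, n_cells = 34,
                                  essential_fraction = 0.2,
                                  essential_mean = -1, sd = 0.3, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  essential <- runif(n_genes) < essential_fraction
  mu <- ifelse(essential, essential_mean, 0)
  effects <- matrix(rnorm(n_genes * n_cells, mean = rep(mu, n_cells), sd = sd),
                    nrow = n_genes,
                    dimnames = list(paste0("gene", seq_len(n_genes)),
                                    paste0("cell", seq_len(n_cells))))
  list(effects = effects, essential = essential)
}
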