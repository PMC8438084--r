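#' Gene essentiality test on CRISPR gene-effect scores
#'
#' For one gene, counts how many cell lines have a negative CERES-style
#' gene-effect score and tests whether negatives exceed chance with a
#' one-sided binomial test (k successes in n trials against p = 0.5,
#' alternative "greater"). Independently of the test, the gene is flagged
#' essential when its median score across the cells falls below `cutoff`
#' (default -0.5, the conventional dependency threshold).
#'
#' @param scores Numeric vector of per-cell-line gene-effect scores.
#' @param cutoff Median-score cutoff for the essentiality flag (default -0.5).
#' @param gene Optional gene label carried into the result.
#' @return One-row tibble: `gene`, `n_cells`, `n_negative`, `median_score`,
#'   `binom_p`, `essential_flag`.
#' @export
essentiality_test <- function(scores, cutoff = -0.5, gene = NA_character_) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) abort("Empty score vector.")
  n <- length(scores)
  k <- sum(scores < 0)
  # one-sided upper tail: P(X >= k), X ~ Binomial(n, 1/2)
  binom_p <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  med <- median(scores)
  tibble(gene = gene, n_cells = n, n_negative = k, median_score = med,
         binom_p = binom_p, essential_flag = med < cutoff)
}

#' Essentiality screen over a gene-effect table
#'
#' @param effects Matrix or data frame of gene-effect scores, genes in rows,
#'   cell lines in columns.
#' @param cell_lines Optional character vector restricting the columns (e.g.
#'   the breast-relevant lines).
#' @param cutoff Median cutoff passed to [essentiality_test()].
#' @return Tibble with one [essentiality_test()] row per gene.
#' @export
essentiality_screen <- function(effects, cell_lines = NULL, cutoff = -0.5) {
  m <- as.matrix(as.data.frame(effects))
  if (!is.null(cell_lines)) {
    missing_cl <- setdiff(cell_lines, colnames(m))
    if (length(missing_cl)) {
      abort(sprintf("Unknown cell line(s): %s", paste(missing_cl, collapse = ", ")))
    }
    m <- m[, cell_lines, drop = FALSE]
  }
  purrr::map_dfr(rownames(m) %||% as.character(seq_len(nrow(m))),
                 function(g) essentiality_test(m[g, ], cutoff = cutoff, gene = g))
}

#' Compare expression fold changes between two gene sets
#'
#' Two-sided Wilcoxon rank-sum test comparing log2 fold changes of two
#' non-overlapping gene sets (e.g. TWAS-identified genes vs the transcriptome
#' background after a TF perturbation). By default the magnitudes
#' `|log2 FC|` are compared; set `use_abs = FALSE` for signed values.
#'
#' @param fc_set_a,fc_set_b Numeric vectors of log2 fold changes.
#' @param use_abs Compare absolute values (default TRUE).
#' @return One-row tibble: `statistic` (rank-sum W), `p_value`,
#'   `median_a`, `median_b`.
#' @export
compare_fold_change_sets <- function(fc_set_a, fc_set_b, use_abs = TRUE) {
  if (!length(fc_set_a) || !length(fc_set_b)) abort("Both sets must be non-empty.")
  a <- if (use_abs) abs(fc_set_a) else fc_set_a
  b <- if (use_abs) abs(fc_set_b) else fc_set_b
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         median_a = median(a), median_b = median(b))
}

#' Log2 fold change from replicate means
#'
#' @param treated,control Numeric matrices (genes x replicates) or vectors of
#'   normalized expression.
#' @return Numeric vector of per-gene `log2(mean(treated) / mean(control))`.
#' @export
log2_fold_change <- function(treated, control) {
  mt <- if (is.matrix(treated)) rowMeans(treated) else treated
  mc <- if (is.matrix(control)) rowMeans(control) else control
  log2(mt / mc)
}
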