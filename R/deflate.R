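#' Build a deflated genome
#'
#' Draws a seeded subsample of variants whose p-value distribution is
#' approximately Uniform(0, 1), preferentially removing small-p variants.
#' Re-running an enrichment analysis on the deflated genome asks whether an
#' annotation's signal survives once the genome-wide-significant excess is
#' stripped away — a deliberately conservative robustness check.
#'
#' P-values are binned into `n_bins` equal-width bins. A variant in bin `b` is
#' kept with probability `min(1, f_ref / f_b)`, where `f_b` is the bin's
#' frequency and `f_ref` the reference-bin frequency. In `per_block` mode the
#' frequencies are computed within each LD block (blocks with fewer variants
#' than `n_bins` fall back to genome-wide frequencies); `global` mode always
#' uses genome-wide frequencies. The reference bin is the highest-p bin by
#' default (`reference = "last"`), the least-enriched bin under the small-p
#' enrichment this procedure targets; `reference = "min"` uses the
#' minimum-frequency bin instead.
#'
#' @param variants Variant tibble with `pvalue` and `block_id`.
#' @param n_bins Number of equal-width p-value bins (>= 2, default 20).
#' @param seed Integer seed controlling the acceptance sampling.
#' @param mode `"per_block"` (default) or `"global"` frequency estimation.
#' @param reference `"last"` (highest-p bin, default) or `"min"`.
#' @param min_block_factor Per-block frequencies are only trusted when a block
#'   holds at least `min_block_factor * n_bins` variants (default 10, i.e. ten
#'   expected variants per bin); smaller blocks fall back to genome-wide
#'   frequencies, which keeps the acceptance probabilities from being driven
#'   by one-variant bins.
#' @return A `tf_deflation` list: `keep` (logical per variant), `bins`
#'   (tibble: bin edges, kept/removed counts), `seed`, `uniformity`
#'   (tibble: KS `statistic`, `p_value` of the kept p-values vs uniform),
#'   `n_input`, `n_kept`.
#' @export
build_deflated_genome <- function(variants, n_bins = 20, seed = 1,
                                  mode = c("per_block", "global"),
                                  reference = c("last", "min"),
                                  min_block_factor = 10) {
  mode <- match.arg(mode)
  reference <- match.arg(reference)
  if (!nrow(variants)) abort("Empty variant table.")
  stopifnot(n_bins >= 2)
  p <- variants$pvalue
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(p, edges, rightmost.closed = TRUE), 1L), n_bins)

  global_f <- tabulate(bin, nbins = n_bins) / length(bin)
  ref_bin <- if (reference == "last") n_bins else which.min(global_f)

  accept_from <- function(f) {
    f_ref <- f[ref_bin]
    acc <- ifelse(f > 0, pmin(1, f_ref / f), 1)
    acc
  }

  accept <- numeric(length(p))
  if (mode == "global") {
    accept <- accept_from(global_f)[bin]
  } else {
    blk <- variants$block_id
    for (b in split(seq_along(p), blk)) {
      if (length(b) < min_block_factor * n_bins) {
        accept[b] <- accept_from(global_f)[bin[b]]
      } else {
        f_blk <- tabulate(bin[b], nbins = n_bins) / length(b)
        # reference frequency taken within the block for a uniform target;
        # fall back to the global reference when the block's reference bin is empty
        f_blk[ref_bin] <- if (f_blk[ref_bin] > 0) f_blk[ref_bin] else global_f[ref_bin]
        accept[b] <- accept_from(f_blk)[bin[b]]
      }
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  keep <- runif(length(p)) < accept

  kept_per_bin <- tabulate(bin[keep], nbins = n_bins)
  removed_per_bin <- tabulate(bin[!keep], nbins = n_bins)
  bins <- tibble(bin = seq_len(n_bins), lower = edges[-(n_bins + 1)],
                 upper = edges[-1],
                 n_kept = kept_per_bin, n_removed = removed_per_bin)
  ks <- uniformity_check(p[keep])
  structure(list(keep = keep, bins = bins, seed = seed, mode = mode,
                 reference = reference, uniformity = ks,
                 n_input = length(p), n_kept = sum(keep)),
            class = "tf_deflation")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
#' @method print tf_deflation
print.tf_deflation <- function(x, ...) {
  cat(sprintf("Deflated genome: kept %d of %d variants (%.1f%%), mode=%s, seed=%d\n",
              x$n_kept, x$n_input, 100 * x$n_kept / x$n_input, x$mode, x$seed))
  cat(sprintf("KS uniformity of kept p-values: D=%.4f, p=%.3g\n",
              x$uniformity$statistic, x$uniformity$p_value))
  invisible(x)
}

#' Kolmogorov-Smirnov check of p-value uniformity
#'
#' One-sample KS test of a p-value vector against Uniform(0, 1).
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return One-row tibble with `statistic` (D) and `p_value`.
#' @export
uniformity_check <- function(pvalues) {
  if (!length(pvalues)) abort("Empty p-value vector.")
  ks <- suppressWarnings(ks.test(pvalues, "punif"))
  tibble(statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' QQ-plot data for observed vs expected -log10 p
#'
#' Expected quantiles are `-log10(i / (n + 1))` for ranked p-values; the usual
#' surface for comparing a whole genome against its deflated subsample.
#'
#' @param pvalues Numeric p-value vector.
#' @param label Series label attached to each row.
#' @return Tibble with `expected`, `observed`, `label`.
#' @export
qq_data <- function(pvalues, label = "genome") {
  p <- sort(pvalues)
  n <- length(p)
  tibble(expected = -log10(seq_len(n) / (n + 1)), observed = -log10(p),
         label = label)
}

#' QQ plot of whole vs deflated genome
#'
#' @param object A `tf_deflation` object.
#' @param variants The variant tibble the deflation was built from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_deflation <- function(object, variants, ...) {
  d <- bind_rows(qq_data(variants$pvalue, "whole genome"),
                 qq_data(variants$pvalue[object$keep], "deflated genome"))
  ggplot2::ggplot(d, ggplot2::aes(.data$expected, .data$observed,
                                  colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c("whole genome" = "#2c64b5",
                                            "deflated genome" = "#c23b22")) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)), colour = NULL) +
    ggplot2::theme_minimal()
}
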