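#' Chi-square statistic from an effect estimate and its standard error
#'
#' The per-variant association statistic is the 1-df Wald chi-square
#' \eqn{(\beta/\mathrm{se})^2}, the quantity modelled against binding
#' annotations by [fit_block_lmm()].
#'
#' @param beta Numeric vector of effect estimates.
#' @param se Numeric vector of standard errors, all strictly positive.
#' @return Numeric vector of chi-square values.
#' @examples
#' chi2_from_beta_se(0.1, 0.05) # 4
#' @export
chi2_from_beta_se <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    abort("`se` must be finite and strictly positive.")
  }
  (beta / se)^2
}

#' Chi-square statistic from a p-value
#'
#' Upper-tail inverse of the 1-df chi-square distribution; the fallback when a
#' summary file reports p-values but not beta/se.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Numeric vector of chi-square values.
#' @examples
#' chi2_from_p(0.05) # ~3.84
#' @export
chi2_from_p <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("`p` must lie in (0, 1].")
  }
  qchisq(p, df = 1, lower.tail = FALSE)
}

#' P-value implied by a 1-df chi-square statistic
#'
#' @param chi2 Numeric vector of non-negative chi-square values.
#' @return Numeric vector of upper-tail p-values.
#' @export
p_from_chi2 <- function(chi2) {
  if (any(chi2 < 0)) abort("`chi2` must be non-negative.")
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Assign variants to non-overlapping LD blocks
#'
#' Contiguous genomic windows of `block_size` base pairs stand in for LD
#' blocks: within-window dependence between variants is absorbed by a
#' per-block random intercept in the enrichment model. Windows are numbered
#' independently per chromosome and then made globally unique, so equal
#' positions on different chromosomes never share a block.
#'
#' @param variants A variant tibble with `chrom` and 1-based `pos` columns.
#' @param block_size Window width in bp (default 100 kb; 500 kb is the usual
#'   sensitivity setting).
#' @return `variants` with an integer `block_id` column (0-based, globally
#'   unique) replacing any existing one.
#' @export
assign_ld_blocks <- function(variants, block_size = 1e5) {
  stopifnot(is.numeric(block_size), length(block_size) == 1, block_size > 0)
  if (!all(c("chrom", "pos") %in% names(variants))) {
    abort("`variants` must have `chrom` and `pos` columns.")
  }
  within <- floor((variants$pos - 1) / block_size)
  key <- paste(variants$chrom, within, sep = ":")
  # stable global numbering: sort keys by (chrom, window index)
  ord <- order(variants$chrom, within)
  lev <- unique(key[ord])
  variants$block_id <- match(key, lev) - 1L
  variants
}

#' Read and validate GWAS summary statistics
#'
#' Reads a tab-separated summary file, normalizes column names, derives the
#' per-variant 1-df chi-square statistic and assigns LD blocks. The chi-square
#' source is \eqn{(\beta/\mathrm{se})^2} when both `beta` and `se` are present,
#' falling back to the inverse chi-square of the reported p-value; when both
#' routes are available and disagree by more than 1% relative, a warning
#' reports the count. Rows with non-positive `se` or p-values outside (0, 1]
#' are dropped with a message; p-values of exactly 0 are clamped to the
#' smallest representable positive double and logged. Duplicated
#' (chrom, pos, ref, alt) keys are a hard error.
#'
#' @param path Path to a TSV file.
#' @param column_map Named character vector mapping canonical names
#'   (`chrom`, `pos`, `ref`, `alt`, `beta`, `se`, `p`) to the file's column
#'   names; defaults assume canonical names.
#' @param block_size LD-block width in bp passed to [assign_ld_blocks()].
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `beta`, `se`,
#'   `pvalue`, `chi2`, `block_id`, sorted by (chrom, pos, ref, alt).
#' @export
read_gwas_summary <- function(path, column_map = NULL, block_size = 1e5) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  canonical <- c("chrom", "pos", "ref", "alt", "beta", "se", "p")
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  for (canon in canonical) {
    src <- map[[canon]]
    if (src %in% names(raw) && src != canon) names(raw)[names(raw) == src] <- canon
  }
  if (!all(c("chrom", "pos") %in% names(raw))) {
    abort("Summary file must provide `chrom` and `pos` columns (after mapping).")
  }
  has_beta_se <- all(c("beta", "se") %in% names(raw))
  has_p <- "p" %in% names(raw)
  if (!has_beta_se && !has_p) {
    abort("Summary file must provide either beta+se or p (after mapping).")
  }
  tab <- as_tibble(raw)
  tab$chrom <- as.character(tab$chrom)
  tab$pos <- as.integer(tab$pos)
  if (!"ref" %in% names(tab)) tab$ref <- NA_character_
  if (!"alt" %in% names(tab)) tab$alt <- NA_character_

  for (col in intersect(c("beta", "se", "p"), names(tab))) {
    bad <- !is.na(tab[[col]]) & is.na(suppressWarnings(as.numeric(tab[[col]])))
    if (any(bad)) {
      abort(sprintf("Unparseable numeric in column `%s` at row(s) %s.",
                    col, paste(head(which(bad), 5), collapse = ", ")))
    }
    tab[[col]] <- as.numeric(tab[[col]])
  }

  n0 <- nrow(tab)
  drop <- rep(FALSE, n0)
  if (has_beta_se) drop <- drop | is.na(tab$se) | tab$se <= 0
  if (has_p) {
    clamp <- !is.na(tab$p) & tab$p == 0
    if (any(clamp)) {
      tab$p[clamp] <- .Machine$double.xmin
      inform(sprintf("%d p-value(s) of exactly 0 clamped to %.3g.",
                     sum(clamp), .Machine$double.xmin))
    }
    drop <- drop | (!has_beta_se & (is.na(tab$p) | tab$p <= 0 | tab$p > 1)) |
      (has_p & !is.na(tab$p) & (tab$p < 0 | tab$p > 1))
  }
  if (any(drop)) {
    inform(sprintf("Dropped %d row(s) with invalid se or p.", sum(drop)))
    tab <- tab[!drop, , drop = FALSE]
  }

  key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicated variant key(s): %s",
                  paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
                        collapse = ", ")))
  }

  if (has_beta_se) {
    tab$chi2 <- chi2_from_beta_se(tab$beta, tab$se)
    if (has_p) {
      ok <- !is.na(tab$p) & tab$p > 0 & tab$p <= 1
      implied <- rep(NA_real_, nrow(tab))
      implied[ok] <- chi2_from_p(tab$p[ok])
      rel <- abs(tab$chi2 - implied) / pmax(implied, .Machine$double.eps)
      n_dis <- sum(ok & rel > 0.01, na.rm = TRUE)
      if (n_dis > 0) {
        warn(sprintf(
          "%d variant(s) have >1%% relative disagreement between (beta/se)^2 and the reported p-value.",
          n_dis))
      }
    }
  } else {
    tab$chi2 <- chi2_from_p(tab$p)
    tab$beta <- NA_real_
    tab$se <- NA_real_
  }
  tab$pvalue <- if (has_p) tab$p else p_from_chi2(tab$chi2)
  tab <- tab[, c("chrom", "pos", "ref", "alt", "beta", "se", "pvalue", "chi2")]
  tab <- arrange(tab, .data$chrom, .data$pos, .data$ref, .data$alt)
  assign_ld_blocks(tab, block_size = block_size)
}

#' Write a normalized variant table
#'
#' @param variants Variant tibble as returned by [read_gwas_summary()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(variants, path) {
  readr::write_tsv(variants, path, progress = FALSE)
  invisible(path)
}
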