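# Shared fixture builders: everything is generated in code at test time.

write_toy_gwas <- function(path, df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      chrom = c("chr1", "chr1", "chr2"),
      pos = c(150L, 250L, 150L),
      ref = c("A", "C", "G"),
      alt = c("G", "T", "A"),
      beta = c(0.1, 0, -0.3),
      se = c(0.05, 1, 0.1),
      p = c(0.0455, 1, 0.00270))
    df$p <- tfgwas::p_from_chi2((df$beta / df$se)^2)
  }
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# brute-force interval containment: 1-based variant pos vs 0-based [start,end)
brute_force_overlap <- function(variants, peaks) {
  vapply(seq_len(nrow(variants)), function(i) {
    p0 <- variants$pos[i] - 1
    any(peaks$chrom == variants$chrom[i] & peaks$start <= p0 & p0 < peaks$end)
  }, logical(1))
}

# textbook normal-equations OLS
ols_oracle <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# small random design fixture for mixed-model tests
random_fixture <- function(seed, n_blocks = 30, vpb = 10, p_extra = 2) {
  set.seed(seed)
  n <- n_blocks * vpb
  X <- cbind(`(Intercept)` = 1,
             matrix(rnorm(n * p_extra), n,
                    dimnames = list(NULL, paste0("x", seq_len(p_extra)))))
  blocks <- rep(seq_len(n_blocks), each = vpb)
  y <- rnorm(n, mean = X %*% runif(p_extra + 1, -1, 1), sd = 1) +
    rep(rnorm(n_blocks, sd = 0.5), each = vpb)
  list(y = y, X = X, blocks = blocks)
}
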