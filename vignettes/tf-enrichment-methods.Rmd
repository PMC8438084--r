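---
title: "Modelling TF-binding enrichment in GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TF-binding enrichment in GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfgwas)
```

## The question and the model

Common-variant heritability for complex traits concentrates in regulatory
DNA. If genetic variation inside the binding sites of a transcription factor
(TF) perturbs that factor's regulatory program, variants covered by the TF's
ChIP-seq peaks should carry systematically larger GWAS association
statistics than the rest of the genome. `tfgwas` quantifies that excess
directly on summary statistics.

Each variant contributes its 1-df Wald chi-square
$Y_{ij} = (\hat\beta_{ij}/\mathrm{se}_{ij})^2$, indexed by LD block $i$ and
variant $j$. Nearby variants are correlated through LD, so the per-TF model
is a linear mixed model with a random intercept per block:

$$Y_{ij} = \beta_0 + \beta_1\,\mathrm{TF}_{ij} + V_i + \varepsilon_{ij},
\qquad V_i \sim N(0, \sigma_b^2),\ \varepsilon_{ij} \sim N(0, \sigma_e^2),$$

where $\mathrm{TF}_{ij} \in \{0,1\}$ indicates binding-site occupancy. The
slope $\beta_1$ is the mean chi-square difference between bound and unbound
variants, written $\Delta\bar\chi^2$. Co-occupancy of two TFs adds main
effects and a product term whose coefficient $\beta_3$ measures super- or
sub-additive co-binding; chromatin states enter as dummy contrasts against
the quiescent state; the TF score (number of distinct panel TFs covering a
variant) enters continuously or as the categories 0 / 1–5 / 6–max.

Blocks are non-overlapping 100 kb windows by default (500 kb as a
sensitivity setting). This is a deliberate approximation: block windows do
not track recombination hotspots, and the random intercept captures
block-level exchangeable correlation only. A chi-square response is not
Gaussian; at genome scale (millions of variants) the fixed-effect estimator
and its Wald z are insensitive to that misspecification, which is why the
Gaussian-error form is used. A gamma-error variant is out of scope.

## Estimation

The two variance components are estimated by REML with the ratio
$\theta = \sigma_b^2/\sigma_e^2$ profiled on the log scale, using the
Sherman–Morrison identity blockwise:
$(I + \theta J_{n_i})^{-1} = I - \tfrac{\theta}{1+\theta n_i} J_{n_i}$.
Every objective evaluation therefore needs only per-block sufficient
statistics, so fitting is $O(\text{blocks} \times p^2)$ per iteration,
linear in the variant count, and no $n \times n$ matrix ever exists. The
1-D optimizer runs at tolerance $10^{-8}$ with an explicit boundary
comparison at $\theta = 0$; at the boundary the fit reduces exactly to OLS
(asserted against a normal-equations oracle in the tests, and cross-checked
against `lme4::lmer` away from the boundary). Inference is Wald-z against
the standard normal — at the sample sizes this model is meant for, t vs z is
immaterial, which the tests verify at desk scale. Binary columns with fewer
than 100 occupied variants are fitted but flagged `low_support`.

When several ChIP-seq datasets exist for one TF, all are fitted; the
smallest-p dataset can be selected afterwards with
`collapse_best_dataset()`, keeping the selection explicit.

## The deflated genome

A strongly powered GWAS leaves genome-wide-significant peaks that could
dominate any enrichment estimate. The deflated genome is a seeded subsample
whose p-value distribution is approximately uniform: p-values are binned
into 20 equal-width bins and a variant in bin $b$ survives with probability
$\min(1, f_{\mathrm{ref}}/f_b)$. The reference bin is the highest-p bin —
under small-p enrichment it is the least-enriched bin, and using it keeps a
genuinely uniform input essentially untouched (the minimum-frequency bin
would let multinomial noise alone delete several percent). Frequencies are
computed per LD block, falling back to genome-wide frequencies when a block
has fewer than `min_block_factor * n_bins` variants (default 10 per bin):
per-block estimation from a handful of variants per bin would make the
acceptance probabilities noise-driven. A `global` mode is available.
Enrichment that survives deflation cannot be explained by the
genome-wide-significant loci alone; the procedure is intentionally
conservative, and the tests assert that a planted enrichment is attenuated
but not erased.

## TF-restricted TWAS

Expression models use only putative regulatory variants: within ±1 Mb of
the TSS, GWAS $p < 0.01$, TF score ≥ 1. Covariates are regressed out of
expression before the penalized fit; this residualization differs from
including covariates inside the penalized regression but coincides with it
in the no-penalty limit and keeps the elastic-net problem standard. The
mixing parameter is fixed at 0.5 (the TWAS convention) and the penalty is
chosen by internal cross-validation with seed-controlled folds. `cv_r2` is
the squared *positive* out-of-fold correlation: under the null,
out-of-fold predictions systematically anti-correlate with the response,
and squaring a negative correlation would masquerade as predictive ability.

The summary-level association is

$$Z_g \approx \sum_{l \in \mathrm{Model}_g} w_{lg}
  \frac{\hat\sigma_l}{\hat\sigma_g} \frac{\hat\beta_l}{\mathrm{se}(\hat\beta_l)},$$

with $\hat\sigma_l$ the dosage SD and $\hat\sigma_g$ the SD of predicted
expression under the reference covariance ($\hat\sigma_g^2 = w^\top \Sigma w$).
The reference defaults to the training panel but is pluggable; when the
reference and the GWAS cohort are the same sample, $Z_g$ matches the
individual-level regression z-score, which is the oracle test the suite
runs. Alleles are harmonized on (chrom, pos): swapped alleles flip the
z-score sign, strand-ambiguous A/T and C/G mismatches are dropped with a
warning. A gene is called significant when `cv_r2 > 0.01` in at least two
expression datasets and the minimum association p across datasets is below
1e-5.

## Essentiality follow-up

For each gene, dependency scores across 34 cell lines are reduced to the
count of negative values, tested one-sided against Binomial(n, 1/2)
("greater": essentiality manifests as an excess of negative effects, so the
one-sided alternative is the natural choice), plus a median-below-−0.5 flag that is
deliberately independent of the test. Fold-change comparisons between gene
sets use the two-sided Wilcoxon rank-sum test on |log2 FC| (the sets are
unpaired; a signed-rank variant is therefore not offered).

## The synthetic world

Every stage is exercisable offline through generators whose defaults are
fixed once:

- **GWAS z-scores**: $z_{ij} = \sqrt{\rho}\,u_i + \sqrt{1-\rho}\,e_{ij} +
  \sum_f \lambda_f A_{ijf}$, so $\chi^2 = z^2$ and the expected bound-unbound
  difference for a single TF is exactly $\lambda^2$. The factor structure
  matches the random-intercept model's assumption; it does not emulate real
  LD decay, allele-frequency spectra, or the heavy empirical tail of a real consortium GWAS, so a green
  recovery test establishes estimator correctness, not real-data replication.
- **Profiles**: smoke = 500 blocks × 20 variants, 5 TFs at 5% coverage,
  $\rho = 0.2$; calibration = 5,000 × 50, $\rho = 0.3$; both with
  $\lambda = 1$ on one TF by default (a mean chi-square excess of 1 —
  the order of magnitude a strongly enriched regulator shows genome-wide).
  Deflation robustness uses $\lambda = 2$, a heavily enriched input whose
  raw p-values visibly fail uniformity.
- **Co-binding**: peaks are slot-sampled so marginal coverage is exact and
  designed pairwise co-occupancy is hit at the slot level; the planted
  super-additive test uses a z-scale co-binding shift of 1 at 30%
  co-occupancy, detectable at the 0.05/231 pairwise threshold at smoke size.
- **Expression panels**: two haplotypes per sample with a neighbour-copy LD
  surrogate, 3 causal variants, $h^2 = 0.3$ (a typical cis-heritability for
  a well-predicted gene), 300 training samples, 5,000-sample cohorts for
  the summary-vs-individual oracle.
- **Gene effects**: essential genes at mean −1 (SD 0.3) across 34 cells,
  well separated from the −0.5 cutoff.

All generators are pure functions of (configuration, seed); the CLI writes
plain-text outputs that are byte-identical under a repeated seed.

## Numerical choices and degenerate inputs

- Positions are 1-based; interval files are BED 0-based half-open; the
  conversion happens once, at lookup.
- p-values of exactly 0 are clamped to the smallest positive double and
  logged; chi-square/p round trips are exact to 1e-9.
- Rank-deficient designs error naming the collinear columns; an all-zero
  annotation column is such a case. An empty 2×2 co-occupancy cell flags
  the fit degenerate rather than silently extrapolating.
- Host motif status wins over non-host when both cover a variant;
  unsegmented chromatin positions get the quiescent state, with a count.
- Variants with both beta/se and p are checked for >1% relative
  disagreement between the two chi-square routes; beta/se wins.

## Limitations

Block windows are a crude LD proxy; the enrichment estimate is marginal,
not conditional on other annotations (no joint heritability partitioning);
the deflation subsample targets a distribution, not a canonical
membership, so two implementations can keep different variants while both
being valid; and headline gene counts from real multi-cohort analyses are
outside what synthetic panels can or should reproduce.
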